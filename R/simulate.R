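#' Pathway dynamics archetype
#'
#' Describes a class of pathway time courses in log2 space: the expected
#' log2 change into each non-baseline sampled week, plus the standard
#' deviation of Gaussian log2 noise added to each step (i.e.
#' multiplicative lognormal noise on abundances).
#'
#' @param name archetype label.
#' @param log2_shifts named numeric vector, week -> expected log2 change
#'   relative to the previous sampled week.
#' @param noise_sd non-negative Gaussian sd in log2 units.
#' @return list of class `pathway_archetype`.
#' @export
pathway_archetype <- function(name, log2_shifts, noise_sd = 0.1) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(names(log2_shifts)))
    stop("log2_shifts must be named by week")
  structure(list(name = name,
                 log2_shifts = log2_shifts,
                 noise_sd = noise_sd),
            class = "pathway_archetype")
}

#' Constant archetype (no expected change at any week)
#' @param weeks non-baseline sampled weeks.
#' @param noise_sd log2 noise sd.
#' @return a [pathway_archetype()].
#' @export
archetype_constant <- function(weeks = c(1, 3, 6, 12, 24),
                               noise_sd = 0.1) {
  pathway_archetype("constant",
                    stats::setNames(rep(0, length(weeks)), weeks),
                    noise_sd)
}

#' Oscillating archetype: sharp rise, collapse, slight re-rise
#'
#' Default log2 shifts (+3, -3, +1, 0, 0) over weeks 1, 3, 6, 12, 24 —
#' a pronounced bloom-and-bust pattern typical of disturbance-responsive
#' pathways, well separated from step noise.
#'
#' @param weeks non-baseline sampled weeks (length 5 for the default
#'   shifts).
#' @param shifts log2 shifts per week.
#' @param noise_sd log2 noise sd.
#' @return a [pathway_archetype()].
#' @export
archetype_oscillating <- function(weeks = c(1, 3, 6, 12, 24),
                                  shifts = c(3, -3, 1, 0, 0),
                                  noise_sd = 0.1) {
  pathway_archetype("oscillating", stats::setNames(shifts, weeks),
                    noise_sd)
}

.arm_weeks <- function(design, arm) {
  sort(design$week[design$arm == arm])
}

.check_archetype_weeks <- function(archetype, weeks) {
  miss <- setdiff(as.character(weeks), names(archetype$log2_shifts))
  if (length(miss) > 0L)
    stop("archetype '", archetype$name, "' defines no shift for week ",
         miss[1L])
}

#' Simulate pathway abundance tables with planted cluster structure
#'
#' Generates a normalized pathway-abundance table over the full design:
#' a majority of pathways following the constant archetype and a
#' minority following the oscillating archetype in the polluted arm
#' (default group sizes 100 and 46). In the control arm every pathway
#' follows the constant archetype (slight noise-driven oscillation
#' only). Each series starts at `baseline_abundance` at week 0 and
#' multiplies by `2^(shift + noise)` at each step.
#'
#' @param design a [sample_design()] (default [default_design()]).
#' @param n_constant,n_responsive planted group sizes (defaults 100
#'   and 46).
#' @param archetype_const,archetype_resp the two
#'   [pathway_archetype()]s; must define shifts for every non-baseline
#'   week of the design.
#' @param baseline_abundance week-0 abundance of every pathway
#'   (default 0.01).
#' @param seed RNG seed; the generator is a pure function of its
#'   arguments and the seed.
#' @return list with `abundance` (pathway [abundance_table()] over all
#'   design samples) and `truth` (data.frame `pathway_id`, `group` in
#'   \{constant, responsive\}).
#' @export
simulate_pathway_tables <- function(design = default_design(),
                                    n_constant = 100,
                                    n_responsive = 46,
                                    archetype_const = archetype_constant(),
                                    archetype_resp = archetype_oscillating(),
                                    baseline_abundance = 0.01,
                                    seed = 1) {
  if (n_constant + n_responsive < 2L)
    stop("need at least 2 pathways in total")
  for (arm in c("control", "polluted")) {
    wk <- .arm_weeks(design, arm)
    .check_archetype_weeks(archetype_const, wk)
    .check_archetype_weeks(archetype_resp, wk)
  }
  n <- n_constant + n_responsive
  ids <- sprintf("path%03d", seq_len(n))
  group <- rep(c("constant", "responsive"), c(n_constant, n_responsive))
  m <- matrix(NA_real_, n, nrow(design),
              dimnames = list(ids, design$sample_id))
  base_id <- design$sample_id[design$arm == "baseline"]
  m[, base_id] <- baseline_abundance
  withr::with_seed(seed, {
    for (arm in c("control", "polluted")) {
      series <- arm_series(design, arm)
      for (i in seq_len(n)) {
        arch <- if (arm == "polluted" && group[i] == "responsive")
          archetype_resp else archetype_const
        val <- baseline_abundance
        for (r in 2:nrow(series)) {
          wk <- as.character(series$week[r])
          step <- arch$log2_shifts[[wk]] +
            if (arch$noise_sd > 0) stats::rnorm(1L, 0, arch$noise_sd) else 0
          val <- val * 2^step
          m[i, series$sample_id[r]] <- val
        }
      }
    }
  })
  list(abundance = abundance_table(m, "pathway"),
       truth = data.frame(pathway_id = ids, group = group,
                          stringsAsFactors = FALSE))
}

#' Simulate marker-gene (and KO) read counts from planted genome counts
#'
#' For each marker g and sample s the expected read count is
#' `truth(s) * length(g)`; counts are Poisson-sampled around that
#' expectation, or rounded expectations when `noise = FALSE`, so that
#' [estimate_genome_equivalents()] is the exact inverse of the
#' noise-free construction.
#'
#' @param design a [sample_design()].
#' @param catalog a [ko_catalog()] holding every marker's length.
#' @param markers a [marker_set()].
#' @param ge_truth named numeric vector sample -> planted genome
#'   equivalents (positive).
#' @param seed RNG seed.
#' @param noise Poisson sampling when `TRUE` (default).
#' @return list with `counts` (a `ko` [count_table()]) and `truth`
#'   (the planted `ge_truth`).
#' @export
simulate_marker_and_ko_counts <- function(design, catalog, markers,
                                          ge_truth, seed = 1,
                                          noise = TRUE) {
  miss <- setdiff(markers, names(catalog$lengths))
  if (length(miss) > 0L)
    stop("marker '", miss[1L], "' missing from catalog")
  samples <- design$sample_id
  if (!all(samples %in% names(ge_truth)))
    stop("ge_truth must cover every design sample")
  if (any(ge_truth[samples] <= 0)) stop("ge_truth must be positive")
  lam <- outer(catalog$lengths[markers], ge_truth[samples])
  counts <- withr::with_seed(seed, {
    if (noise) matrix(stats::rpois(length(lam), lam), nrow(lam),
                      dimnames = dimnames(lam))
    else round(lam)
  })
  list(counts = count_table(counts, "ko"),
       truth = ge_truth[samples])
}

#' Specification of a coupled host/phage bloom
#'
#' @param host_feature host genus label.
#' @param host_peak_week,phage_peak_week peak weeks (must be sampled
#'   weeks of the design used).
#' @param host_fold,phage_fold peak-over-baseline fold rises (>= 1).
#' @param phage_contig_id,phage_contig_length contig label and bp length.
#' @return list of class `bloom_spec`.
#' @export
bloom_spec <- function(host_feature = "Burkholderia",
                       host_peak_week = 1, host_fold = 23,
                       phage_contig_id = "contig70_3",
                       phage_contig_length = 44500,
                       phage_peak_week = 6, phage_fold = 17000) {
  if (host_fold < 1 || phage_fold < 1) stop("folds must be >= 1")
  if (phage_contig_length <= 0) stop("contig length must be positive")
  structure(list(host_feature = host_feature,
                 host_peak_week = host_peak_week,
                 host_fold = host_fold,
                 phage_contig_id = phage_contig_id,
                 phage_contig_length = phage_contig_length,
                 phage_peak_week = phage_peak_week,
                 phage_fold = phage_fold),
            class = "bloom_spec")
}

#' Simulate a transient host bloom followed by a phage-contig bloom
#'
#' In the polluted arm the host genus count peaks at
#' `host_fold x baseline` at its peak week and the phage-contig hit
#' count peaks at `phage_fold x baseline` at its (later) peak week; all
#' other polluted weeks, the whole control arm and the baseline sample
#' stay at `baseline_hits`. Optional Poisson noise around those
#' expectations.
#'
#' @param design a [sample_design()].
#' @param spec a [bloom_spec()]; peak weeks must be sampled weeks.
#' @param baseline_hits baseline read count (>= 1).
#' @param seed RNG seed.
#' @param noise Poisson sampling when `TRUE` (default `FALSE`: exact
#'   planted series).
#' @return list with `host` (genus [count_table()]), `phage` (contig
#'   [count_table()]) and `spec`.
#' @export
simulate_phage_bloom <- function(design = default_design(),
                                 spec = bloom_spec(),
                                 baseline_hits = 100, seed = 1,
                                 noise = FALSE) {
  if (baseline_hits < 1) stop("baseline_hits must be >= 1")
  wk_poll <- c(0, .arm_weeks(design, "polluted"))
  if (!spec$host_peak_week %in% wk_poll ||
      !spec$phage_peak_week %in% wk_poll)
    stop("peak weeks must be sampled weeks of the polluted arm")
  mk <- function(peak_week, fold) {
    x <- stats::setNames(rep(baseline_hits, nrow(design)),
                         design$sample_id)
    at_peak <- design$arm == "polluted" & design$week == peak_week
    x[at_peak] <- round(fold * baseline_hits)
    x
  }
  host <- mk(spec$host_peak_week, spec$host_fold)
  phage <- mk(spec$phage_peak_week, spec$phage_fold)
  if (noise) {
    withr::with_seed(seed, {
      host <- stats::setNames(stats::rpois(length(host), host),
                              names(host))
      phage <- stats::setNames(stats::rpois(length(phage), phage),
                               names(phage))
    })
  }
  as_table <- function(x, feat, kind)
    count_table(matrix(x, 1L, dimnames = list(feat, names(x))), kind)
  list(host = as_table(host, spec$host_feature, "genus"),
       phage = as_table(phage, spec$phage_contig_id, "contig"),
       spec = spec)
}

#' Build a pathway-filter fixture with known pass/fail composition
#'
#' Generates a normalized pathway table plus prokaryote flags in which
#' exactly `n_nonprok` pathways fail the prokaryote rule, `n_below_cutoff`
#' never reach the abundance cutoff, `n_with_zero` contain a zero
#' abundance, and all remaining pathways pass all three filter rules
#' (the three failure sets are disjoint by construction).
#'
#' @param n_total total number of pathways (default 160).
#' @param n_nonprok pathways flagged non-prokaryotic (default 8).
#' @param n_below_cutoff pathways with max abundance below `cutoff`
#'   (default 4).
#' @param n_with_zero pathways with a zero entry (default 2).
#' @param n_timepoints number of time-ordered sample columns (default 6).
#' @param cutoff the filter cutoff the fixture is built against
#'   (default 1e-4).
#' @param seed RNG seed.
#' @return list with `abundance` (pathway [abundance_table()]),
#'   `prokaryote_flags` (named logical) and `truth` (data.frame
#'   `pathway_id`, `category`).
#' @export
make_filter_fixture <- function(n_total = 160, n_nonprok = 8,
                                n_below_cutoff = 4, n_with_zero = 2,
                                n_timepoints = 6, cutoff = 1e-4,
                                seed = 1) {
  n_fail <- n_nonprok + n_below_cutoff + n_with_zero
  if (n_fail > n_total)
    stop("failure sets exceed n_total (overlap would be required)")
  ids <- sprintf("pw%03d", seq_len(n_total))
  cat_lab <- rep("pass", n_total)
  i <- 0L
  take <- function(k) { idx <- i + seq_len(k); i <<- i + k; idx }
  idx_np <- take(n_nonprok); cat_lab[idx_np] <- "non_prokaryote"
  idx_bc <- take(n_below_cutoff); cat_lab[idx_bc] <- "below_cutoff"
  idx_z  <- take(n_with_zero); cat_lab[idx_z] <- "has_zero"
  cols <- paste0("t", seq_len(n_timepoints))
  withr::with_seed(seed, {
    m <- matrix(stats::runif(n_total * n_timepoints, 10 * cutoff,
                             100 * cutoff),
                n_total, n_timepoints, dimnames = list(ids, cols))
    m[idx_bc, ] <- matrix(stats::runif(length(idx_bc) * n_timepoints,
                                       cutoff / 100, cutoff * 0.9),
                          length(idx_bc), n_timepoints)
    for (j in idx_z)
      m[j, sample.int(n_timepoints, 1L)] <- 0
  })
  flags <- stats::setNames(rep(TRUE, n_total), ids)
  flags[idx_np] <- FALSE
  list(abundance = abundance_table(m, "pathway"),
       prokaryote_flags = flags,
       truth = data.frame(pathway_id = ids, category = cat_lab,
                          stringsAsFactors = FALSE))
}

#' Simulate all-against-all best-hit bit-score summaries
#'
#' Plants `S(A -> B) = similarity(A, B) * self_scores(A)`, so the D2
#' distance downstream equals `1 - similarity(A, B)`. All n x n ordered
#' pairs are emitted.
#'
#' @param design a [sample_design()].
#' @param self_scores named numeric vector sample -> S(A -> A) (> 0).
#' @param similarity symmetric matrix over the samples with unit
#'   diagonal and entries in \[0, 1\].
#' @return square matrix S of ordered-pair scores.
#' @export
simulate_blast_summaries <- function(design = default_design(),
                                     self_scores, similarity) {
  samples <- design$sample_id
  if (!all(samples %in% names(self_scores)))
    stop("self_scores must cover every design sample")
  if (any(self_scores[samples] <= 0)) stop("self_scores must be > 0")
  sim <- similarity[samples, samples]
  if (any(abs(sim - t(sim)) > 1e-12)) stop("similarity must be symmetric")
  if (any(abs(diag(sim) - 1) > 1e-12))
    stop("similarity(A, A) must equal 1")
  if (any(sim < 0 | sim > 1)) stop("similarity must lie in [0, 1]")
  S <- sim * self_scores[samples]  # row A scaled by self score of A
  dimnames(S) <- list(samples, samples)
  S
}

#' Run a named simulation preset and optionally write its outputs
#'
#' Presets bundle the default study conditions: `"m1m2"` (146 pathways,
#' 100 constant + 46 oscillating, step noise sd 0.1), `"bloom"` (host
#' peak at week 1 at 23x, 44.5-kb phage contig peak at week 6 at
#' 17000x) and `"filters"` (the 160/8/4/2 filter fixture).
#'
#' @param preset one of `"m1m2"`, `"bloom"`, `"filters"`.
#' @param seed RNG seed.
#' @param out_dir optional directory; when given, all tables plus a
#'   `truth.tsv` are written there as TSV.
#' @return the preset's simulation result list.
#' @export
simulate_preset <- function(preset = c("m1m2", "bloom", "filters"),
                            seed = 1, out_dir = NULL) {
  preset <- match.arg(preset)
  design <- default_design()
  res <- switch(preset,
    m1m2 = simulate_pathway_tables(design, seed = seed),
    bloom = simulate_phage_bloom(design, seed = seed),
    filters = make_filter_fixture(seed = seed))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    if (preset == "m1m2") {
      write_table_tsv(res$abundance, p("pathway_abundance.tsv"))
      poll <- arm_series(design, "polluted")$sample_id
      ctrl <- arm_series(design, "control")$sample_id
      write_table_tsv(res$abundance[, poll, drop = FALSE],
                      p("pathway_abundance_polluted.tsv"))
      write_table_tsv(res$abundance[, ctrl, drop = FALSE],
                      p("pathway_abundance_control.tsv"))
      utils::write.table(res$truth, p("truth.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    } else if (preset == "bloom") {
      write_table_tsv(res$host, p("host_counts.tsv"))
      write_table_tsv(res$phage, p("phage_contig_hits.tsv"))
      utils::write.table(
        data.frame(field = names(unclass(res$spec)),
                   value = vapply(unclass(res$spec), as.character, "")),
        p("truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      write_table_tsv(res$abundance, p("pathway_abundance.tsv"))
      utils::write.table(
        data.frame(pathway_id = names(res$prokaryote_flags),
                   prokaryote_flag = unname(res$prokaryote_flags)),
        p("prokaryote_flags.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      utils::write.table(res$truth, p("truth.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  res
}
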