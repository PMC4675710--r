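#' Classify candidate phage-genome contigs
#'
#' A contig is accepted as a putative phage-genome contig when it
#' (i) exceeds `min_length_bp` in length (strict), (ii) belongs to the
#' phage genome-related contig set, (iii) carries at least one CDS with
#' amino-acid identity >= `min_identity` against a phage-ortholog
#' database, and (iv) contains at least one phage-derived genomic region
#' call.
#'
#' @param records data.frame with columns `contig_id`, `length_bp`,
#'   `phage_related` (logical), `max_pog_identity` (percent),
#'   `phast_region_count` (and optionally `completeness`).
#' @param min_length_bp minimal contig length in bp, exclusive
#'   (default 2000).
#' @param min_identity minimal best CDS identity, inclusive (default 40).
#' @return character vector of accepted contig ids.
#' @export
classify_phage_contigs <- function(records, min_length_bp = 2000,
                                   min_identity = 40) {
  need <- c("contig_id", "length_bp", "phage_related",
            "max_pog_identity", "phast_region_count")
  miss <- setdiff(need, colnames(records))
  if (length(miss) > 0L)
    stop("records lack column '", miss[1L], "'")
  if (any(records$max_pog_identity < 0 | records$max_pog_identity > 100))
    stop("max_pog_identity must lie in [0, 100]")
  keep <- records$length_bp > min_length_bp &
    as.logical(records$phage_related) &
    records$max_pog_identity >= min_identity &
    records$phast_region_count >= 1
  mc_log("classify_phage_contigs: %d/%d accepted", sum(keep), nrow(records))
  records$contig_id[keep]
}

#' Read a contig annotation table from TSV
#'
#' Columns: `contig_id`, `length_bp`, `phage_related`,
#' `max_pog_identity`, `phast_region_count`, `completeness`.
#'
#' @param path TSV path.
#' @return data.frame of contig records.
#' @export
read_contig_records <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$phage_related <- as.logical(df$phage_related)
  df
}

#' Normalized contig abundance time series
#'
#' Divides per-contig hit counts by contig length (bp) and by the
#' sample's genome-equivalent estimate — the same two-step normalization
#' applied to gene-level features.
#'
#' @param hits contig [count_table()] of BLASTN hit reads.
#' @param lengths named numeric vector contig -> length in bp.
#' @param ge genome equivalents per sample.
#' @return an [abundance_table()] with `kind = "contig"`.
#' @export
contig_abundance_series <- function(hits, lengths, ge) {
  normalize_per_genome(length_normalize(hits, lengths), ge)
}

#' Rescale a series so its smallest positive value is 1
#'
#' Presentation helper for relative time courses (abundances expressed
#' by taking the smallest value as 1).
#'
#' @param x numeric vector with at least one positive value.
#' @return `x / min(x[x > 0])`.
#' @export
relative_to_min <- function(x) {
  pos <- x[x > 0]
  if (length(pos) == 0L) stop("no positive value in series")
  x / min(pos)
}

#' Detect host-bloom / phage-bloom asynchrony (kill-the-winner signal)
#'
#' Locates the peak weeks of a host genus abundance series and of a
#' putative phage contig series on the same week grid, computes fold
#' rises relative to configurable baseline weeks, and flags a
#' kill-the-winner pattern when the phage peak lags the host peak, the
#' phage rise is large, and the host has declined by the phage peak.
#'
#' @param host_series named numeric vector of host abundances, names =
#'   weeks; strictly positive.
#' @param phage_series likewise for the phage contig, identical week grid
#'   with at least 3 points.
#' @param host_baseline_week,phage_baseline_week weeks used as fold-rise
#'   denominators (defaults: the earliest week of each series).
#' @param min_phage_fold minimal phage fold rise for the flag
#'   (default 100).
#' @param min_host_decline_fold minimal host decline between host peak
#'   and phage peak (default 2).
#' @return one-row data.frame (class `bloom_report`): `host_peak_week`,
#'   `phage_peak_week`, `lag_weeks`, `host_fold_rise`,
#'   `phage_fold_rise`, `host_decline_after_phage_rise`, `ktw_flag`.
#' @export
detect_bloom_asynchrony <- function(host_series, phage_series,
                                    host_baseline_week = NULL,
                                    phage_baseline_week = NULL,
                                    min_phage_fold = 100,
                                    min_host_decline_fold = 2) {
  hw <- as.numeric(names(host_series))
  pw <- as.numeric(names(phage_series))
  if (length(hw) < 3L) stop("need at least 3 time points")
  if (!identical(hw, pw))
    stop("host and phage series must share the same week grid")
  if (any(host_series <= 0) || any(phage_series <= 0))
    stop("series values must be strictly positive")
  if (is.null(host_baseline_week)) host_baseline_week <- min(hw)
  if (is.null(phage_baseline_week)) phage_baseline_week <- min(pw)
  if (!host_baseline_week %in% hw || !phage_baseline_week %in% pw)
    stop("baseline week not in the sampled weeks")
  peak_week <- function(x, w) w[which.max(x)]  # earliest week on ties
  hp <- peak_week(host_series, hw)
  pp <- peak_week(phage_series, pw)
  host_fold <- unname(host_series[hw == hp] /
                        host_series[hw == host_baseline_week])
  phage_fold <- unname(phage_series[pw == pp] /
                         phage_series[pw == phage_baseline_week])
  decline <- unname(host_series[hw == hp] / host_series[hw == pp])
  lag <- pp - hp
  ktw <- lag > 0 && phage_fold >= min_phage_fold &&
    decline >= min_host_decline_fold
  structure(data.frame(host_peak_week = hp, phage_peak_week = pp,
                       lag_weeks = lag, host_fold_rise = host_fold,
                       phage_fold_rise = phage_fold,
                       host_decline_after_phage_rise = decline,
                       ktw_flag = ktw),
            class = c("bloom_report", "data.frame"))
}
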