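test_that("zero-noise pathway generation realizes its archetypes exactly", {
  design <- default_design()
  sim <- simulate_pathway_tables(
    design, n_constant = 3, n_responsive = 2,
    archetype_const = archetype_constant(noise_sd = 0),
    archetype_resp = archetype_oscillating(noise_sd = 0),
    baseline_abundance = 1, seed = 5)
  poll <- arm_series(design, "polluted")
  m <- unclass(sim$abundance)[, poll$sample_id]
  # constant pathways are exactly flat
  expect_true(all(m["path001", ] == 1))
  # oscillating pathway: cumulative 2^(3,-3,1,0,0) walk from 1
  expect_equal(unname(m["path004", ]), c(1, 8, 1, 2, 2, 2))
  # its V vector downstream is exactly the planted shifts
  v <- variation_scores(m[4L, , drop = FALSE])
  expect_equal(unname(v[1L, ]), c(3, -3, 1, 0, 0))
  # control arm carries no planted response
  ctrl <- arm_series(design, "control")
  expect_true(all(unclass(sim$abundance)[, ctrl$sample_id] == 1))
})

test_that("generators are pure functions of parameters and seed", {
  a <- simulate_pathway_tables(seed = 7)
  b <- simulate_pathway_tables(seed = 7)
  expect_identical(a, b)
  c <- simulate_pathway_tables(seed = 8)
  expect_false(identical(unclass(a$abundance), unclass(c$abundance)))
  expect_identical(simulate_phage_bloom(seed = 3, noise = TRUE),
                   simulate_phage_bloom(seed = 3, noise = TRUE))
  expect_identical(make_filter_fixture(seed = 2),
                   make_filter_fixture(seed = 2))
})

test_that("archetypes must define shifts for every sampled week", {
  bad <- pathway_archetype("short", c(`1` = 0, `3` = 0), noise_sd = 0)
  expect_error(
    simulate_pathway_tables(archetype_const = bad, archetype_resp = bad),
    "no shift for week")
  expect_error(pathway_archetype("x", c(`1` = 0), noise_sd = -1),
               "noise_sd")
})

test_that("marker-count generation inverts through the estimator", {
  design <- default_design()
  cat <- ko_catalog(lengths = c(m1 = 300, m2 = 600))
  markers <- marker_set(c("m1", "m2"))
  truth <- stats::setNames(rep(2, 11), design$sample_id)
  sim <- simulate_marker_and_ko_counts(design, cat, markers, truth,
                                       noise = FALSE)
  # expected count = truth x length
  expect_equal(unname(unclass(sim$counts)["m1", "0"]), 600)
  ge <- estimate_genome_equivalents(sim$counts, markers, cat)
  expect_equal(unname(ge), rep(2, 11), tolerance = 1e-12)
  expect_error(
    simulate_marker_and_ko_counts(design, cat, marker_set("nope"), truth),
    "missing from catalog")
})

test_that("Poisson marker counts recover planted truth within 3 SE", {
  # Monte-Carlo oracle: estimate = mean_g Pois(truth*L)/L over 36 markers
  # of length 300; var(single estimate) = truth/(36*300), 200 replicates.
  design <- sample_design("s1", "baseline", 0)
  lens <- stats::setNames(rep(300, 36), paste0("g", 1:36))
  cat <- ko_catalog(lengths = lens)
  markers <- marker_set(names(lens))
  truth <- c(s1 = 1.0)
  est <- vapply(1:200, function(i) {
    sim <- simulate_marker_and_ko_counts(design, cat, markers, truth,
                                         seed = i, noise = TRUE)
    unname(estimate_genome_equivalents(sim$counts, markers, cat))
  }, numeric(1))
  se <- sqrt(1 / (36 * 300) / 200)
  expect_lt(abs(mean(est) - 1.0), 3 * se)
})

test_that("phage-bloom series peak where planted, control stays flat", {
  design <- default_design()
  sim <- simulate_phage_bloom(design, bloom_spec(), baseline_hits = 100)
  poll <- arm_series(design, "polluted")
  host <- unclass(sim$host)[1L, poll$sample_id]
  phage <- unclass(sim$phage)[1L, poll$sample_id]
  expect_equal(poll$week[which.max(host)], 1)
  expect_equal(poll$week[which.max(phage)], 6)
  expect_equal(unname(max(host) / host[1L]), 23)
  expect_equal(unname(max(phage) / phage[1L]), 17000)
  ctrl <- arm_series(design, "control")$sample_id
  expect_true(all(unclass(sim$host)[1L, ctrl] == 100))
  expect_true(all(unclass(sim$phage)[1L, ctrl] == 100))
  # unit folds give flat series everywhere
  flat <- simulate_phage_bloom(design, bloom_spec(host_fold = 1,
                                                  phage_fold = 1))
  expect_true(all(unclass(flat$host) == 100))
  expect_true(all(unclass(flat$phage) == 100))
})

test_that("filter fixture plants the requested pass/fail composition", {
  fx <- make_filter_fixture(160, 8, 4, 2, seed = 1)
  expect_equal(nrow(fx$abundance), 160L)
  expect_equal(sum(!fx$prokaryote_flags), 8L)
  expect_equal(sum(fx$truth$category == "below_cutoff"), 4L)
  expect_equal(sum(apply(unclass(fx$abundance), 1, min) == 0), 2L)
  kept <- filter_pathways(fx$abundance, fx$prokaryote_flags)
  expect_setequal(rownames(kept),
                  fx$truth$pathway_id[fx$truth$category == "pass"])
  expect_equal(nrow(filter_pathways(make_filter_fixture(10, 0, 0, 0)$abundance,
                                    make_filter_fixture(10, 0, 0, 0)$prokaryote_flags)),
               10L)
  fx0 <- make_filter_fixture(10, 10, 0, 0)
  expect_equal(nrow(filter_pathways(fx0$abundance, fx0$prokaryote_flags)), 0L)
  expect_error(make_filter_fixture(10, 6, 3, 2), "exceed")
})

test_that("simulated bit-score summaries realize S = similarity x self", {
  design <- default_design()
  n <- nrow(design)
  self <- stats::setNames(rep(100, n), design$sample_id)
  sim <- diag(n); dimnames(sim) <- list(design$sample_id, design$sample_id)
  sim[sim == 0] <- 0.5
  S <- simulate_blast_summaries(design, self, sim)
  expect_equal(length(S), 121L)
  expect_equal(S["0", "1C"], 50)
  d2 <- d2_matrix(S)
  expect_equal(unname(d2["0", "1C"]), 0.5)
  # identical pools -> D2 = 0; disjoint pools -> D2 = 1
  sim1 <- sim; sim1[] <- 1
  expect_true(all(d2_matrix(simulate_blast_summaries(design, self, sim1)) == 0))
  sim0 <- diag(n); dimnames(sim0) <- dimnames(sim)
  d0 <- d2_matrix(simulate_blast_summaries(design, self, sim0))
  expect_true(all(d0[upper.tri(d0)] == 1))
  bad <- sim; bad[1, 2] <- 0.9
  expect_error(simulate_blast_summaries(design, self, bad), "symmetric")
})
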