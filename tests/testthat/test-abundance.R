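test_that("length normalization divides counts by feature length", {
  x <- count_table(matrix(c(50L, 0L), 2, 1,
                          dimnames = list(c("a", "b"), "s1")), "ko")
  ab <- length_normalize(x, c(a = 500, b = 300))
  expect_equal(unname(unclass(ab)[, 1]), c(0.1, 0))
  expect_error(length_normalize(x, c(a = 500)), "no length for feature 'b'")
  expect_error(length_normalize(x, c(a = 500, b = 0)),
               "non-positive length")
})

test_that("genome equivalents are the mean marker abundance over the full set", {
  mk <- marker_set(c("g1", "g2"))
  cat <- ko_catalog(lengths = c(g1 = 300, g2 = 600))
  tab <- count_table(matrix(c(30L, 120L), 2, 1,
                            dimnames = list(c("g1", "g2"), "s1")), "ko")
  expect_equal(unname(estimate_genome_equivalents(tab, mk, cat)), 0.15)
  # a marker with zero reads still counts in the divisor
  tab2 <- count_table(matrix(c(30L, 0L), 2, 1,
                             dimnames = list(c("g1", "g2"), "s1")), "ko")
  expect_equal(unname(estimate_genome_equivalents(tab2, mk, cat)), 0.05)
  # a marker entirely absent from the table behaves like zero reads
  tab3 <- count_table(matrix(30L, 1, 1, dimnames = list("g1", "s1")), "ko")
  expect_equal(unname(estimate_genome_equivalents(tab3, mk, cat)), 0.05)
  # abundance 1 for every marker -> exactly 1 genome equivalent
  tab4 <- count_table(matrix(c(300L, 600L), 2, 1,
                             dimnames = list(c("g1", "g2"), "s1")), "ko")
  expect_equal(unname(estimate_genome_equivalents(tab4, mk, cat)), 1.0)
  zero <- count_table(matrix(c(0L, 0L), 2, 1,
                             dimnames = list(c("g1", "g2"), "s1")), "ko")
  expect_error(estimate_genome_equivalents(zero, mk, cat), "zero")
})

test_that("pathway aggregation sums member KOs, sharing multi-pathway KOs", {
  cat <- toy_catalog()
  ab <- abundance_table(matrix(c(0.1, 0.2, 0.05), 3, 1,
                               dimnames = list(c("KOa", "KOb", "KOc"), "s1")),
                        "ko")
  pw <- pathway_abundance(ab, cat)
  expect_equal(unclass(pw)["pwX", 1], 0.3)          # KOa + KOb
  expect_equal(unclass(pw)["pwY", 1], 0.25)         # KOb + KOc (shared KOb)
  expect_equal(unclass(pw)["pwZ", 1], 0)            # no observed member
  rownames(ab)[1] <- "KOmissing"
  expect_error(pathway_abundance(ab, cat), "absent from catalog")
})

test_that("per-genome normalization divides by the sample estimate", {
  ab <- abundance_table(matrix(0.3, 1, 1, dimnames = list("p", "s1")),
                        "pathway")
  expect_equal(unclass(normalize_per_genome(ab, c(s1 = 0.15)))[1, 1], 2.0)
  expect_equal(unclass(normalize_per_genome(ab, c(s1 = 1)))[1, 1], 0.3)
  expect_error(normalize_per_genome(ab, c(s1 = 0)), "positive")
  expect_error(normalize_per_genome(ab, c(other = 1)), "s1")
})

test_that("doubling sequencing depth leaves per-genome abundances invariant", {
  mk <- marker_set(c("g1", "g2"))
  cat <- ko_catalog(lengths = c(g1 = 300, g2 = 600, KOa = 500),
                    pathways = list(g1 = character(), g2 = character(),
                                    KOa = "pwX"),
                    prokaryote = c(pwX = TRUE))
  counts <- count_table(
    matrix(c(30L, 120L, 50L, 60L, 240L, 100L), 3, 2,
           dimnames = list(c("g1", "g2", "KOa"), c("s1", "s2"))), "ko")
  norm <- function(ct) {
    ge <- estimate_genome_equivalents(ct, mk, cat)
    normalize_per_genome(length_normalize(ct, cat$lengths), ge)
  }
  base <- norm(counts)
  doubled <- norm(count_table(unclass(counts) * 2L, "ko"))
  expect_equal(unclass(doubled)[, ], unclass(base)[, ], tolerance = 1e-12)
})

test_that("pathway aggregation is additive over split KO counts", {
  cat <- toy_catalog()
  ab <- abundance_table(matrix(c(0.1, 0.2), 2, 1,
                               dimnames = list(c("KOa", "KOb"), "s1")), "ko")
  whole <- pathway_abundance(ab, cat)
  half <- abundance_table(matrix(c(0.05, 0.05, 0.2), 3, 1,
                                 dimnames = list(c("KOa", "KOa2", "KOb"), "s1")),
                          "ko")
  cat2 <- cat
  cat2$pathways$KOa2 <- cat$pathways$KOa
  cat2$lengths <- c(cat$lengths, KOa2 = 500)
  split <- pathway_abundance(half, cat2)
  expect_equal(unclass(split)["pwX", ], unclass(whole)["pwX", ])
})

test_that("normalization chain matches a naive double-loop oracle on 5x5", {
  withr::local_seed(11)
  feats <- c("g1", "g2", "k1", "k2", "k3")
  samples <- paste0("s", 1:5)
  counts <- matrix(sample(10:500, 25), 5, 5,
                   dimnames = list(feats, samples))
  lengths <- c(g1 = 300, g2 = 600, k1 = 100, k2 = 250, k3 = 400)
  mk <- marker_set(c("g1", "g2"))
  cat <- ko_catalog(lengths = lengths)
  ct <- count_table(counts, "ko")
  ge <- estimate_genome_equivalents(ct, mk, cat)
  got <- normalize_per_genome(length_normalize(ct, lengths), ge)
  want <- normalize_oracle(counts, as.list(lengths), mk,
                           as.list(lengths[c("g1", "g2")]))
  expect_equal(unclass(got)[, ], want, tolerance = 1e-12)
})

test_that("KO catalog IO round-trips lengths, memberships and flags", {
  ko_path <- withr::local_tempfile(fileext = ".tsv")
  fl_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("ko_id\tmedian_length\tpathway_ids",
               "KOa\t500\tpwX", "KOb\t300\tpwX,pwY", "KOd\t200\t"), ko_path)
  writeLines(c("pathway_id\tprokaryote_flag",
               "pwX\tTRUE", "pwY\tFALSE"), fl_path)
  cat <- read_ko_catalog(ko_path, fl_path)
  expect_equal(cat$lengths[["KOb"]], 300)
  expect_equal(cat$pathways$KOb, c("pwX", "pwY"))
  expect_equal(cat$pathways$KOd, character(0))
  expect_false(cat$prokaryote[["pwY"]])
  expect_error(ko_catalog(c(KOa = 0)), "non-positive")
})
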