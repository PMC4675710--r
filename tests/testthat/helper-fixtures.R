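# Shared fixtures and independent oracles for the test suite.

toy_counts <- function() {
  count_table(matrix(c(2L, 3L, 5L, 0L, 1L, 4L), nrow = 3,
                     dimnames = list(c("f1", "f2", "f3"), c("s1", "s2"))),
              "otu")
}

toy_catalog <- function() {
  ko_catalog(
    lengths = c(KOa = 500, KOb = 300, KOc = 600, KOd = 200),
    pathways = list(KOa = c("pwX"), KOb = c("pwX", "pwY"),
                    KOc = c("pwY"), KOd = character()),
    prokaryote = c(pwX = TRUE, pwY = TRUE, pwZ = TRUE))
}

toy_hits <- function() {
  blast_hits(
    query_id   = c("r1", "r1", "r2", "r2", "r3"),
    subject_id = c("sA", "sB", "sA", "sC", "sB"),
    identity   = c(75, 95, 70, 69.9, 80),
    bitscore   = c(45, 60, 40, 100, 39.9),
    evalue     = 1e-10)
}

# Brute-force Calinski-Harabasz oracle: explicit double loops over the
# within/between sums of squares, no shared code with ch_index().
ch_oracle <- function(pts, labels) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  k <- length(unique(labels))
  gm <- colMeans(pts)
  W <- 0; B <- 0
  for (g in unique(labels)) {
    sub <- pts[labels == g, , drop = FALSE]
    cm <- colMeans(sub)
    for (i in seq_len(nrow(sub))) W <- W + sum((sub[i, ] - cm)^2)
    B <- B + nrow(sub) * sum((cm - gm)^2)
  }
  if (W == 0) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

# Naive per-element normalization oracle: explicit loops, recomputes
# length + genome-equivalent normalization one cell at a time.
normalize_oracle <- function(counts, lengths, markers, marker_lengths) {
  ge <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    acc <- 0
    for (g in markers) {
      cnt <- if (g %in% rownames(counts)) counts[g, j] else 0
      acc <- acc + cnt / marker_lengths[[g]]
    }
    ge[j] <- acc / length(markers)
  }
  out <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  for (i in seq_len(nrow(counts)))
    for (j in seq_len(ncol(counts)))
      out[i, j] <- counts[i, j] / lengths[[rownames(counts)[i]]] / ge[j]
  out
}

# Brute-force best-hit oracle: enumerate all hits per query.
best_hit_oracle <- function(hits) {
  out <- NULL
  for (q in sort(unique(hits$query_id))) {
    h <- hits[hits$query_id == q, , drop = FALSE]
    top <- h[h$bitscore == max(h$bitscore), , drop = FALSE]
    win <- top[order(top$subject_id)[1L], ]
    out <- rbind(out, data.frame(query_id = q, feature_id = win$subject_id,
                                 bitscore = win$bitscore))
  }
  out
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
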