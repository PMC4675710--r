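#' Summarize all-against-all best-hit bit scores
#'
#' For every ordered pair of samples (A, B), S(A -> B) is the sum over
#' A's reads of the best (maximal) bit score of that read against B's
#' read set, after discarding hits with e-value above `max_evalue`;
#' reads with no surviving hit contribute 0. With n samples the full
#' comparison comprises n x n ordered pairs (self-comparisons included).
#'
#' @param pair_hits named list of [blast_hits()] data.frames; element
#'   `"A|B"` holds the hits of A's reads against B.
#' @param samples character vector of sample ids; every ordered pair must
#'   be present in `pair_hits`.
#' @param max_evalue e-value cutoff applied before summation
#'   (default 0.01).
#' @return square numeric matrix S with `S[A, B] = S(A -> B)`.
#' @export
summarize_bitscores <- function(pair_hits, samples, max_evalue = 0.01) {
  S <- matrix(NA_real_, length(samples), length(samples),
              dimnames = list(samples, samples))
  for (a in samples) {
    for (b in samples) {
      key <- paste(a, b, sep = "|")
      if (!key %in% names(pair_hits))
        stop("missing hits for ordered pair ", key)
      h <- pair_hits[[key]]
      h <- h[h$evalue <= max_evalue, , drop = FALSE]
      S[a, b] <- if (nrow(h) == 0L) 0
                 else sum(tapply(h$bitscore, h$query_id, max))
    }
  }
  S
}

#' Read a precomputed bit-score summary from TSV
#'
#' Columns `sample_a`, `sample_b`, `score`: one row per ordered pair.
#'
#' @param path TSV path.
#' @return square matrix S over the samples found in the file.
#' @export
read_bitscore_summary <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_a", "sample_b", "score")
  if (!all(need %in% colnames(df)))
    stop("summary must have columns: ", paste(need, collapse = ", "))
  samples <- unique(c(df$sample_a, df$sample_b))
  S <- matrix(NA_real_, length(samples), length(samples),
              dimnames = list(samples, samples))
  S[cbind(df$sample_a, df$sample_b)] <- df$score
  S
}

#' D2 gene-pool distance matrix from bit-score summaries
#'
#' `D2(A, B) = 1 - (S(A->B) + S(B->A)) / (S(A->A) + S(B->B))`, clamped
#' to \[0, 1\]: 0 for identical gene pools, 1 for pools sharing no
#' similar sequence. Normalizing by the self-comparison scores removes
#' sample-size effects.
#'
#' @param S square matrix of ordered-pair best-hit bit-score sums; the
#'   diagonal (self-scores) must be positive and no entry missing.
#' @return symmetric D2 matrix with zero diagonal, entries in \[0, 1\].
#' @export
d2_matrix <- function(S) {
  if (nrow(S) != ncol(S) || !identical(rownames(S), colnames(S)))
    stop("S must be square with matching sample names")
  if (any(is.na(S))) {
    bad <- which(is.na(S), arr.ind = TRUE)[1L, ]
    stop("missing ordered pair ", rownames(S)[bad[1L]], " -> ",
         colnames(S)[bad[2L]])
  }
  self <- diag(S)
  zero <- rownames(S)[self <= 0]
  if (length(zero) > 0L)
    stop("non-positive self-score for sample '", zero[1L], "'")
  d2 <- 1 - (S + t(S)) / outer(self, self, "+")
  d2 <- pmin(pmax(d2, 0), 1)  # clamp: heuristic cross-scores can exceed self
  diag(d2) <- 0
  d2
}

#' Complete-linkage clustering of gene pools by D2
#'
#' @param d2 D2 matrix from [d2_matrix()].
#' @param k optional cut count.
#' @return as [hclust_complete()].
#' @export
cluster_genepools <- function(d2, k = NULL) {
  hclust_complete(d2, k = k)
}
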