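#' Column-wise relative abundances
#'
#' Converts counts (or abundances) to per-sample proportions; every
#' sample column of the result sums to 1.
#'
#' @param counts features x samples matrix with dimnames.
#' @return numeric matrix of proportions, same dimnames.
#' @export
relative_abundance <- function(counts) {
  m <- unclass(as.matrix(counts))
  cs <- colSums(m)
  zero <- colnames(m)[cs <= 0]
  if (length(zero) > 0L)
    stop("sample '", zero[1L], "' has zero total count")
  sweep(m, 2L, cs, "/")
}

#' Shannon-Wiener diversity per sample
#'
#' H' = -sum p_i ln p_i over the features with p_i > 0, in natural-log
#' units (the Shannon-Wiener convention).
#'
#' @param proportions features x samples matrix of proportions (each
#'   column sums to 1), or a single proportion vector.
#' @return named numeric vector of H' per sample.
#' @export
shannon_index <- function(proportions) {
  p <- as.matrix(proportions)
  if (any(p < 0)) stop("proportions must be non-negative")
  off <- which(abs(colSums(p) - 1) > 1e-6)
  if (length(off) > 0L)
    stop("column ", off[1L], " does not sum to 1")
  h <- vegan::diversity(t(p), index = "shannon")
  stats::setNames(as.numeric(h), colnames(p))
}

#' Pairwise 1 - Pearson correlation distances between samples
#'
#' d(A, B) = 1 - r(A, B) over the feature abundances of the two sample
#' columns; the result is symmetric with zero diagonal and entries in
#' \[0, 2\].
#'
#' @param table features x samples matrix (counts, abundances or
#'   proportions).
#' @return square symmetric distance matrix over samples.
#' @export
correlation_distance <- function(table) {
  m <- unclass(as.matrix(table))
  sds <- apply(m, 2L, stats::sd)
  flat <- colnames(m)[sds == 0]
  if (length(flat) > 0L)
    stop("sample '", flat[1L], "' has a constant profile; ",
         "correlation is undefined")
  d <- 1 - stats::cor(m)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

#' Complete-linkage hierarchical clustering of a distance matrix
#'
#' @param dist square symmetric distance matrix (or `dist` object).
#' @param k optional number of groups to cut the tree into.
#' @return list with `tree` (an `hclust`) and, when `k` is given,
#'   `labels` (named integer vector from [stats::cutree()]).
#' @export
hclust_complete <- function(dist, k = NULL) {
  d <- if (inherits(dist, "dist")) dist else stats::as.dist(dist)
  n <- attr(d, "Size")
  tree <- stats::hclust(d, method = "complete")
  out <- list(tree = tree)
  if (!is.null(k)) {
    if (k > n) stop("cannot cut ", n, " leaves into ", k, " groups")
    out$labels <- stats::cutree(tree, k = k)
  }
  out
}

#' Export a dendrogram as Newick text
#' @param tree an `hclust` object.
#' @return single Newick string (also usable with [ape::read.tree()]).
#' @export
as_newick <- function(tree) {
  ape::write.tree(ape::as.phylo(tree))
}

#' Co-occurrence clustering of abundant genus time profiles
#'
#' Ranks genera by their maximum (default) or mean relative abundance
#' across the samples, takes the top N, and clusters their time profiles
#' by 1 - Pearson correlation distance with complete linkage, cut into k
#' groups — genera that rise and fall together share a cluster.
#'
#' @param rel_abund genus x samples matrix of relative abundances whose
#'   columns are time-ordered.
#' @param top_n number of most abundant genera to keep (default 30).
#' @param k number of co-occurrence clusters (default 4).
#' @param rank_by `"max"` (captures transient bloomers) or `"mean"`.
#' @return named integer vector genus -> cluster label.
#' @export
cooccurrence_clusters <- function(rel_abund, top_n = 30, k = 4,
                                  rank_by = c("max", "mean")) {
  rank_by <- match.arg(rank_by)
  m <- unclass(as.matrix(rel_abund))
  score <- if (rank_by == "max") apply(m, 1L, max) else rowMeans(m)
  top_n <- min(top_n, nrow(m))
  if (top_n < k) stop("top_n must be >= k")
  top <- m[order(-score)[seq_len(top_n)], , drop = FALSE]
  if (k == 1L)
    return(stats::setNames(rep(1L, nrow(top)), rownames(top)))
  d <- correlation_distance(t(top))  # distance between genus profiles
  hclust_complete(d, k = k)$labels
}
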