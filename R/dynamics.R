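#' Filter pathways before variation-profile analysis
#'
#' Removes pathways that (i) do not occur in prokaryotes, (ii) never
#' reach the normalized abundance cutoff at any time point, or (iii)
#' have zero abundance in any analysed sample (log2 ratios would be
#' undefined).
#'
#' @param table pathway [abundance_table()] (normalized).
#' @param prokaryote_flags named logical vector pathway -> flag; must
#'   cover every row of `table`.
#' @param cutoff minimal maximum abundance (default 1e-4).
#' @return the retained rows, same class.
#' @export
filter_pathways <- function(table, prokaryote_flags, cutoff = 1e-4) {
  pw <- rownames(table)
  miss <- setdiff(pw, names(prokaryote_flags))
  if (length(miss) > 0L)
    stop("no prokaryote flag for pathway '", miss[1L], "'")
  m <- unclass(table)
  keep <- prokaryote_flags[pw] &
    apply(m, 1L, max) >= cutoff &
    apply(m, 1L, function(r) all(r > 0))
  mc_log("filter_pathways: %d/%d retained (cutoff %g)",
         sum(keep), length(keep), cutoff)
  out <- m[keep, , drop = FALSE]
  abundance_table(out, "pathway")
}

#' Per-pathway variation scores V_p(t)
#'
#' For each pathway p the score at time point t is
#' `log2(K_p(t) / K_p(t-1))`, where t-1 is the previous sampled time
#' point regardless of the spacing in weeks: a series over T time points
#' yields T-1 scores per pathway.
#'
#' @param table filtered pathway [abundance_table()] whose columns are a
#'   time-ordered series (baseline first); all entries must be > 0.
#' @param weeks optional numeric vector of sampled weeks (same length as
#'   columns) used only to label the score columns.
#' @return numeric matrix pathways x (T-1) of variation scores; column
#'   `V_w` is the change into week w.
#' @export
variation_scores <- function(table, weeks = NULL) {
  m <- unclass(table)
  if (ncol(m) < 2L) stop("need at least two time points")
  if (any(m <= 0))
    stop("zero abundance encountered; run filter_pathways() first")
  v <- log2(m[, -1L, drop = FALSE] / m[, -ncol(m), drop = FALSE])
  if (!is.null(weeks)) {
    if (length(weeks) != ncol(m))
      stop("weeks must match the number of time points")
    colnames(v) <- paste0("V_", weeks[-1L])
  }
  v
}

#' Calinski-Harabasz index of a clustering
#'
#' CH = \[B/(k-1)\] / \[W/(n-k)\], where B and W are the between- and
#' within-cluster sums of squared Euclidean distances to the respective
#' means. Returns `Inf` when the within-cluster scatter is exactly zero.
#'
#' @param points numeric matrix (rows = observations) or vector.
#' @param labels cluster assignment, one label per row; k >= 2 clusters,
#'   each non-empty, and n > k.
#' @return the CH index (a non-negative real, possibly `Inf`).
#' @export
ch_index <- function(points, labels) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (length(labels) != n) stop("one label per observation required")
  cl <- split(seq_len(n), labels)
  k <- length(cl)
  if (k < 2L) stop("CH index requires k >= 2 clusters")
  if (n <= k) stop("CH index requires n > k")
  grand <- colMeans(points)
  W <- 0; B <- 0
  for (idx in cl) {
    centroid <- colMeans(points[idx, , drop = FALSE])
    W <- W + sum(sweep(points[idx, , drop = FALSE], 2L, centroid)^2)
    B <- B + length(idx) * sum((centroid - grand)^2)
  }
  if (W == 0) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

#' Cluster variation profiles by k-means with CH model selection
#'
#' Runs Euclidean k-means (best of `restarts` random starts) on the
#' pathway variation-score vectors for every k in `k_range`, scores each
#' solution with the Calinski-Harabasz index and selects the k with the
#' highest CH (ties to the smallest k). Values of k exceeding the number
#' of distinct profiles are skipped. Deterministic given `seed`.
#'
#' @param profiles numeric matrix pathways x scores (from
#'   [variation_scores()]).
#' @param k_range integer vector of candidate cluster counts
#'   (default `2:10`).
#' @param restarts number of random starts per k (default 100).
#' @param seed RNG seed.
#' @return list of class `pathway_clustering`: `k_selected`, `labels`
#'   (named integer vector), `ch_scores` (named by k), `centroids`
#'   (k_selected x scores matrix), `sizes`.
#' @export
cluster_variation_profiles <- function(profiles, k_range = 2:10,
                                       restarts = 100, seed = 1) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  n_distinct <- nrow(unique(profiles))
  ks <- k_range[k_range >= 2 & k_range < n & k_range <= n_distinct]
  if (length(ks) == 0L)
    stop("no feasible k in k_range for ", n, " profiles (",
         n_distinct, " distinct)")
  fits <- vector("list", length(ks))
  ch <- stats::setNames(rep(NA_real_, length(ks)), ks)
  withr::with_seed(seed, {
    for (i in seq_along(ks)) {
      fits[[i]] <- stats::kmeans(profiles, centers = ks[i],
                                 nstart = restarts, iter.max = 100L)
      ch[i] <- ch_index(profiles, fits[[i]]$cluster)
    }
  })
  best <- which.max(ch)  # ties resolve to the smallest k
  fit <- fits[[best]]
  labels <- fit$cluster
  names(labels) <- rownames(profiles)
  mc_log("cluster_variation_profiles: k = %d selected (CH = %g)",
         ks[best], ch[best])
  structure(list(k_selected = ks[best],
                 labels = labels,
                 ch_scores = ch,
                 centroids = fit$centers,
                 sizes = fit$size),
            class = "pathway_clustering")
}

#' @export
print.pathway_clustering <- function(x, ...) {
  cat(sprintf("pathway clustering: k = %d (CH-selected), sizes %s\n",
              x$k_selected, paste(x$sizes, collapse = "/")))
  invisible(x)
}

#' Label clusters as constant or responsive
#'
#' The cluster whose centroid has the smallest Euclidean norm (variation
#' scores closest to zero throughout) is labelled `constant`; all others
#' `responsive`. Ties go to the lowest cluster index.
#'
#' @param result a `pathway_clustering` from
#'   [cluster_variation_profiles()].
#' @return character vector, one label per cluster index.
#' @export
label_clusters <- function(result) {
  norms <- sqrt(rowSums(result$centroids^2))
  lab <- rep("responsive", nrow(result$centroids))
  lab[which.min(norms)] <- "constant"
  names(lab) <- rownames(result$centroids)
  lab
}

#' Write clustering results as TSV
#'
#' Writes a `(pathway, cluster, label)` table and a `(k, ch)` table of
#' the model-selection trace.
#'
#' @param result a `pathway_clustering`.
#' @param members_path,ch_path output paths.
#' @return `members_path`, invisibly.
#' @export
write_clustering <- function(result, members_path, ch_path) {
  lab <- label_clusters(result)
  utils::write.table(
    data.frame(pathway = names(result$labels),
               cluster = unname(result$labels),
               label = lab[result$labels]),
    members_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(k = as.integer(names(result$ch_scores)),
               ch = unname(result$ch_scores)),
    ch_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(members_path)
}
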