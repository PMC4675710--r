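#' Threshold-filter BLAST hits
#'
#' Keeps hits with identity >= `min_identity` and bit score >=
#' `min_bitscore` (both boundaries inclusive); input order is preserved
#' and the operation is idempotent.
#'
#' @param hits a [blast_hits()] data.frame.
#' @param min_identity percent identity threshold (default 70).
#' @param min_bitscore bit-score threshold (default 40).
#' @return the retained hits.
#' @export
filter_hits <- function(hits, min_identity = 70, min_bitscore = 40) {
  stopifnot(is.finite(min_identity), is.finite(min_bitscore))
  keep <- hits$identity >= min_identity & hits$bitscore >= min_bitscore
  out <- hits[keep, , drop = FALSE]
  mc_log("filter_hits: %d/%d retained (identity >= %g, bitscore >= %g)",
         nrow(out), nrow(hits), min_identity, min_bitscore)
  out
}

#' Best-hit assignment per query
#'
#' Assigns each query to the subject of its highest-bit-score hit.
#' Ties on bit score are broken to the lexicographically smallest
#' subject id so assignment is deterministic.
#'
#' @param hits a [blast_hits()] data.frame, already threshold-filtered.
#' @return data.frame with one row per query: `query_id`, `feature_id`
#'   (the winning subject), `bitscore`.
#' @export
best_hit <- function(hits) {
  if (nrow(hits) == 0L)
    return(data.frame(query_id = character(), feature_id = character(),
                      bitscore = numeric(), stringsAsFactors = FALSE))
  o <- order(hits$query_id, -hits$bitscore, hits$subject_id,
             method = "radix")
  h <- hits[o, , drop = FALSE]
  first <- !duplicated(h$query_id)
  data.frame(query_id = h$query_id[first],
             feature_id = h$subject_id[first],
             bitscore = h$bitscore[first],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Confirm candidate assignments against a comprehensive database
#'
#' Two-stage assignment: a candidate (a best hit against the curated
#' in-house DB) is kept only if the same query's best hit against the
#' comprehensive DB is itself a member of the in-house sequence set.
#' Queries with no comprehensive-DB hit at all are retained — the
#' in-house hit is then trivially the best known hit.
#'
#' @param candidates data.frame as returned by [best_hit()] (queries vs
#'   the in-house DB).
#' @param nr_hits a [blast_hits()] data.frame of the same queries against
#'   the comprehensive DB, threshold-filtered with the same cutoffs.
#' @param inhouse_ids character vector of in-house sequence ids.
#' @return the retained subset of `candidates`.
#' @export
confirm_inhouse <- function(candidates, nr_hits, inhouse_ids) {
  nr_best <- best_hit(nr_hits)
  best_subj <- stats::setNames(nr_best$feature_id, nr_best$query_id)
  has_nr <- candidates$query_id %in% names(best_subj)
  keep <- !has_nr |
    best_subj[candidates$query_id] %in% inhouse_ids
  out <- candidates[keep, , drop = FALSE]
  mc_log("confirm_inhouse: %d/%d candidates confirmed",
         nrow(out), nrow(candidates))
  out
}

#' Select reference sequences for in-house DB construction
#'
#' A subject qualifies when at least one hit reaches identity >= 90 with
#' both query and subject coverage >= 70 (defaults; all inclusive).
#'
#' @param hits a [blast_hits()] data.frame carrying `qcov` and `scov`.
#' @param min_identity,min_qcov,min_scov thresholds (percent).
#' @return character vector of unique qualifying subject ids.
#' @export
db_build_filter <- function(hits, min_identity = 90, min_qcov = 70,
                            min_scov = 70) {
  nocov <- which(is.na(hits$qcov) | is.na(hits$scov))
  if (length(nocov) > 0L)
    stop("hit '", hits$query_id[nocov[1L]], "' vs '",
         hits$subject_id[nocov[1L]], "' lacks coverage fields")
  keep <- hits$identity >= min_identity & hits$qcov >= min_qcov &
    hits$scov >= min_scov
  unique(hits$subject_id[keep])
}

#' Write assignments as a two-column TSV
#' @param assignments data.frame from [best_hit()]/[confirm_inhouse()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  utils::write.table(assignments[, c("query_id", "feature_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
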