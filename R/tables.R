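#' Sample design of a time-course microcosm experiment
#'
#' A design describes the samples of a closed-microcosm time course: one
#' baseline sample taken before the disturbance (week 0) and two parallel
#' arms (an undisturbed control and a disturbed/polluted arm) sampled at
#' increasing weeks afterwards.
#'
#' @param sample_id character vector of unique sample labels.
#' @param arm character vector, each element one of `"baseline"`,
#'   `"control"`, `"polluted"`.
#' @param week non-negative integer vector, weeks after the disturbance.
#' @return A `data.frame` of class `sample_design` with columns
#'   `sample_id`, `arm`, `week`.
#' @examples
#' default_design()
#' @export
sample_design <- function(sample_id, arm, week) {
  arm <- match.arg(arm, c("baseline", "control", "polluted"),
                   several.ok = TRUE)
  if (length(sample_id) != length(arm) || length(arm) != length(week))
    stop("sample_id, arm and week must have equal length")
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id: ", sample_id[duplicated(sample_id)][1L])
  if (any(week < 0) || any(week != floor(week)))
    stop("week must be a non-negative integer")
  base <- week[arm == "baseline"]
  if (length(base) > 1L)
    stop("at most one baseline sample is allowed")
  if (length(base) == 1L && base != 0)
    stop("the baseline sample must have week = 0")
  for (a in c("control", "polluted")) {
    w <- week[arm == a]
    if (length(w) > 1L && any(diff(w) <= 0))
      stop("weeks within arm '", a, "' must be strictly increasing")
  }
  structure(data.frame(sample_id = as.character(sample_id),
                       arm = arm, week = as.integer(week),
                       stringsAsFactors = FALSE),
            class = c("sample_design", "data.frame"))
}

#' Default 11-sample microcosm design
#'
#' One shared baseline at week 0 plus control and polluted arms each sampled
#' at weeks 1, 3, 6, 12 and 24 (sample labels `1C`..`24C`, `1M`..`24M`).
#'
#' @return a [sample_design()].
#' @export
default_design <- function() {
  wk <- c(1L, 3L, 6L, 12L, 24L)
  sample_design(
    sample_id = c("0", paste0(wk, "C"), paste0(wk, "M")),
    arm = c("baseline", rep("control", 5L), rep("polluted", 5L)),
    week = c(0L, wk, wk))
}

#' Samples of one arm in time order
#'
#' Returns the baseline sample (if present) followed by the arm's samples
#' ordered by week, so that columns selected with the result form a
#' time-ordered series.
#'
#' @param design a [sample_design()].
#' @param arm `"control"` or `"polluted"`.
#' @return data.frame with columns `sample_id`, `week`, time-ordered.
#' @export
arm_series <- function(design, arm = c("polluted", "control")) {
  arm <- match.arg(arm)
  keep <- design$arm %in% c("baseline", arm)
  out <- design[keep, c("sample_id", "week")]
  out[order(out$week), , drop = FALSE]
}

.feature_kinds <- c("otu", "genus", "ko", "gene", "contig", "pathway")

#' Construct a validated count table
#'
#' A count table is a features x samples matrix of non-negative integer
#' read counts tagged with the kind of feature its rows represent.
#'
#' @param counts numeric matrix with unique rownames (feature ids) and
#'   unique colnames (sample ids); entries must be non-negative integers.
#' @param kind one of `"otu"`, `"genus"`, `"ko"`, `"gene"`, `"contig"`.
#' @return the matrix, classed `count_table`, with a `kind` attribute.
#' @export
count_table <- function(counts, kind) {
  kind <- match.arg(kind, setdiff(.feature_kinds, "pathway"))
  counts <- as.matrix(counts)
  .check_dimnames(counts)
  bad <- which(!is.finite(counts) | counts < 0 |
                 abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("count for feature '", rownames(counts)[bad[1L, 1L]],
         "', sample '", colnames(counts)[bad[1L, 2L]],
         "' is not a non-negative integer")
  structure(counts, kind = kind, class = c("count_table", class(counts)))
}

#' Construct a normalized abundance table
#'
#' Holds non-negative real abundances (e.g. reads per residue per genome
#' equivalent); for `kind = "pathway"` rows carry the pathway abundances
#' K_p(t) consumed by the variation-profile analysis.
#'
#' @param x numeric matrix, non-negative, unique dimnames.
#' @param kind feature kind, one of `r paste(.feature_kinds, collapse = ", ")`.
#' @return the matrix, classed `abundance_table`, with a `kind` attribute.
#' @export
abundance_table <- function(x, kind) {
  kind <- match.arg(kind, .feature_kinds)
  x <- as.matrix(x)
  .check_dimnames(x)
  if (any(!is.finite(x)) || any(x < 0))
    stop("abundances must be finite and non-negative")
  structure(x, kind = kind, class = c("abundance_table", class(x)))
}

.check_dimnames <- function(m) {
  if (nrow(m) == 0L) {
    if (is.null(colnames(m))) stop("matrix must have sample colnames")
    return(invisible(m))
  }
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("matrix must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(m)))
    stop("duplicate feature id: ", rownames(m)[duplicated(rownames(m))][1L])
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample id: ", colnames(m)[duplicated(colnames(m))][1L])
  invisible(m)
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count table [%s]: %d features x %d samples\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance table [%s]: %d features x %d samples\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' Read a feature-by-sample count table from TSV
#'
#' Expects a header row of sample ids, a first column of feature ids and
#' non-negative integer cells. Row and column order are preserved.
#'
#' @param path TSV file path.
#' @param kind feature kind of the rows (see [count_table()]).
#' @return a [count_table()].
#' @export
read_count_table <- function(path, kind) {
  m <- .read_matrix_tsv(path, integer_cells = TRUE)
  count_table(m, kind)
}

#' Read a normalized abundance table from TSV
#' @inheritParams read_count_table
#' @return an [abundance_table()].
#' @export
read_abundance_table <- function(path, kind) {
  m <- .read_matrix_tsv(path, integer_cells = FALSE)
  abundance_table(m, kind)
}

.read_matrix_tsv <- function(path, integer_cells) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, header = TRUE,
                          colClasses = "character", sep = "\t")
  if (ncol(df) < 2L) stop("table must have a feature column and >= 1 sample")
  feat <- df[[1L]]
  samp <- colnames(df)[-1L]
  m <- matrix(NA_real_, nrow(df), length(samp),
              dimnames = list(feat, samp))
  for (j in seq_along(samp)) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(is.na(v) | v < 0 |
                   (integer_cells & abs(v - round(v)) > 1e-8))
    if (length(bad) > 0L)
      stop("malformed cell at feature '", feat[bad[1L]], "', sample '",
           samp[j], "': '", df[[j + 1L]][bad[1L]], "'")
    m[, j] <- v
  }
  m
}

#' Write a count or abundance table as TSV
#'
#' Inverse of [read_count_table()] / [read_abundance_table()]: the first
#' column holds feature ids under the header `feature_id`, remaining
#' columns the samples.
#'
#' @param x matrix with dimnames (count or abundance table).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  df <- data.frame(feature_id = rownames(x), unclass(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Feature kind of a table
#' @param x a count or abundance table.
#' @return the `kind` attribute string.
#' @export
feature_kind <- function(x) attr(x, "kind")
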