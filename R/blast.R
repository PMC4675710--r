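#' Construct a table of BLAST hits
#'
#' Validates the fields the assignment filters rely on: percent identity
#' and (when present) query/subject coverage must lie in [0, 100],
#' alignment lengths must be positive and bit scores non-negative.
#'
#' @param query_id,subject_id character vectors.
#' @param identity percent identity in \[0, 100\].
#' @param aln_length positive integer alignment length.
#' @param bitscore non-negative real.
#' @param evalue non-negative real.
#' @param qcov,scov optional percent query/subject coverage in \[0, 100\]
#'   (`NA` when unknown).
#' @return data.frame of class `blast_hits`.
#' @export
blast_hits <- function(query_id, subject_id, identity, aln_length = 1L,
                       bitscore = 0, evalue = 0, qcov = NA_real_,
                       scov = NA_real_) {
  if (length(query_id) == 0L) {
    df <- data.frame(query_id = character(), subject_id = character(),
                     identity = numeric(), aln_length = integer(),
                     bitscore = numeric(), evalue = numeric(),
                     qcov = numeric(), scov = numeric(),
                     stringsAsFactors = FALSE)
    return(.validate_hits(df))
  }
  df <- data.frame(query_id = as.character(query_id),
                   subject_id = as.character(subject_id),
                   identity = as.numeric(identity),
                   aln_length = as.integer(aln_length),
                   bitscore = as.numeric(bitscore),
                   evalue = as.numeric(evalue),
                   qcov = as.numeric(qcov), scov = as.numeric(scov),
                   stringsAsFactors = FALSE)
  .validate_hits(df)
}

.validate_hits <- function(df) {
  chk <- function(v, lo, hi, what) {
    bad <- which(!is.na(v) & (v < lo | v > hi))
    if (length(bad) > 0L)
      stop(what, " out of [", lo, ", ", hi, "] for query '",
           df$query_id[bad[1L]], "' vs subject '", df$subject_id[bad[1L]], "'")
  }
  chk(df$identity, 0, 100, "identity")
  chk(df$qcov, 0, 100, "query coverage")
  chk(df$scov, 0, 100, "subject coverage")
  if (any(df$bitscore < 0, na.rm = TRUE)) stop("negative bitscore")
  class(df) <- c("blast_hits", "data.frame")
  df
}

#' Read BLAST tabular output (outfmt 6)
#'
#' Parses the 12 canonical tab-separated columns (query, subject,
#' percent identity, alignment length, mismatches, gap opens, qstart,
#' qend, sstart, send, e-value, bit score). Optional 13th/14th columns
#' are kept as query and subject coverage (`qcovs`/`scovs` style).
#'
#' @param path file path.
#' @return a [blast_hits()] data.frame, one row per hit line; zero rows
#'   for an empty file.
#' @export
read_blast_tabular <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(blast_hits(character(), character(), numeric()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 12L))
    stop("line ", which(nf < 12L)[1L],
         ": expected >= 12 tab-separated fields, found ", nf[nf < 12L][1L])
  num <- function(i) as.numeric(vapply(parts, `[`, "", i))
  opt <- function(i) ifelse(nf >= i, suppressWarnings(num(i)), NA_real_)
  blast_hits(query_id   = vapply(parts, `[`, "", 1L),
             subject_id = vapply(parts, `[`, "", 2L),
             identity   = num(3L),
             aln_length = num(4L),
             bitscore   = num(12L),
             evalue     = num(11L),
             qcov       = opt(13L),
             scov       = opt(14L))
}
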