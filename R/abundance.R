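#' KEGG-orthology catalog
#'
#' Per-KO median protein length (amino acids) and pathway memberships,
#' plus a per-pathway prokaryote flag. Lengths divide read counts during
#' length normalization; memberships drive pathway aggregation; the
#' prokaryote flags feed the pathway filter.
#'
#' @param lengths named numeric vector, KO id -> median protein length
#'   (must be > 0).
#' @param pathways named list, KO id -> character vector of pathway ids
#'   (may be empty for KOs outside any pathway).
#' @param prokaryote named logical vector, pathway id -> whether the
#'   pathway occurs in prokaryotes.
#' @return list of class `ko_catalog` with elements `lengths`,
#'   `pathways`, `prokaryote`.
#' @export
ko_catalog <- function(lengths, pathways = list(), prokaryote = logical()) {
  if (is.null(names(lengths)) || anyDuplicated(names(lengths)))
    stop("lengths must be uniquely named by KO id")
  bad <- names(lengths)[!is.finite(lengths) | lengths <= 0]
  if (length(bad) > 0L)
    stop("non-positive median length for KO '", bad[1L], "'")
  if (length(pathways) > 0L && is.null(names(pathways)))
    stop("pathways must be named by KO id")
  structure(list(lengths = lengths,
                 pathways = pathways,
                 prokaryote = prokaryote),
            class = "ko_catalog")
}

#' Read a KO catalog from TSV
#'
#' The KO table has columns `ko_id`, `median_length`,
#' `pathway_ids` (comma-separated, possibly empty). The optional flags
#' table has columns `pathway_id`, `prokaryote_flag` (TRUE/FALSE).
#'
#' @param ko_path path to the KO table.
#' @param flags_path optional path to the pathway flags table.
#' @return a [ko_catalog()].
#' @export
read_ko_catalog <- function(ko_path, flags_path = NULL) {
  df <- utils::read.delim(ko_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("ko_id", "median_length", "pathway_ids")
  if (!all(need %in% colnames(df)))
    stop("KO catalog must have columns: ", paste(need, collapse = ", "))
  lengths <- stats::setNames(as.numeric(df$median_length), df$ko_id)
  pw <- lapply(strsplit(as.character(df$pathway_ids), ",", fixed = TRUE),
               function(x) x[nzchar(x)])
  names(pw) <- df$ko_id
  prok <- logical()
  if (!is.null(flags_path)) {
    fl <- utils::read.delim(flags_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    prok <- stats::setNames(as.logical(fl$prokaryote_flag), fl$pathway_id)
  }
  ko_catalog(lengths, pw, prok)
}

#' Marker gene set for genome-equivalent estimation
#'
#' An ordered set of single-copy marker ids (by convention gyrB plus 35
#' universal single-copy genes, 36 in total) whose mean length-normalized
#' abundance estimates the number of genomes sequenced per sample.
#'
#' @param ids character vector of marker (KO) ids, unique.
#' @return character vector of class `marker_set`.
#' @export
marker_set <- function(ids) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate marker id")
  if (length(ids) < 1L) stop("marker set must not be empty")
  structure(ids, class = "marker_set")
}

#' Default 36-gene marker set (gyrB-added USCGs)
#'
#' gyrB (K02470) plus 35 universal single-copy genes, here represented by
#' ribosomal-protein and aminoacyl-tRNA-ligase KO ids. The identity of
#' the 35 USCGs is a documented placeholder: any set of single-copy KOs
#' present in the catalog may be supplied instead via [marker_set()].
#'
#' @return a [marker_set()] of 36 KO ids.
#' @export
default_marker_set <- function() {
  marker_set(c(
    "K02470",                                        # gyrB
    "K02863", "K02886", "K02906", "K02926", "K02931",  # rplA-E
    "K02933", "K02939", "K02864", "K02867", "K02871",  # rplF,I,J,K,M
    "K02874", "K02876", "K02878", "K02879", "K02881",  # rplN,O,P,Q,R
    "K02884", "K02887", "K02888", "K02890", "K02892",  # rplS,T,U,V,W
    "K02895", "K02899", "K02902", "K02904", "K02907",  # rplX,rpmA-D
    "K02946", "K02948", "K02950", "K02952", "K02956",  # rpsJ,K,L,M,O
    "K02959", "K02961", "K02963", "K02965", "K01866"   # rpsP,Q,R,S; tyrS
  ))
}

#' Length-normalize a count table
#'
#' Divides each feature's read counts by the feature's reference length
#' (median protein length in amino acids for KO/gene features, contig
#' length in bp for contigs), giving reads per residue or per bp.
#'
#' @param counts a [count_table()] (or matrix with dimnames).
#' @param lengths named numeric vector feature id -> positive length.
#' @return an [abundance_table()] of the same kind.
#' @export
length_normalize <- function(counts, lengths) {
  feats <- rownames(counts)
  miss <- setdiff(feats, names(lengths))
  if (length(miss) > 0L)
    stop("no length for feature '", miss[1L], "'")
  len <- lengths[feats]
  bad <- feats[!is.finite(len) | len <= 0]
  if (length(bad) > 0L)
    stop("non-positive length for feature '", bad[1L], "'")
  kind <- attr(counts, "kind")
  if (is.null(kind)) kind <- "gene"
  abundance_table(unclass(counts) / len, kind)
}

#' Estimate per-sample genome equivalents from marker genes
#'
#' For each sample, the genome equivalent is the arithmetic mean over the
#' whole marker set of each marker's length-normalized abundance
#' (count / median length). Markers absent from the count table count as
#' abundance 0 inside the mean: the divisor is always the full set size,
#' so shallow samples are not inflated.
#'
#' @param ko_table a [count_table()] with KO rows.
#' @param markers a [marker_set()]; every id must be in `catalog`.
#' @param catalog a [ko_catalog()] providing marker lengths.
#' @return named numeric vector sample id -> genome equivalents (> 0).
#' @export
estimate_genome_equivalents <- function(ko_table, markers,
                                        catalog = NULL) {
  lengths <- if (inherits(catalog, "ko_catalog")) catalog$lengths
             else catalog
  miss <- setdiff(markers, names(lengths))
  if (length(miss) > 0L)
    stop("marker '", miss[1L], "' missing from catalog")
  m <- matrix(0, length(markers), ncol(ko_table),
              dimnames = list(markers, colnames(ko_table)))
  present <- intersect(markers, rownames(ko_table))
  m[present, ] <- unclass(ko_table)[present, , drop = FALSE]
  ge <- colMeans(m / lengths[markers])
  zero <- names(ge)[ge <= 0]
  if (length(zero) > 0L)
    stop("genome-equivalent estimate is zero for sample '", zero[1L],
         "'; per-genome normalization is impossible")
  mc_log("genome equivalents from %d markers: %s", length(markers),
         paste(signif(ge, 4), collapse = ", "))
  ge
}

#' Aggregate KO abundances into pathway abundances
#'
#' A pathway's abundance is the sum of the abundances of its member KOs;
#' a KO belonging to m pathways contributes to all m sums. Every pathway
#' known to the catalog appears in the output (zero if none of its KOs
#' were observed).
#'
#' @param ko_abund an [abundance_table()] with KO rows.
#' @param catalog a [ko_catalog()]; every KO row must be listed in it.
#' @return an [abundance_table()] with `kind = "pathway"`.
#' @export
pathway_abundance <- function(ko_abund, catalog) {
  kos <- rownames(ko_abund)
  miss <- setdiff(kos, names(catalog$pathways))
  if (length(miss) > 0L)
    stop("KO '", miss[1L], "' absent from catalog")
  all_pw <- unique(c(unlist(catalog$pathways, use.names = FALSE),
                     names(catalog$prokaryote)))
  if (length(all_pw) == 0L) stop("catalog defines no pathways")
  out <- matrix(0, length(all_pw), ncol(ko_abund),
                dimnames = list(all_pw, colnames(ko_abund)))
  for (ko in kos) {
    for (pw in catalog$pathways[[ko]])
      out[pw, ] <- out[pw, ] + unclass(ko_abund)[ko, ]
  }
  abundance_table(out, "pathway")
}

#' Normalize abundances per genome equivalent
#'
#' Divides each sample column by that sample's genome-equivalent estimate,
#' removing sequencing-depth and community-size effects. Applied
#' identically to KO, pathway, degradation-gene and phage-contig tables.
#'
#' @param table an [abundance_table()] (or matrix).
#' @param ge named numeric vector of genome equivalents per sample, all
#'   positive, covering every sample column.
#' @return an [abundance_table()] of the same kind.
#' @export
normalize_per_genome <- function(table, ge) {
  samp <- colnames(table)
  miss <- setdiff(samp, names(ge))
  if (length(miss) > 0L)
    stop("no genome-equivalent estimate for sample '", miss[1L], "'")
  if (any(ge[samp] <= 0) || any(!is.finite(ge[samp])))
    stop("genome equivalents must be positive and finite")
  kind <- attr(table, "kind")
  if (is.null(kind)) kind <- "gene"
  abundance_table(sweep(unclass(table), 2L, ge[samp], "/"), kind)
}
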