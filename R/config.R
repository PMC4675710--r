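#' Default pipeline configuration
#'
#' All thresholds default to the values used throughout the pipeline:
#' read assignment keeps hits with identity >= 70 and bit score >= 40;
#' the in-house reference DB is built from hits with identity >= 90 and
#' query/subject coverage >= 70; pathways whose normalized abundance never
#' reaches 1e-4 are excluded; k-means model selection searches k in
#' \[2, 10\].
#'
#' @return a named list of class `metacosm_config`.
#' @export
default_config <- function() {
  structure(list(
    marker_list_path = NULL,
    ko_catalog_path  = NULL,
    min_identity     = 70,
    min_bitscore     = 40,
    abundance_cutoff = 1e-4,
    db_min_identity  = 90,
    db_min_qcov      = 70,
    db_min_scov      = 70,
    genepool_max_evalue = 0.01,
    k_range          = c(2L, 10L),
    kmeans_restarts  = 100L,
    seed             = 1L
  ), class = "metacosm_config")
}

#' Read a YAML pipeline configuration
#'
#' Unknown keys are rejected; keys absent from the file keep their
#' [default_config()] values; thresholds are range-checked.
#'
#' @param path YAML file path.
#' @return a validated `metacosm_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown config key: ", unknown[1L])
  cfg[names(user)] <- user
  validate_config(cfg)
}

#' Validate a configuration list
#' @param cfg a config list as from [default_config()].
#' @return `cfg`, invisibly classed, or an error on out-of-range values.
#' @export
validate_config <- function(cfg) {
  in_range <- function(v, lo, hi, what) {
    if (!is.numeric(v) || any(v < lo) || any(v > hi))
      stop(what, " must lie in [", lo, ", ", hi, "]")
  }
  in_range(cfg$min_identity, 0, 100, "min_identity")
  in_range(cfg$db_min_identity, 0, 100, "db_min_identity")
  in_range(cfg$db_min_qcov, 0, 100, "db_min_qcov")
  in_range(cfg$db_min_scov, 0, 100, "db_min_scov")
  if (!is.numeric(cfg$abundance_cutoff) || cfg$abundance_cutoff <= 0)
    stop("abundance_cutoff must be > 0")
  if (cfg$min_bitscore < 0) stop("min_bitscore must be >= 0")
  kr <- cfg$k_range
  if (length(kr) != 2L || kr[1L] < 2 || kr[2L] < kr[1L])
    stop("k_range must be c(kmin, kmax) with 2 <= kmin <= kmax")
  class(cfg) <- "metacosm_config"
  cfg
}

#' Write a configuration as YAML
#' @param cfg config list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg)[!vapply(cfg, is.null, TRUE)], path)
  invisible(path)
}

# Stage logging: audit trail of inputs, thresholds and row counts.
# Silent unless options(metacosm.verbose = TRUE).
mc_log <- function(fmt, ...) {
  if (isTRUE(getOption("metacosm.verbose", FALSE)))
    message(sprintf("[metacosm] %s", sprintf(fmt, ...)))
  invisible(NULL)
}
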