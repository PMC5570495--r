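# Internal helpers shared across modules.

# Identity columns of a well table, in canonical order. Everything numeric
# after these is treated as a marker.
.id_cols <- c("plate_id", "well_id", "role", "gene", "sirna_id",
              "experiment", "cell_line")

.roles <- c("library", "scrambled", "positive_control", "etoposide",
            "untransfected")

#' Marker columns of a well table
#'
#' Any numeric column that is not part of the identity set
#' (`plate_id`, `well_id`, `role`, `gene`, `sirna_id`, `experiment`,
#' `cell_line`) is a marker. The assay panel varies between screens
#' (morphology biomarkers, a cytokine panel), so markers are detected,
#' not enumerated.
#'
#' @param wells a well table (`data.frame`).
#' @return character vector of marker column names.
#' @export
well_markers <- function(wells) {
  cand <- setdiff(names(wells), .id_cols)
  cand[vapply(wells[cand], is.numeric, logical(1))]
}

# Draw from Normal(mean, sd) truncated below at 0 (marker values are
# non-negative by construction). Vectorised over mean.
.rtnorm0 <- function(n, mean, sd) {
  lo <- stats::pnorm(0, mean = mean, sd = sd)
  u <- stats::runif(n, min = lo, max = 1)
  stats::qnorm(u, mean = mean, sd = sd)
}

# Stable content hash of an R object (config provenance). md5 over the
# serialised representation via a temp file; base R only.
.config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}

# ceiling(m_of_n * n) with protection against floating-point droop
# (2/3 * 3 must give 2, never 3).
.m_of_n_count <- function(n, m_of_n) {
  as.integer(ceiling(m_of_n * n - 1e-9))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
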