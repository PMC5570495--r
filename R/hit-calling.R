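#' Per-plate (or per-experiment) scrambled-control statistics
#'
#' Computes, for every control group and marker, the arithmetic mean and
#' sample standard deviation (n - 1 denominator) over present values.
#' These anchor every downstream threshold: a screen's cut-offs are
#' expressed as `mean + k * sd` of the plate's own negative controls, so
#' additive plate-to-plate offsets cancel.
#'
#' @param wells a well table.
#' @param role which wells define the control distribution
#'   (default `"scrambled"`).
#' @param scope `"plate"` (default) groups by `plate_id`;
#'   `"experiment"` pools plates within `cell_line` x `experiment`.
#' @param markers marker columns to summarise; default all.
#' @return `data.frame` of class `control_stats` with columns `scope`,
#'   `group`, `marker`, `mean`, `sd`, `n`.
#' @export
control_stats <- function(wells, role = "scrambled",
                          scope = c("plate", "experiment"),
                          markers = NULL) {
  scope <- match.arg(scope)
  if (is.null(markers)) markers <- well_markers(wells)
  ctrl <- wells[wells$role == role, , drop = FALSE]
  if (nrow(ctrl) == 0)
    .stopf("degenerate-control error: no wells with role '%s'", role)
  group <- if (scope == "plate") ctrl$plate_id
           else paste(ctrl$cell_line, ctrl$experiment, sep = "|")
  out <- list()
  for (g in unique(group)) {
    sub <- ctrl[group == g, , drop = FALSE]
    if (nrow(sub) < 2)
      .stopf("degenerate-control error: fewer than 2 control wells in group '%s'", g)
    for (m in markers) {
      v <- sub[[m]]
      v <- v[!is.na(v)]
      if (length(v) < 2)
        .stopf("degenerate-control error: fewer than 2 control values for marker '%s' in group '%s'", m, g)
      out[[length(out) + 1L]] <- data.frame(
        scope = scope, group = g, marker = m,
        mean = mean(v), sd = stats::sd(v), n = length(v),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("control_stats", "data.frame")
  res
}

# Look up (mean, sd) for each (group, marker) pair; errors on absence.
.stats_lookup <- function(stats_df, groups, marker) {
  idx <- match(paste(groups, marker, sep = "\r"),
               paste(stats_df$group, stats_df$marker, sep = "\r"))
  if (anyNA(idx))
    .stopf("no control stats for marker '%s' in group '%s'",
           marker, groups[which(is.na(idx))[1]])
  list(mean = stats_df$mean[idx], sd = stats_df$sd[idx])
}

# Group identifier of a well under the stats' scope.
.well_group <- function(wells, stats_df) {
  if (stats_df$scope[1] == "plate") wells$plate_id
  else paste(wells$cell_line, wells$experiment, sep = "|")
}

#' Primary-screen hit calling per siRNA
#'
#' A primary hit is a nuclear-area increase with reduced proliferation:
#' the siRNA's nuclear area must exceed the control
#' `mean + k * sd` for at least one configured `k` (strictly — exact
#' equality at a threshold does not pass), AND its object count must
#' fall strictly below `mean - count_k * sd` of the same controls.
#' Values are aggregated to one number per siRNA per experiment (mean
#' over its replicate wells) before thresholding; per-well mode is
#' available via `unit = "well"`.
#'
#' @param wells a well table.
#' @param stats a [control_stats()] table for the same wells.
#' @param area_marker,count_marker marker column names.
#' @param area_k increasing SD multipliers for the area rule
#'   (default `c(1, 2, 3)`).
#' @param count_k SD multiplier for the proliferation (object count)
#'   rule; `NULL` disables the count criterion.
#' @param unit `"sirna"` (default; mean over replicate wells) or
#'   `"well"` (every well scored, best well per siRNA retained).
#' @return `data.frame` with one row per
#'   cell line x experiment x gene x siRNA: the aggregated `area` and
#'   `count` values, `count_ok`, `passed` (at the smallest `k`), and
#'   `best_k` (largest `k` passed; `NA` if none).
#' @export
call_primary_hits <- function(wells, stats, area_marker = "nuclear_area",
                              count_marker = "object_count",
                              area_k = c(1, 2, 3), count_k = 1,
                              unit = c("sirna", "well")) {
  unit <- match.arg(unit)
  stopifnot(all(area_k > 0))
  lib <- wells[wells$role == "library", , drop = FALSE]
  if (nrow(lib) == 0) .stopf("no library wells to score")
  if (!area_marker %in% names(lib))
    .stopf("marker '%s' not present in well table", area_marker)
  lib$.group <- .well_group(lib, stats)
  keyv <- c("cell_line", "experiment", "gene", "sirna_id", ".group")
  if (unit == "sirna") {
    agg <- stats::aggregate(lib[c(area_marker, count_marker)],
                            by = lib[keyv], FUN = mean, na.rm = TRUE)
  } else {
    agg <- lib[c(keyv, area_marker, count_marker)]
  }
  if (anyNA(agg[[area_marker]]) || any(is.nan(agg[[area_marker]])))
    .stopf("no-data error: siRNA with no %s measurements", area_marker)
  st_a <- .stats_lookup(stats, agg$.group, area_marker)
  area_k <- sort(area_k)
  pass_k <- sapply(area_k, function(k)
    agg[[area_marker]] > st_a$mean + k * st_a$sd)
  pass_k <- matrix(pass_k, nrow = nrow(agg))
  count_ok <- rep(TRUE, nrow(agg))
  if (!is.null(count_k) && count_marker %in% names(agg)) {
    st_c <- .stats_lookup(stats, agg$.group, count_marker)
    count_ok <- !is.na(agg[[count_marker]]) &
      agg[[count_marker]] < st_c$mean - count_k * st_c$sd
  }
  pass_k <- pass_k & count_ok
  best_k <- apply(pass_k, 1, function(p)
    if (any(p)) max(area_k[p]) else NA_real_)
  res <- data.frame(cell_line = agg$cell_line, experiment = agg$experiment,
                    gene = agg$gene, sirna_id = agg$sirna_id,
                    area = agg[[area_marker]], count = agg[[count_marker]],
                    count_ok = count_ok, passed = !is.na(best_k),
                    best_k = best_k, stringsAsFactors = FALSE)
  if (unit == "well") {
    # retain each siRNA's best well
    ord <- order(res$cell_line, res$experiment, res$gene, res$sirna_id,
                 -ifelse(is.na(res$best_k), -1, res$best_k))
    res <- res[ord, ]
    res <- res[!duplicated(res[c("cell_line", "experiment", "gene",
                                 "sirna_id")]), ]
  }
  rownames(res) <- NULL
  res
}

#' Canonical confidence-ranking label
#'
#' Joins the non-zero per-level siRNA counts in descending SD order,
#' e.g. `"2 siRNA at 3 x SD; 1 siRNA at 2 x SD"`.
#'
#' @param n3,n2,n1 number of siRNAs whose best passing level is
#'   3, 2, 1 SD respectively.
#' @return character label (`"0 siRNA"` when all counts are zero).
#' @export
confidence_label <- function(n3, n2, n1) {
  part <- function(n, k) if (n > 0) sprintf("%d siRNA at %d x SD", n, k)
  mapply(function(a, b, c) {
    parts <- c(part(a, 3), part(b, 2), part(c, 1))
    if (length(parts) == 0) "0 siRNA" else paste(parts, collapse = "; ")
  }, n3, n2, n1)
}

#' Confidence ranking of genes from per-siRNA best thresholds
#'
#' For each gene, counts how many of its library siRNAs have a best
#' passing level of 3, 2 or 1 control SDs, renders the canonical label,
#' and orders genes lexicographically descending on
#' `(n_at_3sd, n_at_2sd, n_at_1sd)`.
#'
#' @param hits per-siRNA results from [call_primary_hits()] (one
#'   experiment), or any `data.frame` with columns `gene` and `best_k`.
#' @return `data.frame` with columns `gene`, `n_at_3sd`, `n_at_2sd`,
#'   `n_at_1sd`, `label`, ordered by descending confidence.
#' @export
rank_confidence <- function(hits) {
  stopifnot(all(c("gene", "best_k") %in% names(hits)))
  bad <- !(is.na(hits$best_k) | hits$best_k %in% c(1, 2, 3))
  if (any(bad))
    .stopf("best_k values must be in {NA, 1, 2, 3}; got %s",
           hits$best_k[bad][1])
  genes <- unique(hits$gene)
  cnt <- t(vapply(genes, function(g) {
    k <- hits$best_k[hits$gene == g]
    c(sum(k == 3, na.rm = TRUE), sum(k == 2, na.rm = TRUE),
      sum(k == 1, na.rm = TRUE))
  }, integer(3)))
  res <- data.frame(gene = genes, n_at_3sd = cnt[, 1], n_at_2sd = cnt[, 2],
                    n_at_1sd = cnt[, 3], stringsAsFactors = FALSE)
  res$label <- confidence_label(res$n_at_3sd, res$n_at_2sd, res$n_at_1sd)
  res <- res[order(-res$n_at_3sd, -res$n_at_2sd, -res$n_at_1sd, res$gene), ]
  rownames(res) <- NULL
  res
}
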