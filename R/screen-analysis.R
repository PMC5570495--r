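#' Analyse a senescence screen
#'
#' The central analysis step: from a per-well measurement table, anchors
#' thresholds to the scrambled controls of each plate, applies the
#' replicate-reproducibility hit rule to every biomarker (and, with the
#' inclusive comparison, to any cytokine panel present), classifies
#' per-gene proliferation against the seeding density, and combines
#' nuclear area, SAbGal and proliferation arrest into the
#' complete/partial/none senescence-response taxonomy per cell line.
#'
#' @param wells a well table ([read_well_table()] or
#'   [simulate_screen()]).
#' @param seeding_density cells seeded per well (default 3000).
#' @param markers biomarkers to score with the strict rule; default all
#'   non-cytokine markers except `object_count`.
#' @param unit replicate unit for the m-of-n rule, `"sirna"` (default)
#'   or `"well"`.
#' @param k SD multiplier of the validated-hit cut-off (default 3).
#' @param m_of_n reproducibility fraction (default 2/3).
#' @param scope control anchoring, `"plate"` (default) or
#'   `"experiment"`.
#' @param panel optional named list: cell line -> genotype description,
#'   for the summary table.
#' @return object of class `senescence_screen`: list with `stats`,
#'   `calls`, `cytokine_calls` (or `NULL`), `prolif`, `responses`,
#'   `summary_table`, and the call parameters.
#' @seealso [validated_hits()], [senescence_responses()],
#'   [summarize_panel()]
#' @examples
#' cfg <- screen_config(
#'   profiles = effect_profile("ECT2", c(nuclear_area = 5, sabgal = 5),
#'                             proliferation_pct = 120),
#'   n_null_genes = 2, seed = 1)
#' scr <- senescence_screen(simulate_screen(cfg))
#' scr
#' summary(scr)
#' @export
senescence_screen <- function(wells, seeding_density = 3000,
                              markers = NULL, unit = c("sirna", "well"),
                              k = 3, m_of_n = 2 / 3,
                              scope = c("plate", "experiment"),
                              panel = NULL) {
  unit <- match.arg(unit)
  scope <- match.arg(scope)
  wells <- validate_wells(wells)
  all_markers <- well_markers(wells)
  cytokines <- grep("^cytokine_", all_markers, value = TRUE)
  if (is.null(markers))
    markers <- setdiff(all_markers, c("object_count", cytokines))
  stats <- control_stats(wells, scope = scope)
  calls <- validated_hits(wells, stats, markers = markers, unit = unit,
                          k = k, m_of_n = m_of_n, comparison = "gt")
  cyto <- NULL
  if (length(cytokines) > 0)
    cyto <- call_cytokine_hits(wells, stats, cytokines = cytokines,
                               k = k, m_of_n = m_of_n)
  prolif <- proliferation_calls(wells, seeding_density)
  responses <- if (all(c("nuclear_area", "sabgal") %in% markers))
    senescence_responses(calls, prolif) else NULL
  summary_table <- if (!is.null(responses))
    summarize_panel(responses, panel = panel) else NULL
  structure(list(stats = stats, calls = calls, cytokine_calls = cyto,
                 prolif = prolif, responses = responses,
                 summary_table = summary_table,
                 params = list(seeding_density = seeding_density,
                               markers = markers, unit = unit, k = k,
                               m_of_n = m_of_n, scope = scope),
                 n_wells = nrow(wells)),
            class = "senescence_screen")
}

#' @export
print.senescence_screen <- function(x, ...) {
  p <- x$params
  cat("Senescence screen analysis\n")
  cat(sprintf("  %d wells, %d cell line(s), %d gene(s)\n", x$n_wells,
              length(unique(x$calls$cell_line)),
              length(unique(x$calls$gene))))
  cat(sprintf("  rule: unit value %s control mean + %g SD (%s-anchored), ",
              ">", p$k, p$scope))
  cat(sprintf(">= %s of %ss in >= %s of experiments\n",
              format(p$m_of_n, digits = 3), p$unit,
              format(p$m_of_n, digits = 3)))
  cat(sprintf("  biomarker hits: %d of %d gene x line x marker calls\n",
              sum(x$calls$hit), nrow(x$calls)))
  if (!is.null(x$cytokine_calls))
    cat(sprintf("  cytokine hits: %d of %d calls\n",
                sum(x$cytokine_calls$hit), nrow(x$cytokine_calls)))
  if (!is.null(x$responses)) {
    tab <- table(x$responses$response)
    cat(sprintf("  responses: %d complete, %d partial, %d none\n",
                tab[["complete"]], tab[["partial"]], tab[["none"]]))
  }
  invisible(x)
}

#' @export
summary.senescence_screen <- function(object, ...) {
  out <- list(summary_table = object$summary_table,
              responses = object$responses,
              hit_rate = mean(object$calls$hit),
              params = object$params)
  class(out) <- "summary.senescence_screen"
  out
}

#' @export
print.summary.senescence_screen <- function(x, ...) {
  cat("Genotype panel summary\n")
  if (!is.null(x$summary_table)) {
    print(x$summary_table, row.names = FALSE)
  } else {
    cat("  (nuclear_area/sabgal not both scored; no response table)\n")
  }
  cat(sprintf("\nOverall biomarker hit rate: %.3f\n", x$hit_rate))
  invisible(x)
}

#' Heat-map of per-experiment pass counts
#'
#' Draws the screen's hit/miss matrix: genes as rows, cell line x
#' marker as columns, cell colour by hit status, the printed number
#' being how many independent experiments passed the replicate rule.
#'
#' @param x a `senescence_screen` object.
#' @param ... passed to [graphics::image()].
#' @return invisibly, the pass-count matrix drawn.
#' @export
plot.senescence_screen <- function(x, ...) {
  calls <- x$calls
  genes <- sort(unique(calls$gene))
  combo <- unique(calls[c("cell_line", "marker")])
  combo <- combo[order(combo$cell_line, combo$marker), ]
  cn <- paste(combo$cell_line, combo$marker, sep = "\n")
  m <- matrix(NA_real_, length(genes), nrow(combo),
              dimnames = list(genes, cn))
  hit <- m
  for (i in seq_len(nrow(calls))) {
    r <- match(calls$gene[i], genes)
    c <- match(paste(calls$cell_line[i], calls$marker[i], sep = "\n"), cn)
    m[r, c] <- calls$n_experiments_pass[i]
    hit[r, c] <- as.numeric(calls$hit[i])
  }
  op <- graphics::par(mar = c(6, 6, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(hit),
                  col = c("#d73027", "#1a9850"), zlim = c(0, 1),
                  axes = FALSE, xlab = "", ylab = "",
                  main = "Validated hits (label = experiments passing)",
                  ...)
  graphics::axis(1, seq_len(ncol(m)), colnames(m), las = 2,
                 cex.axis = 0.7, tick = FALSE)
  graphics::axis(2, seq_len(nrow(m)), rownames(m), las = 2,
                 cex.axis = 0.7, tick = FALSE)
  for (j in seq_len(ncol(m)))
    graphics::text(j, seq_len(nrow(m)), m[, j], cex = 0.7)
  invisible(m)
}
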