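#' Replicate-reproducibility hit call (m-of-n rule)
#'
#' The validated-hit rule: a unit (well or siRNA) passes an experiment
#' when its value exceeds the control `mean + k * sd`; an experiment
#' passes when at least `ceiling(m_of_n * units)` of its units pass; the
#' gene is a hit when at least `ceiling(m_of_n * experiments)`
#' experiments pass. With the defaults this is the
#' "2/3 units in 2/3 independent experiments beyond mean + 3 SD" rule.
#' The biomarker convention is a strict `>` comparison; the cytokine
#' convention ("by at least mean + 3SD") is `>=` — select with
#' `comparison`.
#'
#' @param values per-experiment unit values: a list of numeric vectors
#'   (one per experiment) or a matrix with experiments as columns.
#' @param control_mean,control_sd control statistics the threshold is
#'   anchored to. Scalars apply to all experiments; vectors of length
#'   `n_experiments` give each experiment (plate) its own anchor.
#' @param k SD multiplier (default 3).
#' @param m_of_n required fraction at both levels (default 2/3).
#' @param comparison `"gt"` (strict, biomarkers) or `"ge"` (cytokines).
#' @return one-row `data.frame`: `n_experiments`, `n_experiments_pass`,
#'   `hit`.
#' @export
call_validated_hit <- function(values, control_mean, control_sd, k = 3,
                               m_of_n = 2 / 3, comparison = c("gt", "ge")) {
  comparison <- match.arg(comparison)
  if (is.matrix(values)) values <- lapply(seq_len(ncol(values)),
                                          function(j) values[, j])
  values <- lapply(values, function(v) v[!is.na(v)])
  keep <- lengths(values) > 0
  if (!all(keep)) {
    .warnf("excluding %d experiment(s) with no units", sum(!keep))
    values <- values[keep]
  }
  n_exp <- length(values)
  if (n_exp == 0) .stopf("no experiments with data")
  if (length(control_mean) == 1) control_mean <- rep(control_mean, n_exp)
  if (length(control_sd) == 1) control_sd <- rep(control_sd, n_exp)
  if (length(control_mean) != n_exp || length(control_sd) != n_exp)
    .stopf("control stats must be scalar or one per experiment")
  exp_pass <- vapply(seq_len(n_exp), function(e) {
    thr <- control_mean[e] + k * control_sd[e]
    ok <- if (comparison == "gt") values[[e]] > thr else values[[e]] >= thr
    sum(ok) >= .m_of_n_count(length(ok), m_of_n)
  }, logical(1))
  n_pass <- sum(exp_pass)
  data.frame(n_experiments = n_exp, n_experiments_pass = n_pass,
             hit = n_pass >= .m_of_n_count(n_exp, m_of_n))
}

#' Validated hit calls for every gene x cell line x marker
#'
#' Applies [call_validated_hit()] across a well table: for each cell
#' line, gene and marker, the unit values of each experiment (per-siRNA
#' replicate-well means by default, or raw wells) are compared against
#' that experiment's plate-anchored control threshold.
#'
#' @param wells a well table (library wells are scored).
#' @param stats a [control_stats()] table.
#' @param markers markers to score; default all except `object_count`.
#' @param unit `"sirna"` (default) or `"well"`.
#' @inheritParams call_validated_hit
#' @return `data.frame` of class `hit_calls`: `gene`, `cell_line`,
#'   `marker`, `n_experiments`, `n_experiments_pass`, `hit`.
#' @export
validated_hits <- function(wells, stats, markers = NULL,
                           unit = c("sirna", "well"), k = 3,
                           m_of_n = 2 / 3, comparison = c("gt", "ge")) {
  unit <- match.arg(unit)
  comparison <- match.arg(comparison)
  if (is.null(markers)) markers <- setdiff(well_markers(wells), "object_count")
  lib <- wells[wells$role == "library", , drop = FALSE]
  if (nrow(lib) == 0) .stopf("no library wells to score")
  lib$.group <- .well_group(lib, stats)
  out <- list()
  for (line in unique(lib$cell_line)) {
    sub_l <- lib[lib$cell_line == line, , drop = FALSE]
    for (g in unique(sub_l$gene)) {
      sub_g <- sub_l[sub_l$gene == g, , drop = FALSE]
      exps <- sort(unique(sub_g$experiment))
      for (m in markers) {
        vals <- vector("list", length(exps))
        mu <- sd <- numeric(length(exps))
        for (i in seq_along(exps)) {
          se <- sub_g[sub_g$experiment == exps[i], , drop = FALSE]
          st <- .stats_lookup(stats, se$.group[1], m)
          mu[i] <- st$mean; sd[i] <- st$sd
          vals[[i]] <- if (unit == "sirna") {
            as.numeric(tapply(se[[m]], se$sirna_id,
                              function(v) mean(v, na.rm = TRUE)))
          } else se[[m]]
        }
        call <- call_validated_hit(vals, mu, sd, k = k, m_of_n = m_of_n,
                                   comparison = comparison)
        out[[length(out) + 1L]] <- cbind(
          data.frame(gene = g, cell_line = line, marker = m,
                     stringsAsFactors = FALSE), call)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("hit_calls", "data.frame")
  res
}

#' SASP cytokine hit calls
#'
#' Scores a cytokine panel with the induction rule: at least 2/3 of the
#' library siRNAs raising the cytokine by at least `mean + 3 SD` of the
#' scrambled controls, in at least 2/3 of experiments. This is
#' [validated_hits()] with `unit = "sirna"` and the inclusive (`>=`)
#' comparison.
#'
#' @param wells a well table.
#' @param stats a [control_stats()] table.
#' @param cytokines cytokine marker names; default every marker whose
#'   name starts with `"cytokine_"`.
#' @inheritParams call_validated_hit
#' @return a `hit_calls` data frame (one row per
#'   gene x cell line x cytokine).
#' @export
call_cytokine_hits <- function(wells, stats, cytokines = NULL, k = 3,
                               m_of_n = 2 / 3) {
  if (is.null(cytokines))
    cytokines <- grep("^cytokine_", well_markers(wells), value = TRUE)
  if (length(cytokines) == 0)
    .stopf("no cytokine markers found in well table")
  validated_hits(wells, stats, markers = cytokines, unit = "sirna",
                 k = k, m_of_n = m_of_n, comparison = "ge")
}

#' Fold change over scrambled control
#'
#' @param value measured level.
#' @param scrambled_mean mean of the scrambled (non-targeting) controls;
#'   must be positive.
#' @return `value / scrambled_mean`, vectorised.
#' @export
fold_of_scrambled <- function(value, scrambled_mean) {
  if (any(scrambled_mean <= 0))
    .stopf("scrambled mean must be positive for fold computation")
  value / scrambled_mean
}

#' Proliferation class relative to seeding density
#'
#' The endpoint cell number as a percentage of seeding density
#' partitions outcomes: below 100% is toxicity, 100-150% (both ends
#' inclusive) is cytostasis ("no growth"), above 150% is growth.
#'
#' @param final_count endpoint cell number (vectorised).
#' @param seeding_density cells seeded per well.
#' @return `data.frame` with `pct_of_seeding` and `class` (factor with
#'   levels `toxic`, `cytostasis`, `growth`).
#' @export
classify_proliferation <- function(final_count, seeding_density = 3000) {
  if (seeding_density <= 0) .stopf("seeding_density must be positive")
  if (any(final_count < 0)) .stopf("final_count must be non-negative")
  pct <- 100 * final_count / seeding_density
  cls <- ifelse(pct < 100, "toxic",
                ifelse(pct <= 150, "cytostasis", "growth"))
  data.frame(pct_of_seeding = pct,
             class = factor(cls, levels = c("toxic", "cytostasis", "growth")))
}

#' Proliferation class from a percentage
#'
#' Convenience wrapper of [classify_proliferation()] when the percentage
#' of seeding density is already known.
#'
#' @param pct endpoint cell number as % of seeding density (vectorised).
#' @return factor with levels `toxic`, `cytostasis`, `growth`.
#' @export
proliferation_class <- function(pct) {
  classify_proliferation(pct, seeding_density = 100)$class
}

#' Complete / partial / none senescence-response class
#'
#' A complete senescence response requires all three phenotypes:
#' nuclear-area hit, SAbGal hit, and proliferation arrest (cytostasis).
#' No marker hit together with unimpeded growth is "none"; every other
#' combination — including marker induction with toxicity — is a partial
#' response.
#'
#' @param area_hit,sabgal_hit logical marker hits (vectorised).
#' @param prolif proliferation class (`toxic` / `cytostasis` / `growth`,
#'   as factor or character).
#' @return factor with levels `complete`, `partial`, `none`.
#' @export
classify_senescence_response <- function(area_hit, sabgal_hit, prolif) {
  prolif <- as.character(prolif)
  bad <- setdiff(unique(prolif), c("toxic", "cytostasis", "growth"))
  if (length(bad) > 0)
    .stopf("unknown proliferation class: %s", bad[1])
  cls <- ifelse(area_hit & sabgal_hit & prolif == "cytostasis", "complete",
                ifelse(!area_hit & !sabgal_hit & prolif == "growth", "none",
                       "partial"))
  factor(cls, levels = c("complete", "partial", "none"))
}

#' Per-gene proliferation calls from a well table
#'
#' Endpoint object counts of a gene's library wells (all siRNAs, all
#' experiments) are averaged and expressed as a percentage of seeding
#' density, then classified.
#'
#' @param wells a well table with an `object_count` marker.
#' @param seeding_density cells seeded per well.
#' @return `data.frame`: `gene`, `cell_line`, `pct_of_seeding`, `class`.
#' @export
proliferation_calls <- function(wells, seeding_density = 3000) {
  lib <- wells[wells$role == "library", , drop = FALSE]
  if (!"object_count" %in% names(lib))
    .stopf("well table has no object_count marker")
  agg <- stats::aggregate(lib["object_count"],
                          by = lib[c("gene", "cell_line")],
                          FUN = mean, na.rm = TRUE)
  cls <- classify_proliferation(agg$object_count, seeding_density)
  data.frame(gene = agg$gene, cell_line = agg$cell_line,
             pct_of_seeding = cls$pct_of_seeding, class = cls$class,
             stringsAsFactors = FALSE)
}

#' Senescence-response classification across a panel
#'
#' Joins marker hit calls and proliferation classes per gene x cell line
#' and applies [classify_senescence_response()].
#'
#' @param calls a `hit_calls` table containing the `area_marker` and
#'   `sabgal_marker` rows.
#' @param prolif output of [proliferation_calls()].
#' @param area_marker,sabgal_marker marker names used for the two
#'   morphology criteria.
#' @return `data.frame`: `gene`, `cell_line`, `nuclear_area_hit`,
#'   `sabgal_hit`, `prolif_class`, `pct_of_seeding`, `response`.
#' @export
senescence_responses <- function(calls, prolif,
                                 area_marker = "nuclear_area",
                                 sabgal_marker = "sabgal") {
  key <- unique(prolif[c("gene", "cell_line")])
  pick <- function(marker) {
    sub <- calls[calls$marker == marker, , drop = FALSE]
    idx <- match(paste(key$gene, key$cell_line),
                 paste(sub$gene, sub$cell_line))
    if (anyNA(idx))
      .stopf("missing %s hit call for %s / %s", marker,
             key$gene[which(is.na(idx))[1]],
             key$cell_line[which(is.na(idx))[1]])
    sub$hit[idx]
  }
  area_hit <- pick(area_marker)
  sab_hit <- pick(sabgal_marker)
  pidx <- match(paste(key$gene, key$cell_line),
                paste(prolif$gene, prolif$cell_line))
  pcls <- as.character(prolif$class[pidx])
  data.frame(gene = key$gene, cell_line = key$cell_line,
             nuclear_area_hit = area_hit, sabgal_hit = sab_hit,
             prolif_class = pcls,
             pct_of_seeding = prolif$pct_of_seeding[pidx],
             response = classify_senescence_response(area_hit, sab_hit, pcls),
             stringsAsFactors = FALSE)
}

#' Genotype-panel summary of senescence responses
#'
#' Renders the per-cell-line response lists: genes with a complete
#' senescence response and genes with a partial response, sorted
#' alphabetically, `"None"` when a list is empty. Genes present in the
#' panel but unscored in a line are reported in an `unscored` column.
#'
#' @param responses output of [senescence_responses()].
#' @param panel optional named list/vector: cell line -> genotype
#'   description, defining the row set and order; genes expected per
#'   line default to all genes seen anywhere.
#' @param genes optional character vector of genes expected in every
#'   line.
#' @return `data.frame`: `cell_line`, `genotype` (if panel given),
#'   `senescence_response`, `partial_senescence_response`, `none`,
#'   `unscored`.
#' @export
summarize_panel <- function(responses, panel = NULL, genes = NULL) {
  lines <- if (!is.null(panel)) names(panel) else unique(responses$cell_line)
  if (is.null(genes)) genes <- sort(unique(responses$gene))
  render <- function(v) if (length(v) == 0) "None"
                        else paste(sort(v), collapse = ", ")
  rows <- lapply(lines, function(line) {
    sub <- responses[responses$cell_line == line, , drop = FALSE]
    data.frame(
      cell_line = line,
      genotype = if (!is.null(panel)) as.character(panel[[line]]) else NA,
      senescence_response = render(sub$gene[sub$response == "complete"]),
      partial_senescence_response = render(sub$gene[sub$response == "partial"]),
      none = render(sub$gene[sub$response == "none"]),
      unscored = render(setdiff(genes, sub$gene)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(panel)) out$genotype <- NULL
  out$unscored[out$unscored == "None"] <- ""
  out
}
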