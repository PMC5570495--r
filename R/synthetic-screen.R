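#' Default marker panel for the synthetic screen
#'
#' Control-level means and standard deviations for the four morphology
#' biomarkers and a nine-cytokine inflammatory panel. The screen's
#' thresholding is anchored to scrambled controls, so only the relative
#' scale (mean/SD) matters downstream; these levels are package
#' conventions in assay-plausible units (nuclear area in square microns,
#' object count in cells, SAbGal and p21 in intensity units, 53BP1 in
#' foci per nucleus, cytokines in pg/mL).
#'
#' @return list with numeric vectors `mean` and `sd`, named by marker.
#' @export
default_marker_panel <- function() {
  cytokines <- c("gmcsf", "ifng", "il10", "il12p70", "il1b",
                 "il2", "il6", "il8", "tnfa")
  mean <- c(nuclear_area = 200, sabgal = 10, p21 = 500, bp1_foci = 1.5,
            stats::setNames(rep(20, 9), paste0("cytokine_", cytokines)))
  sd <- c(nuclear_area = 20, sabgal = 1.5, p21 = 50, bp1_foci = 0.3,
          stats::setNames(rep(3, 9), paste0("cytokine_", cytokines)))
  list(mean = mean, sd = sd)
}

#' Effect profile of a knocked-down gene
#'
#' Generative description of one gene's phenotype in one cell line:
#' per-marker shifts in units of the control SD, the endpoint cell
#' number as a percentage of seeding density, and how many of the
#' library siRNAs are active (off-target/efficacy heterogeneity —
#' inactive siRNAs draw from the control distribution).
#'
#' @param gene gene symbol.
#' @param shift named numeric vector of per-marker shifts (control-SD
#'   units); markers not named shift by 0.
#' @param proliferation_pct endpoint cell number, % of seeding density.
#' @param n_sirnas_active number of active library siRNAs (0-3).
#' @param cell_line cell line the profile applies to.
#' @return a one-row `data.frame` profile.
#' @export
effect_profile <- function(gene, shift = c(nuclear_area = 0),
                           proliferation_pct = 250, n_sirnas_active = 3,
                           cell_line = "HCT116") {
  stopifnot(proliferation_pct >= 0, n_sirnas_active >= 0)
  data.frame(gene = gene, cell_line = cell_line,
             proliferation_pct = proliferation_pct,
             n_sirnas_active = n_sirnas_active,
             shift = I(list(shift)), stringsAsFactors = FALSE)
}

#' Configuration of a synthetic screen
#'
#' Bundles the plate layout, control-level marker panel, gene effect
#' profiles, and nuisance parameters into a validated configuration for
#' [simulate_screen()].
#'
#' The layout defaults mirror the screen design the decision rules
#' assume: 3000 cells seeded per well, 3 library siRNAs per gene, 3
#' replicate wells per condition, 3 independent experiments. Each
#' experiment of each cell line is one plate carrying its own scrambled,
#' positive-control (CDK1) and etoposide wells; plate-to-plate offsets
#' are additive and shared by every well of the plate (controls
#' included), which is exactly the structure per-plate control anchoring
#' removes.
#'
#' @param profiles `data.frame` of effect profiles (rbind of
#'   [effect_profile()] rows); may be `NULL` for a null screen.
#' @param n_null_genes extra null genes drawn from the control
#'   distribution in every cell line.
#' @param seeding_density cells seeded per well.
#' @param wells_per_condition replicate wells per siRNA per experiment.
#' @param sirnas_per_gene library siRNAs per gene.
#' @param experiments independent experiments (one plate each).
#' @param control_mean,control_sd named per-marker control levels;
#'   default [default_marker_panel()].
#' @param n_scrambled scrambled-control wells per plate.
#' @param scrambled_prolif_pct endpoint % of seeding for unaffected
#'   (control / inactive / null) wells.
#' @param plate_effect_sd SD of the additive per-plate offset, in units
#'   of each marker's control SD.
#' @param cell_lines cell lines to simulate; defaults to those named in
#'   `profiles` (or `"HCT116"` for a pure null screen).
#' @param seed RNG seed recorded in the output provenance.
#' @return a list of class `screen_config`.
#' @export
screen_config <- function(profiles = NULL, n_null_genes = 0,
                          seeding_density = 3000, wells_per_condition = 3,
                          sirnas_per_gene = 3, experiments = 3,
                          control_mean = NULL, control_sd = NULL,
                          n_scrambled = 6, scrambled_prolif_pct = 250,
                          plate_effect_sd = 0.25, cell_lines = NULL,
                          seed = NULL) {
  panel <- default_marker_panel()
  if (is.null(control_mean)) control_mean <- panel$mean
  if (is.null(control_sd)) control_sd <- panel$sd[names(control_mean)]
  if (!identical(sort(names(control_mean)), sort(names(control_sd))))
    .stopf("config error: control_mean and control_sd must name the same markers")
  if (any(control_sd <= 0))
    .stopf("config error: control SD must be positive for every marker")
  if (seeding_density <= 0)
    .stopf("config error: seeding_density must be positive")
  if (!is.null(profiles) && any(profiles$n_sirnas_active > sirnas_per_gene))
    .stopf("config error: n_sirnas_active exceeds sirnas_per_gene")
  if (is.null(cell_lines))
    cell_lines <- if (is.null(profiles)) "HCT116" else unique(profiles$cell_line)
  cfg <- list(profiles = profiles, n_null_genes = n_null_genes,
              seeding_density = as.integer(seeding_density),
              wells_per_condition = as.integer(wells_per_condition),
              sirnas_per_gene = as.integer(sirnas_per_gene),
              experiments = as.integer(experiments),
              control_mean = control_mean,
              control_sd = control_sd[names(control_mean)],
              n_scrambled = as.integer(n_scrambled),
              scrambled_prolif_pct = scrambled_prolif_pct,
              plate_effect_sd = plate_effect_sd,
              cell_lines = cell_lines, seed = seed)
  class(cfg) <- "screen_config"
  cfg
}

# Marker draws for one block of wells sharing a shift vector.
.draw_block <- function(n, cfg, shift, plate_off) {
  markers <- names(cfg$control_mean)
  out <- matrix(NA_real_, n, length(markers),
                dimnames = list(NULL, markers))
  for (m in markers) {
    sh <- if (m %in% names(shift)) shift[[m]] else 0
    mu <- cfg$control_mean[[m]] + (sh + plate_off[[m]]) * cfg$control_sd[[m]]
    out[, m] <- .rtnorm0(n, mu, cfg$control_sd[[m]])
  }
  out
}

#' Simulate a well table
#'
#' Generates per-well marker measurements with the statistical structure
#' the screen's decision rules assume: marker values are Normal around
#' `control_mean + shift * control_sd` plus an additive per-plate offset,
#' truncated at 0; inactive siRNAs and null genes draw from the control
#' distribution; `object_count` is Poisson around the profile's
#' proliferation percentage of the seeding density. Scrambled,
#' positive-control (CDK1, strong senescence-like effect) and etoposide
#' wells are emitted on every plate. Identical seeds give identical
#' tables.
#'
#' @param config a [screen_config()].
#' @return a well-table `data.frame` (see [read_well_table()] for the
#'   schema) with a `provenance` attribute recording seed and config
#'   hash.
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "screen_config"))
  cfg <- config
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  markers <- names(cfg$control_mean)
  rows <- list()
  ri <- 0L
  add <- function(df) { ri <<- ri + 1L; rows[[ri]] <<- df }
  ctrl_lambda <- cfg$seeding_density * cfg$scrambled_prolif_pct / 100
  # positive control emulates a robust senescence inducer; etoposide a
  # DNA-damage arrest control
  pos_shift <- c(nuclear_area = 5, sabgal = 5, p21 = 5, bp1_foci = 5)
  eto_shift <- c(nuclear_area = 4, sabgal = 4, p21 = 4, bp1_foci = 4)

  for (line in cfg$cell_lines) {
    prof <- cfg$profiles
    if (!is.null(prof)) prof <- prof[prof$cell_line == line, , drop = FALSE]
    genes <- if (is.null(prof)) character(0) else prof$gene
    null_genes <- if (cfg$n_null_genes > 0)
      sprintf("NULL%04d", seq_len(cfg$n_null_genes)) else character(0)
    for (exp in seq_len(cfg$experiments)) {
      plate <- sprintf("%s_E%d_P1", line, exp)
      plate_off <- stats::setNames(
        stats::rnorm(length(markers), 0, cfg$plate_effect_sd), markers)
      emit <- function(role, gene, sirna, n, shift, lambda) {
        vals <- .draw_block(n, cfg, shift, plate_off)
        df <- data.frame(plate_id = plate,
                         well_id = sprintf("W%03d", seq_len(n)),
                         role = role, gene = gene, sirna_id = sirna,
                         experiment = exp, cell_line = line,
                         stringsAsFactors = FALSE)
        df <- cbind(df, as.data.frame(vals))
        df$object_count <- as.numeric(stats::rpois(n, lambda))
        df
      }
      add(emit("scrambled", "", "scrambled", cfg$n_scrambled,
               numeric(0), ctrl_lambda))
      add(emit("positive_control", "CDK1", "CDK1_q", cfg$wells_per_condition,
               pos_shift, cfg$seeding_density * 0.9))
      add(emit("etoposide", "", "etoposide", cfg$wells_per_condition,
               eto_shift, cfg$seeding_density * 1.2))
      for (g in seq_along(genes)) {
        p <- prof[g, ]
        shift <- p$shift[[1]]
        for (s in seq_len(cfg$sirnas_per_gene)) {
          active <- s <= p$n_sirnas_active
          add(emit("library", genes[g], sprintf("%s_si%d", genes[g], s),
                   cfg$wells_per_condition,
                   if (active) shift else numeric(0),
                   if (active) cfg$seeding_density * p$proliferation_pct / 100
                   else ctrl_lambda))
        }
      }
      for (g in null_genes) {
        for (s in seq_len(cfg$sirnas_per_gene)) {
          add(emit("library", g, sprintf("%s_si%d", g, s),
                   cfg$wells_per_condition, numeric(0), ctrl_lambda))
        }
      }
    }
  }
  wells <- do.call(rbind, rows)
  # well ids unique within plate
  wells$well_id <- stats::ave(seq_len(nrow(wells)), wells$plate_id,
                              FUN = seq_along)
  wells$well_id <- sprintf("W%03d", wells$well_id)
  rownames(wells) <- NULL
  attr(wells, "provenance") <- list(
    seed = cfg$seed,
    config_hash = .config_hash(unclass(cfg)),
    generated = "simulate_screen")
  validate_wells(wells)
}

#' Simulate a probe-level expression matrix
#'
#' Log2 intensities are `baseline + group * fold + Normal(0, noise_sd)`,
#' plus a per-array scale offset so that percentile normalisation is
#' non-trivial. Group A is the treatment (e.g. knockdown) group; a
#' negative log2 fold in `de_probes` means the probe is reduced in A
#' relative to B.
#'
#' @param n_probes number of probes.
#' @param de_probes named numeric vector of true log2 folds (names are
#'   probe ids among `probe0001...`); `NULL` for a null matrix.
#' @param n_arrays_a,n_arrays_b arrays per group.
#' @param noise_sd residual SD of log2 intensity; must be positive.
#' @param array_offset_sd SD of the per-array additive offset.
#' @param seed RNG seed.
#' @return numeric matrix probes x arrays with a `groups` attribute
#'   (named list `A`, `B` of array ids) and a `provenance` attribute.
#' @export
simulate_expression <- function(n_probes, de_probes = NULL,
                                n_arrays_a = 3, n_arrays_b = 5,
                                noise_sd = 0.25, array_offset_sd = 0.5,
                                seed = NULL) {
  if (noise_sd <= 0) .stopf("config error: noise_sd must be positive")
  if (!is.null(de_probes) && length(de_probes) > n_probes)
    .stopf("config error: more DE probes than probes")
  if (!is.null(seed)) set.seed(seed)
  probes <- sprintf("probe%04d", seq_len(n_probes))
  arrays <- c(paste0("A", seq_len(n_arrays_a)),
              paste0("B", seq_len(n_arrays_b)))
  baseline <- stats::runif(n_probes, 6, 12)
  fold <- stats::setNames(rep(0, n_probes), probes)
  if (!is.null(de_probes)) {
    unknown <- setdiff(names(de_probes), probes)
    if (length(unknown) > 0)
      .stopf("config error: DE probe id(s) not in matrix: %s",
             paste(unknown, collapse = ", "))
    fold[names(de_probes)] <- de_probes
  }
  n_arr <- n_arrays_a + n_arrays_b
  is_a <- rep(c(1, 0), c(n_arrays_a, n_arrays_b))
  offset <- stats::rnorm(n_arr, 0, array_offset_sd)
  m <- matrix(NA_real_, n_probes, n_arr, dimnames = list(probes, arrays))
  for (j in seq_len(n_arr)) {
    m[, j] <- baseline + is_a[j] * fold + offset[j] +
      stats::rnorm(n_probes, 0, noise_sd)
  }
  attr(m, "groups") <- list(A = arrays[seq_len(n_arrays_a)],
                            B = arrays[n_arrays_a + seq_len(n_arrays_b)])
  attr(m, "provenance") <- list(seed = seed,
                                generated = "simulate_expression")
  m
}
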