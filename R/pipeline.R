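#' Run the full screen pipeline
#'
#' Chains simulate (or load) -> control stats -> validated hit calls ->
#' proliferation classes -> senescence responses -> genotype summary,
#' and, when the configuration carries a network block, the
#' expression/shortest-paths stage. Every output is written to
#' `out_dir` along with a run log echoing the seed and the full
#' configuration; the run is deterministic given the seed.
#'
#' @param config a configuration list, or the path to a YAML file with
#'   (all optional) blocks `wells` (path to a well table; otherwise
#'   `simulation` is used), `simulation` (`n_null_genes`, `profiles`
#'   as a list of `gene`/`cell_line`/`proliferation_pct`/
#'   `n_sirnas_active`/`shift` entries), `layout` (`seeding_density`,
#'   `wells_per_condition`, `sirnas_per_gene`, `experiments`),
#'   `threshold` (`k`, `m_of_n`, `unit`, `scope`), `panel` (cell line ->
#'   genotype string), `network` (`graph` SIF path, `expression` TSV
#'   path or simulation spec, `seed_node`, `alpha`, `min_fold`), and
#'   `seed`.
#' @param out_dir output directory (created if needed).
#' @param seed overrides the config seed when given.
#' @return the `senescence_screen` object, invisibly, with the output
#'   paths in attribute `outputs`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(seed)) config$seed <- seed
  if (is.null(config$seed)) config$seed <- 1L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...),
                                 file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("senescreen pipeline run")
  logf("seed: %s", config$seed)
  logf("config: %s", paste(utils::capture.output(utils::str(config)),
                           collapse = "\n  "))
  stage <- "screen_io"
  res <- tryCatch({
    lay <- config$layout
    get <- function(blk, name, default) {
      if (!is.null(blk[[name]])) blk[[name]] else default
    }
    seeding <- get(lay, "seeding_density", 3000)
    if (!is.null(config$wells)) {
      if (!file.exists(config$wells))
        .stopf("well table not found: %s", config$wells)
      wells <- read_well_table(config$wells)
    } else {
      stage <- "synthetic_screen"
      sim <- config$simulation
      profiles <- NULL
      if (!is.null(sim$profiles)) {
        profiles <- do.call(rbind, lapply(sim$profiles, function(p) {
          effect_profile(p$gene,
                         shift = unlist(get(p, "shift",
                                            list(nuclear_area = 0))),
                         proliferation_pct = get(p, "proliferation_pct", 250),
                         n_sirnas_active = get(p, "n_sirnas_active", 3),
                         cell_line = get(p, "cell_line", "HCT116"))
        }))
      }
      cfg <- screen_config(
        profiles = profiles,
        n_null_genes = get(sim, "n_null_genes", 0),
        seeding_density = seeding,
        wells_per_condition = get(lay, "wells_per_condition", 3),
        sirnas_per_gene = get(lay, "sirnas_per_gene", 3),
        experiments = get(lay, "experiments", 3),
        plate_effect_sd = get(sim, "plate_effect_sd", 0.25),
        seed = config$seed)
      wells <- simulate_screen(cfg)
      write_well_table(wells, file.path(out_dir, "wells.tsv"))
      logf("simulated %d wells (config hash %s)", nrow(wells),
           attr(wells, "provenance")$config_hash)
    }
    stage <- "hit_calling"
    thr <- config$threshold
    scr <- senescence_screen(
      wells, seeding_density = seeding,
      unit = get(thr, "unit", "sirna"), k = get(thr, "k", 3),
      m_of_n = get(thr, "m_of_n", 2 / 3),
      scope = get(thr, "scope", "plate"),
      panel = config$panel)
    write_hit_matrix(scr$calls, file.path(out_dir, "hit_matrix.tsv"))
    stats <- scr$stats
    primary <- call_primary_hits(wells, stats)
    ranking <- rank_confidence(primary[primary$experiment ==
                                         min(primary$experiment), ])
    utils::write.table(ranking, file.path(out_dir, "confidence_ranking.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stage <- "phenotype_classification"
    if (!is.null(scr$summary_table))
      utils::write.table(scr$summary_table,
                         file.path(out_dir, "panel_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(scr$cytokine_calls))
      write_hit_matrix(scr$cytokine_calls,
                       file.path(out_dir, "cytokine_hit_matrix.tsv"))
    if (!is.null(config$network)) {
      stage <- "expression_network"
      run_network_stage(config$network, out_dir, seed = config$seed,
                        logf = logf)
    }
    logf("pipeline complete")
    scr
  }, error = function(e) {
    logf("FAILED at stage %s: %s", stage, conditionMessage(e))
    .stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
  outputs <- list.files(out_dir, full.names = TRUE)
  attr(res, "outputs") <- outputs
  invisible(res)
}

#' Expression + shortest-paths network stage
#'
#' Normalises the expression matrix (75th percentile per array), selects
#' differentially expressed probes by unpaired t-test at `alpha`,
#' builds the seed-anchored shortest-paths subnetworks for the two
#' conditions on the supplied interaction graph, and writes the merged,
#' fold-overlaid network.
#'
#' @param net network block of the run configuration: `graph` (SIF
#'   path) or `edges` (data frame), `seed_node`, condition blocks `a`
#'   and `b` each holding either `expression` (TSV path) + `group_a` /
#'   `group_b` column names, or a simulation spec for
#'   [simulate_expression()]; `probe_to_gene` optional TSV mapping;
#'   `alpha` (default 0.03); `min_fold` (default 2).
#' @param out_dir output directory.
#' @param seed RNG seed for simulated expression.
#' @param logf internal logger.
#' @return the `merged_network`, invisibly.
#' @export
run_network_stage <- function(net, out_dir, seed = 1,
                              logf = function(...) invisible()) {
  graph <- if (!is.null(net$graph)) read_sif(net$graph)
           else as_interaction_graph(net$edges)
  de_for <- function(blk, seed_offset) {
    if (!is.null(blk$expression)) {
      mat <- read_expression(blk$expression)
      groups <- list(A = blk$group_a, B = blk$group_b)
      attr(mat, "groups") <- groups
    } else {
      mat <- simulate_expression(
        n_probes = blk$n_probes,
        de_probes = unlist(blk$de_probes),
        n_arrays_a = if (is.null(blk$n_arrays_a)) 3 else blk$n_arrays_a,
        n_arrays_b = if (is.null(blk$n_arrays_b)) 5 else blk$n_arrays_b,
        noise_sd = if (is.null(blk$noise_sd)) 0.25 else blk$noise_sd,
        seed = seed + seed_offset)
    }
    mat <- normalize_percentile(mat)
    alpha <- if (is.null(net$alpha)) 0.03 else net$alpha
    select_de(mat, alpha = alpha)
  }
  de_a <- de_for(net$a, 101)
  de_b <- de_for(net$b, 202)
  map <- NULL
  if (!is.null(net$probe_to_gene)) {
    mp <- utils::read.table(net$probe_to_gene, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    map <- stats::setNames(mp[[2]], mp[[1]])
  }
  gene_de <- function(de) {
    if (!is.null(map)) collapse_probes(de, map)
    else transform(de, gene = probe)
  }
  ga <- gene_de(de_a); gb <- gene_de(de_b)
  fold_a <- stats::setNames(ga$log2_fold, ga$gene)
  fold_b <- stats::setNames(gb$log2_fold, gb$gene)
  seed_node <- net$seed_node
  targ <- function(g) intersect(g$gene[g$selected],
                                igraph::V(graph)$name)
  net_a <- shortest_paths_network(graph, seed_node, targ(ga),
                                  max_len = net$max_len)
  net_b <- shortest_paths_network(graph, seed_node, targ(gb),
                                  max_len = net$max_len)
  min_fold <- if (is.null(net$min_fold)) 2 else net$min_fold
  merged <- merge_networks(net_a, net_b, fold_a, fold_b,
                           min_fold = min_fold)
  write_merged_network(merged, file.path(out_dir, "merged_network"))
  logf("network stage: %d nodes, %d edges (%d common)",
       nrow(merged$nodes), nrow(merged$edges),
       sum(merged$edges$origin == "common"))
  invisible(merged)
}
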