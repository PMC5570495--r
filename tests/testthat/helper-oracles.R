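# Independent brute-force oracles and small fixture builders. These are
# deliberately written as plain loops with integer arithmetic, sharing
# no code with the package implementations they check.

# m-of-n replicate rule, expressed with exact integer fractions
# (m_num/m_den), e.g. 2/3 -> (2, 3).
oracle_validated <- function(values_list, mu, sd, k = 3,
                             m_num = 2, m_den = 3, ge = FALSE) {
  if (length(mu) == 1) mu <- rep(mu, length(values_list))
  if (length(sd) == 1) sd <- rep(sd, length(values_list))
  n_exp <- 0
  n_pass <- 0
  for (e in seq_along(values_list)) {
    v <- values_list[[e]]
    v <- v[!is.na(v)]
    if (length(v) == 0) next
    n_exp <- n_exp + 1
    thr <- mu[e] + k * sd[e]
    n_units <- 0
    for (x in v) {
      ok <- if (ge) x >= thr else x > thr
      if (ok) n_units <- n_units + 1
    }
    # ceiling(m_num * length(v) / m_den) without floating point
    need <- (m_num * length(v) + m_den - 1) %/% m_den
    if (n_units >= need) n_pass <- n_pass + 1
  }
  need_e <- (m_num * n_exp + m_den - 1) %/% m_den
  list(n_experiments = n_exp, n_pass = n_pass, hit = n_pass >= need_e)
}

# All simple directed paths from `from` to `to` over an edge data frame
# (source, target), by depth-first enumeration.
oracle_all_paths <- function(edges, from, to) {
  adj <- split(edges$target, edges$source)
  paths <- list()
  rec <- function(path) {
    last <- path[length(path)]
    if (last == to && length(path) > 1) {
      paths[[length(paths) + 1]] <<- path
      return(invisible(NULL))
    }
    for (nxt in adj[[last]]) {
      if (!nxt %in% path) rec(c(path, nxt))
    }
  }
  if (from %in% c(edges$source, edges$target) || from == to) rec(from)
  paths
}

# Edge set of the union of all shortest paths seed->t and t->seed,
# per target, from exhaustive path enumeration.
oracle_sp_edges <- function(edges, seed, targets) {
  src <- tgt <- character(0)
  for (t in setdiff(targets, seed)) {
    for (dirn in 1:2) {
      ps <- if (dirn == 1) oracle_all_paths(edges, seed, t)
            else oracle_all_paths(edges, t, seed)
      if (length(ps) == 0) next
      lens <- vapply(ps, length, integer(1))
      for (p in ps[lens == min(lens)]) {
        src <- c(src, p[-length(p)])
        tgt <- c(tgt, p[-1])
      }
    }
  }
  if (length(src) == 0)
    return(data.frame(source = character(0), target = character(0)))
  unique(data.frame(source = src, target = tgt,
                    stringsAsFactors = FALSE))
}

# Sorted "source->target" strings for set comparison.
edge_key <- function(df) sort(paste(df$source, df$target, sep = "->"))

# Random directed graph as an edge data frame.
rand_graph <- function(n_nodes, p_edge = 0.25) {
  nodes <- paste0("n", seq_len(n_nodes))
  grid <- expand.grid(source = nodes, target = nodes,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$source != grid$target, ]
  grid[stats::runif(nrow(grid)) < p_edge, , drop = FALSE]
}

# Minimal hand-built well table: one plate, scrambled controls with
# known mean/sd, plus library wells at given values.
tiny_wells <- function(scr_area = c(100, 110, 120),
                       scr_count = c(1000, 1100, 1200),
                       lib = NULL, cell_line = "HCT116",
                       experiment = 1L) {
  plate <- sprintf("%s_E%d_P1", cell_line, experiment)
  scr <- data.frame(plate_id = plate,
                    well_id = sprintf("S%02d", seq_along(scr_area)),
                    role = "scrambled", gene = "", sirna_id = "scr",
                    experiment = experiment, cell_line = cell_line,
                    nuclear_area = scr_area, object_count = scr_count,
                    stringsAsFactors = FALSE)
  if (is.null(lib)) return(scr)
  lib$plate_id <- plate
  lib$role <- "library"
  lib$experiment <- experiment
  lib$cell_line <- cell_line
  lib$well_id <- sprintf("L%02d", seq_len(nrow(lib)))
  rbind(scr, lib[names(scr)])
}

lib_rows <- function(gene, sirna_id, nuclear_area, object_count) {
  data.frame(gene = gene, sirna_id = sirna_id,
             nuclear_area = nuclear_area, object_count = object_count,
             stringsAsFactors = FALSE)
}
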