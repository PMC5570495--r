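#' Read a per-well measurement table
#'
#' Reads a delimited text export of per-well image-derived measurements.
#' The table must carry the identity columns `plate_id`, `well_id`,
#' `role`, `gene`, `sirna_id`, `experiment`, `cell_line`; every numeric
#' column after those is auto-detected as a marker (e.g. `nuclear_area`
#' in square microns, `object_count` in cells, `sabgal`, `p21`,
#' `bp1_foci`, `cytokine_<name>` in pg/mL). Empty marker cells are read
#' as `NA` and later excluded from means — never treated as zero, since
#' zero is a valid intensity.
#'
#' @param path path to the delimited file.
#' @param sep field delimiter; tab by default.
#' @return a `data.frame` of wells, one row per data row in file order,
#'   validated by [validate_wells()].
#' @seealso [write_well_table()], [simulate_screen()]
#' @export
read_well_table <- function(path, sep = "\t") {
  if (!file.exists(path)) .stopf("well table not found: %s", path)
  wells <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, check.names = FALSE,
                             na.strings = "", quote = "",
                             colClasses = NA, comment.char = "")
  missing <- setdiff(.id_cols, names(wells))
  if (length(missing) > 0)
    .stopf("format error: missing identity column(s): %s",
           paste(missing, collapse = ", "))
  for (col in c("plate_id", "well_id", "role", "gene", "sirna_id", "cell_line"))
    wells[[col]] <- ifelse(is.na(wells[[col]]), "", as.character(wells[[col]]))
  wells$experiment <- as.integer(wells$experiment)
  validate_wells(wells)
}

#' Validate a well table
#'
#' Checks the structural invariants of a well table: known roles,
#' experiment index at least 1, non-negative marker values, and
#' non-empty gene / siRNA identifiers for library wells.
#'
#' @param wells a well-table `data.frame`.
#' @return `wells`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_wells <- function(wells) {
  missing <- setdiff(.id_cols, names(wells))
  if (length(missing) > 0)
    .stopf("format error: missing identity column(s): %s",
           paste(missing, collapse = ", "))
  bad_role <- setdiff(unique(wells$role), .roles)
  if (length(bad_role) > 0)
    .stopf("validation error: unknown role(s): %s",
           paste(bad_role, collapse = ", "))
  if (any(is.na(wells$experiment)) || any(wells$experiment < 1))
    .stopf("validation error: experiment index must be an integer >= 1")
  markers <- well_markers(wells)
  if (length(markers) == 0)
    .stopf("format error: no numeric marker column found")
  for (m in markers) {
    neg <- which(!is.na(wells[[m]]) & wells[[m]] < 0)
    if (length(neg) > 0)
      .stopf("validation error: negative value for marker '%s' at row %d",
             m, neg[1])
  }
  lib <- wells$role == "library"
  bad <- which(lib & (wells$gene == "" | wells$sirna_id == ""))
  if (length(bad) > 0)
    .stopf("validation error: library well with empty gene/sirna_id at row %d",
           bad[1])
  wells
}

#' Write a per-well measurement table
#'
#' Tab-separated, UTF-8, `"."` decimal; missing marker values are written
#' as empty cells. Inverse of [read_well_table()] to at least six
#' significant digits.
#'
#' @param wells a validated well table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_well_table <- function(wells, path) {
  cols <- c(.id_cols, well_markers(wells))
  utils::write.table(wells[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a hit matrix
#'
#' Serialises validated-hit calls as a genes x (cell line, marker) table.
#' Each cell holds `"<n>;hit"` or `"<n>;miss"` where `<n>` is the number
#' of independent experiments in which the replicate rule passed — the
#' per-box counts of a screen heat-map. Combinations never scored are
#' left empty.
#'
#' @param calls a hit-call `data.frame` as produced by
#'   [validated_hits()]: columns `gene`, `cell_line`, `marker`,
#'   `n_experiments_pass`, `hit`.
#' @param path output path (TSV).
#' @return the wide `data.frame` written, invisibly.
#' @export
write_hit_matrix <- function(calls, path) {
  if (is.null(calls) || nrow(calls) == 0)
    .stopf("integrity error: no hit calls to write")
  key <- paste(calls$gene, calls$cell_line, calls$marker, sep = "\r")
  if (anyDuplicated(key))
    .stopf("integrity error: duplicate (gene, cell_line, marker) entry: %s",
           gsub("\r", "/", key[duplicated(key)][1]))
  genes <- sort(unique(calls$gene))
  combo <- unique(calls[c("cell_line", "marker")])
  combo <- combo[order(combo$cell_line, combo$marker), , drop = FALSE]
  cn <- paste(combo$cell_line, combo$marker, sep = "|")
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (j in seq_len(nrow(combo))) out[[cn[j]]] <- ""
  cell <- paste0(calls$n_experiments_pass, ";",
                 ifelse(calls$hit, "hit", "miss"))
  for (i in seq_len(nrow(calls))) {
    col <- paste(calls$cell_line[i], calls$marker[i], sep = "|")
    out[out$gene == calls$gene[i], col] <- cell[i]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(out)
}

#' Read a directed interaction graph from a SIF-like TSV
#'
#' Expects three tab-separated columns: source, interaction effect,
#' target. Effects other than `activation` / `inhibition` are kept as
#' `unspecified`. Self-loops are allowed but flagged with a warning.
#'
#' @param path path to the edge list.
#' @return an `igraph` directed graph with an `effect` edge attribute.
#' @seealso [write_sif()], [shortest_paths_network()]
#' @export
read_sif <- function(path) {
  if (!file.exists(path)) .stopf("interaction graph not found: %s", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          col.names = c("source", "effect", "target"))
  as_interaction_graph(df)
}

#' Build an interaction graph from an edge data frame
#'
#' @param edges `data.frame` with columns `source`, `effect`, `target`
#'   (or `source`, `target` — effect defaults to `unspecified`).
#' @return an `igraph` directed graph with an `effect` edge attribute.
#' @export
as_interaction_graph <- function(edges) {
  if (!"effect" %in% names(edges)) edges$effect <- "unspecified"
  edges$effect <- ifelse(edges$effect %in% c("activation", "inhibition"),
                         edges$effect, "unspecified")
  if (any(edges$source == edges$target))
    .warnf("interaction graph contains %d self-loop(s)",
           sum(edges$source == edges$target))
  g <- igraph::graph_from_data_frame(
    edges[c("source", "target", "effect")], directed = TRUE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = FALSE,
                   edge.attr.comb = "first")
}

#' Write an interaction (sub)graph as SIF-like TSV
#'
#' @param net an `igraph` graph with an `effect` edge attribute, or an
#'   edge `data.frame` with `source`, `effect`, `target` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path) {
  if (inherits(net, "igraph")) {
    el <- igraph::as_data_frame(net, what = "edges")
    df <- data.frame(source = el$from,
                     effect = if ("effect" %in% names(el)) el$effect
                              else "unspecified",
                     target = el$to, stringsAsFactors = FALSE)
  } else {
    df <- net[c("source", "effect", "target")]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an expression matrix (probes x arrays) from TSV
#'
#' First column is the probe id; remaining columns are arrays. Group
#' membership is carried separately (see [select_de()]).
#'
#' @param path path to the TSV.
#' @return numeric matrix with probe rownames and array colnames.
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write an expression matrix to TSV
#'
#' @param mat numeric matrix, probes x arrays.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(probe = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
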