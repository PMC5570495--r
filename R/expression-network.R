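#' Percentile normalisation of an expression matrix
#'
#' Intra-array normalisation: from every array (column), subtract that
#' array's `pct`-th percentile of log2 intensity, so that after
#' normalisation each array's `pct`-th percentile is exactly zero. The
#' percentile is the linear-interpolation order-statistic estimator
#' (R's quantile type 7), fixed so results are reproducible
#' bit-for-bit. Idempotent, and invariant to per-array additive
#' offsets.
#'
#' @param mat numeric matrix, probes x arrays, of log2 intensities.
#' @param pct percentile in (0, 100); default 75.
#' @return normalised matrix (attributes preserved).
#' @export
normalize_percentile <- function(mat, pct = 75) {
  stopifnot(is.matrix(mat), pct > 0, pct < 100)
  q <- apply(mat, 2, function(col) {
    col <- col[is.finite(col)]
    if (length(col) == 0)
      .stopf("array with no finite values cannot be normalised")
    stats::quantile(col, probs = pct / 100, type = 7, names = FALSE)
  })
  out <- sweep(mat, 2, q, "-")
  attributes(out)[setdiff(names(attributes(mat)),
                          c("dim", "dimnames"))] <-
    attributes(mat)[setdiff(names(attributes(mat)), c("dim", "dimnames"))]
  out
}

#' Differential expression by unpaired t-test
#'
#' Per-probe two-sample unpaired t-test between array groups A and B on
#' log2 intensities, Welch (unequal-variance) form by default; probes
#' with `p < alpha` are selected. The log2 fold is `mean_A - mean_B`
#' (A = treatment). When either group has a single array the Welch
#' statistic is undefined; the variance is then borrowed from the
#' larger group (pooled form on that group's degrees of freedom) with a
#' warning. Probes with zero variance in both groups get `p = 1` when
#' the means are equal and `p = 0` otherwise.
#'
#' @param mat numeric matrix, probes x arrays (normalised log2).
#' @param group_a,group_b column names (or indices) of the two groups;
#'   default taken from the matrix's `groups` attribute.
#' @param alpha selection threshold on the two-sided p-value
#'   (default 0.03).
#' @param var_equal use the pooled-variance (Student) form instead of
#'   Welch.
#' @return `data.frame`: `probe`, `mean_a`, `mean_b`, `log2_fold`,
#'   `t`, `df`, `p_value`, `selected`.
#' @export
select_de <- function(mat, group_a = NULL, group_b = NULL, alpha = 0.03,
                      var_equal = FALSE) {
  grp <- attr(mat, "groups")
  if (is.null(group_a)) group_a <- grp$A
  if (is.null(group_b)) group_b <- grp$B
  if (is.null(group_a) || is.null(group_b))
    .stopf("array groups must be given or carried by the matrix")
  a <- mat[, group_a, drop = FALSE]
  b <- mat[, group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  if (max(na, nb) < 2)
    .stopf("at least one group needs >= 2 arrays")
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- if (na > 1) apply(a, 1, stats::var) else rep(NA_real_, nrow(a))
  vb <- if (nb > 1) apply(b, 1, stats::var) else rep(NA_real_, nrow(b))
  if (na == 1 || nb == 1) {
    .warnf("group with a single array: variance borrowed from the larger group")
    s2 <- if (na == 1) vb else va
    se2 <- s2 * (1 / na + 1 / nb)
    df <- max(na, nb) - 1
    tt <- (ma - mb) / sqrt(se2)
    df <- rep(df, length(tt))
  } else if (var_equal) {
    s2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- s2 * (1 / na + 1 / nb)
    tt <- (ma - mb) / sqrt(se2)
    df <- rep(na + nb - 2, length(tt))
  } else {
    se2 <- va / na + vb / nb
    tt <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  p <- 2 * stats::pt(-abs(tt), df)
  degenerate <- !is.finite(tt)
  if (any(degenerate)) {
    eq <- degenerate & (abs(ma - mb) < .Machine$double.eps^0.5)
    p[degenerate] <- ifelse(eq[degenerate], 1, 0)
    tt[degenerate] <- 0
  }
  data.frame(probe = rownames(mat), mean_a = ma, mean_b = mb,
             log2_fold = ma - mb, t = tt, df = df, p_value = p,
             selected = p < alpha, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Collapse probe-level selections to genes
#'
#' Multi-probe genes are represented by their most significant probe
#' (smallest p-value; ties broken by larger absolute fold, then probe
#' id).
#'
#' @param de output of [select_de()].
#' @param probe_to_gene named character vector: probe id -> gene symbol.
#'   Probes without a mapping are dropped.
#' @return `de` restricted to one row per gene, with a `gene` column.
#' @export
collapse_probes <- function(de, probe_to_gene) {
  de$gene <- unname(probe_to_gene[de$probe])
  de <- de[!is.na(de$gene), , drop = FALSE]
  ord <- order(de$gene, de$p_value, -abs(de$log2_fold), de$probe)
  de <- de[ord, , drop = FALSE]
  de <- de[!duplicated(de$gene), , drop = FALSE]
  rownames(de) <- NULL
  de
}

#' Seed-anchored shortest-paths subnetwork
#'
#' From a directed interaction graph, extracts the union over targets
#' of ALL shortest directed paths (path length = edge count) from the
#' seed node to each target and from each target back to the seed.
#' Ties are all retained. Targets absent from the graph are skipped
#' with a warning; present but unreachable targets are annotated.
#'
#' @param graph an `igraph` directed graph (see
#'   [as_interaction_graph()]).
#' @param seed_node the seed gene (e.g. the knocked-down gene) the
#'   network is built out from.
#' @param targets node ids to connect to the seed (e.g. differentially
#'   expressed genes).
#' @param max_len optional cap on path length (edges); paths longer
#'   than this are dropped even if shortest.
#' @param mode `"both"` (default: seed->target and target->seed),
#'   `"out"`, `"in"`, or `"undirected"`.
#' @return list of class `sp_network`: `edges` (`data.frame` `source`,
#'   `target`, `effect`), `nodes`, `seed`, `targets`, `unreachable`,
#'   `distance` (named, edge counts seed->target where finite).
#' @export
shortest_paths_network <- function(graph, seed_node, targets,
                                   max_len = NULL,
                                   mode = c("both", "out", "in",
                                            "undirected")) {
  mode <- match.arg(mode)
  vn <- igraph::V(graph)$name
  if (!seed_node %in% vn) .stopf("seed node '%s' not in graph", seed_node)
  targets <- setdiff(unique(targets), seed_node)
  missing <- setdiff(targets, vn)
  if (length(missing) > 0) {
    .warnf("skipping %d target(s) not in graph: %s", length(missing),
           paste(utils::head(missing, 5), collapse = ", "))
    targets <- intersect(targets, vn)
  }
  collect <- function(g, from, to, m) {
    # all shortest paths from `from` to each node of `to`, as vertex-name
    # sequences
    res <- suppressWarnings(
      igraph::all_shortest_paths(g, from = from, to = to, mode = m))
    vp <- res$vpaths
    if (is.null(vp)) vp <- res$res
    lapply(vp, function(p) names(p))
  }
  paths <- list()
  for (t in targets) {
    ps <- list()
    if (mode %in% c("both", "out"))
      ps <- c(ps, collect(graph, seed_node, t, "out"))
    if (mode %in% c("both", "in")) {
      back <- collect(graph, t, seed_node, "out")
      ps <- c(ps, back)
    }
    if (mode == "undirected")
      ps <- collect(graph, seed_node, t, "all")
    ps <- ps[lengths(ps) >= 2]
    if (!is.null(max_len))
      ps <- ps[lengths(ps) - 1 <= max_len]
    paths <- c(paths, ps)
  }
  # collapse to an edge set
  src <- tgt <- character(0)
  for (p in paths) {
    src <- c(src, p[-length(p)])
    tgt <- c(tgt, p[-1])
  }
  edges <- unique(data.frame(source = src, target = tgt,
                             stringsAsFactors = FALSE))
  if (mode == "undirected" && nrow(edges) > 0) {
    # orient each traversed edge as it exists in the directed graph
    fwd <- igraph::are_adjacent
    keep <- mapply(function(s, t) fwd(graph, s, t), edges$source,
                   edges$target)
    flipped <- edges[!keep, c("target", "source")]
    names(flipped) <- c("source", "target")
    edges <- unique(rbind(edges[keep, ], flipped))
  }
  eff <- character(nrow(edges))
  if (nrow(edges) > 0) {
    eids <- igraph::get_edge_ids(graph,
                                 rbind(edges$source, edges$target))
    eff <- igraph::E(graph)$effect[eids]
    if (is.null(eff)) eff <- rep("unspecified", nrow(edges))
  }
  edges$effect <- eff
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  reach <- vapply(targets, function(t)
    any(vapply(paths, function(p)
      p[1] == t || p[length(p)] == t, logical(1))), logical(1))
  dist_out <- igraph::distances(graph, v = seed_node, to = targets,
                                mode = "out")
  structure(list(edges = edges,
                 nodes = sort(unique(c(seed_node, edges$source,
                                       edges$target))),
                 seed = seed_node, targets = targets,
                 unreachable = targets[!reach],
                 distance = stats::setNames(as.numeric(dist_out),
                                            targets)),
            class = "sp_network")
}

#' @export
print.sp_network <- function(x, ...) {
  cat("Shortest-paths subnetwork\n")
  cat("  seed:", x$seed, "\n")
  cat("  targets:", length(x$targets),
      sprintf("(%d unreachable)", length(x$unreachable)), "\n")
  cat("  nodes:", length(x$nodes), " edges:", nrow(x$edges), "\n")
  invisible(x)
}

#' Merge two condition subnetworks with expression overlay
#'
#' Takes the union of two seed-anchored subnetworks built on the same
#' graph namespace, labels every edge by origin (`A_specific`,
#' `B_specific`, `common`), and overlays per-condition expression folds
#' on nodes. A node's overlay is reported only when its absolute linear
#' fold reaches `min_fold` (inclusive); smaller changes are shown as
#' unmarked.
#'
#' @param net_a,net_b `sp_network` objects for conditions A and B.
#' @param overlay_a,overlay_b named numeric vectors of log2 folds per
#'   node for each condition (optional).
#' @param min_fold minimum linear fold for a node mark (default 2).
#' @param labels length-2 character vector naming the conditions.
#' @return list of class `merged_network`: `edges` (`source`, `target`,
#'   `effect`, `origin`), `nodes` (`node`, `log2_fold_a`, `log2_fold_b`,
#'   `mark_a`, `mark_b` in `{"up", "down", ""}`), `labels`.
#' @export
merge_networks <- function(net_a, net_b, overlay_a = NULL,
                           overlay_b = NULL, min_fold = 2,
                           labels = c("A", "B")) {
  stopifnot(inherits(net_a, "sp_network"), inherits(net_b, "sp_network"))
  ids <- unique(c(net_a$nodes, net_b$nodes))
  if (length(ids) != length(unique(tolower(ids))))
    .warnf("node ids differing only by case across networks")
  key <- function(n) paste(n$edges$source, n$edges$target, sep = "\r")
  ka <- key(net_a); kb <- key(net_b)
  all_edges <- unique(rbind(net_a$edges, net_b$edges))
  k <- paste(all_edges$source, all_edges$target, sep = "\r")
  origin <- ifelse(k %in% ka & k %in% kb, "common",
                   ifelse(k %in% ka, paste0(labels[1], "_specific"),
                          paste0(labels[2], "_specific")))
  all_edges$origin <- origin
  all_edges <- all_edges[order(all_edges$source, all_edges$target), ]
  rownames(all_edges) <- NULL
  nodes <- sort(unique(c(net_a$nodes, net_b$nodes)))
  get_fold <- function(ov) {
    f <- rep(NA_real_, length(nodes))
    if (!is.null(ov)) f <- unname(ov[nodes])
    f
  }
  fa <- get_fold(overlay_a); fb <- get_fold(overlay_b)
  mark <- function(f) {
    ifelse(is.na(f) | 2^abs(f) < min_fold, "",
           ifelse(f > 0, "up", "down"))
  }
  structure(list(edges = all_edges,
                 nodes = data.frame(node = nodes, log2_fold_a = fa,
                                    log2_fold_b = fb, mark_a = mark(fa),
                                    mark_b = mark(fb),
                                    stringsAsFactors = FALSE),
                 labels = labels),
            class = "merged_network")
}

#' @export
print.merged_network <- function(x, ...) {
  tab <- table(x$edges$origin)
  cat("Merged condition network (", paste(x$labels, collapse = " vs "),
      ")\n", sep = "")
  cat("  nodes:", nrow(x$nodes), " edges:", nrow(x$edges), "\n")
  for (o in names(tab)) cat(sprintf("    %s: %d\n", o, tab[[o]]))
  invisible(x)
}

#' Write a merged network for external viewers
#'
#' Emits the edge list (with origin) as SIF-like TSV, the node overlay
#' as TSV, and a GraphML file readable by Cytoscape-class viewers.
#'
#' @param mnet a `merged_network`.
#' @param basename output path prefix; writes `<basename>.sif.tsv`,
#'   `<basename>.nodes.tsv`, `<basename>.graphml`.
#' @return character vector of the paths written, invisibly.
#' @export
write_merged_network <- function(mnet, basename) {
  stopifnot(inherits(mnet, "merged_network"))
  sif <- paste0(basename, ".sif.tsv")
  utils::write.table(mnet$edges, sif, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  nod <- paste0(basename, ".nodes.tsv")
  utils::write.table(mnet$nodes, nod, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  gml <- paste0(basename, ".graphml")
  g <- igraph::graph_from_data_frame(
    mnet$edges, directed = TRUE,
    vertices = mnet$nodes[!is.na(mnet$nodes$node), , drop = FALSE])
  igraph::write_graph(g, gml, format = "graphml")
  invisible(c(sif, nod, gml))
}
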