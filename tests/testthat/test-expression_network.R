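test_that("percentile normalisation zeroes each array's percentile", {
  m <- cbind(a1 = c(1, 2, 3, 4), a2 = c(11, 12, 13, 14))
  n <- normalize_percentile(m)
  # type-7 75th percentile of {1,2,3,4} is 3.25
  expect_equal(n[, "a1"], c(1, 2, 3, 4) - 3.25)
  expect_equal(apply(n, 2, quantile, probs = 0.75, names = FALSE),
               c(a1 = 0, a2 = 0), tolerance = 1e-9)
  # arrays differing by a constant offset coincide afterwards
  expect_equal(n[, "a1"], n[, "a2"])
})

test_that("normalisation is idempotent on random matrices", {
  set.seed(141)
  for (rep in 1:10) {
    m <- matrix(rnorm(20 * 6, 8, 2), 20, 6,
                dimnames = list(NULL, paste0("a", 1:6)))
    n1 <- normalize_percentile(m)
    expect_equal(normalize_percentile(n1), n1, tolerance = 1e-12)
  }
  expect_error(normalize_percentile(cbind(a = rep(NA_real_, 3))), "finite")
})

test_that("identical groups give p = 1 and are never selected", {
  m <- matrix(rep(c(5, 6, 7), each = 6), 3, 6, byrow = TRUE,
              dimnames = list(paste0("p", 1:3), paste0("a", 1:6)))
  de <- select_de(m, group_a = paste0("a", 1:3), group_b = paste0("a", 4:6))
  expect_equal(de$p_value, rep(1, 3))
  expect_false(any(de$selected))
})

test_that("Welch and pooled t match stats::t.test on random matrices", {
  set.seed(151)
  for (rep in 1:20) {
    m <- matrix(rnorm(15 * 8, 8, 1), 15, 8,
                dimnames = list(paste0("p", 1:15), paste0("a", 1:8)))
    ga <- paste0("a", 1:3); gb <- paste0("a", 4:8)
    for (ve in c(FALSE, TRUE)) {
      de <- select_de(m, ga, gb, var_equal = ve)
      i <- sample(15, 3)
      for (j in i) {
        tt <- t.test(m[j, ga], m[j, gb], var.equal = ve)
        expect_equal(de$p_value[j], unname(tt$p.value), tolerance = 1e-10)
        expect_equal(de$t[j], unname(tt$statistic), tolerance = 1e-10)
        expect_equal(de$log2_fold[j],
                     unname(tt$estimate[1] - tt$estimate[2]))
      }
    }
  }
})

test_that("a single-array group falls back to the larger group's variance", {
  set.seed(161)
  m <- matrix(rnorm(10 * 3, 8, 1), 10, 3,
              dimnames = list(paste0("p", 1:10), c("a1", "b1", "b2")))
  expect_warning(de <- select_de(m, "a1", c("b1", "b2")), "single array")
  expect_true(all(is.finite(de$p_value)))
  expect_true(all(de$df == 1))
})

test_that("null selection fraction is near alpha (small calibration run)", {
  set.seed(171)
  frac <- mean(replicate(50, {
    m <- simulate_expression(100, noise_sd = 0.1,
                             seed = sample.int(1e6, 1))
    de <- select_de(normalize_percentile(m))
    mean(de$selected)
  }))
  expect_lt(abs(frac - 0.03), 0.012)
})

test_that("a 2.2-fold knockdown probe is selected near its true ratio", {
  set.seed(181)
  ratios <- replicate(20, {
    m <- simulate_expression(100, c(probe0001 = -1.15), noise_sd = 0.05,
                             seed = sample.int(1e6, 1))
    de <- select_de(normalize_percentile(m))
    expect_true(de$selected[de$probe == "probe0001"])
    2^de$log2_fold[de$probe == "probe0001"]
  })
  expect_gt(mean(ratios), 0.40)
  expect_lt(mean(ratios), 0.50)
})

test_that("probe collapse keeps each gene's most significant probe", {
  de <- data.frame(probe = paste0("p", 1:4),
                   log2_fold = c(1, -2, 0.5, 3),
                   p_value = c(0.01, 0.001, 0.5, 0.2),
                   selected = c(TRUE, TRUE, FALSE, FALSE))
  map <- c(p1 = "G1", p2 = "G1", p3 = "G2", p4 = NA)
  got <- collapse_probes(de, map)
  expect_equal(got$gene, c("G1", "G2"))
  expect_equal(got$probe, c("p2", "p3"))
})

test_that("a chain and a tied pair of paths are extracted in full", {
  edges <- data.frame(source = c("S", "A", "S", "X", "S", "Y"),
                      effect = "activation",
                      target = c("A", "B", "X", "T", "Y", "T"))
  g <- as_interaction_graph(edges)
  chain <- shortest_paths_network(g, "S", "B")
  expect_equal(edge_key(chain$edges), c("A->B", "S->A"))
  expect_equal(unname(chain$distance["B"]), 2)
  ties <- shortest_paths_network(g, "S", "T")
  expect_equal(edge_key(ties$edges), c("S->X", "S->Y", "X->T", "Y->T"))
  expect_error(shortest_paths_network(g, "NOPE", "T"), "seed node")
})

test_that("both orientations are walked and unreachable targets annotated", {
  edges <- data.frame(source = c("S", "T", "U"), effect = "activation",
                      target = c("T", "S", "S"))
  g <- as_interaction_graph(edges)
  net <- shortest_paths_network(g, "S", c("T", "U"))
  # S->T, T->S, and U->S (U reachable backwards only)
  expect_equal(edge_key(net$edges), c("S->T", "T->S", "U->S"))
  expect_equal(net$unreachable, character(0))
  fwd_only <- shortest_paths_network(g, "S", c("T", "U"), mode = "out")
  expect_equal(fwd_only$unreachable, "U")
})

test_that("max_len caps path length monotonically", {
  edges <- data.frame(source = c("S", "A", "B"), effect = "activation",
                      target = c("A", "B", "T"))
  g <- as_interaction_graph(edges)
  n1 <- shortest_paths_network(g, "S", "T", max_len = 2)
  expect_equal(nrow(n1$edges), 0)
  n2 <- shortest_paths_network(g, "S", "T", max_len = 3)
  expect_equal(nrow(n2$edges), 3)
  expect_true(all(edge_key(n1$edges) %in% edge_key(n2$edges)))
})

test_that("subnetworks equal exhaustive path enumeration on random graphs", {
  set.seed(191)
  for (rep in 1:30) {
    edges <- rand_graph(sample(4:10, 1), p_edge = 0.25)
    if (nrow(edges) == 0) next
    nodes <- unique(c(edges$source, edges$target))
    seed_node <- sample(nodes, 1)
    targets <- sample(setdiff(nodes, seed_node),
                      min(3, length(nodes) - 1))
    g <- as_interaction_graph(edges)
    got <- suppressWarnings(
      shortest_paths_network(g, seed_node, targets))
    want <- oracle_sp_edges(edges, seed_node, targets)
    expect_equal(edge_key(got$edges), edge_key(want))
  }
})

test_that("merged networks label edge origin and respect the fold floor", {
  edges <- data.frame(source = c("S", "S", "A", "B"), effect = "activation",
                      target = c("A", "B", "T", "T"))
  g <- as_interaction_graph(edges)
  net_a <- shortest_paths_network(g, "S", "T")
  net_b <- shortest_paths_network(g, "S", "A")
  m <- merge_networks(net_a, net_b,
                      overlay_a = c(T = log2(2), A = log2(1.5)),
                      overlay_b = c(A = -1.2))
  ek <- paste(m$edges$source, m$edges$target, sep = "->")
  expect_equal(m$edges$origin[ek == "S->A"], "common")
  expect_equal(m$edges$origin[ek == "A->T"], "A_specific")
  nd <- m$nodes
  expect_equal(nd$mark_a[nd$node == "T"], "up")     # exactly 2-fold: marked
  expect_equal(nd$mark_a[nd$node == "A"], "")       # 1.5-fold: below floor
  expect_equal(nd$mark_b[nd$node == "A"], "down")   # 2^1.2 > 2
  # swapping arguments swaps the specific labels, common stays common
  m2 <- merge_networks(net_b, net_a)
  ek2 <- paste(m2$edges$source, m2$edges$target, sep = "->")
  expect_equal(m2$edges$origin[ek2 == "S->A"], "common")
  expect_equal(m2$edges$origin[ek2 == "A->T"], "B_specific")
  # self-merge: everything common, node set preserved
  m3 <- merge_networks(net_a, net_a)
  expect_true(all(m3$edges$origin == "common"))
  expect_equal(m3$nodes$node, sort(net_a$nodes))
})

test_that("merged networks serialise to SIF, node table and GraphML", {
  edges <- data.frame(source = c("S", "A"), effect = "activation",
                      target = c("A", "T"))
  g <- as_interaction_graph(edges)
  net <- shortest_paths_network(g, "S", "T")
  m <- merge_networks(net, net, overlay_a = c(T = 2))
  base <- withr::local_tempfile()
  paths <- write_merged_network(m, base)
  expect_true(all(file.exists(paths)))
  expect_match(readLines(paths[3], n = 2)[1], "xml", ignore.case = TRUE)
})
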