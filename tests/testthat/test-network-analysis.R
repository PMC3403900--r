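test_that("the largest weak component is extracted deterministically", {
  # components of 8 and 3 nodes: keep the 8
  big <- edges_df(paste0("TF", c(1, 1, 1, 2, 2, 3, 3)),
                  paste0("g", 1:7))
  big$regulator_class <- "TF"
  big <- rbind(big, edges_df("TF1", "TF2", to_class = "TF"),
               edges_df("TF1", "TF3", to_class = "TF"))
  small <- edges_df(c("TF9", "TF9"), c("g8", "g9"))
  net <- make_grn(rbind(big, small))
  comp <- largest_component(net)
  expect_equal(nrow(comp$nodes), 10)
  expect_false("TF9" %in% comp$nodes$id)
  expect_equal(attr(comp, "component_fraction"), 10 / 13)

  # a connected network is unchanged
  again <- largest_component(comp)
  expect_equal(sort(again$nodes$id), sort(comp$nodes$id))
  expect_equal(attr(again, "component_fraction"), 1)

  # size tie: the component holding the lexicographically smallest id wins
  tie <- make_grn(rbind(edges_df("g8", c("g2", "g3")),
                        edges_df("g9", c("g1", "g4"))))
  kept <- largest_component(tie)
  expect_setequal(kept$nodes$id, c("g9", "g1", "g4"))  # "g1" beats "g2"
})

test_that("walktrap separates planted communities", {
  # two 10-cliques joined by one edge
  g <- igraph::disjoint_union(igraph::make_full_graph(10),
                              igraph::make_full_graph(10))
  g <- igraph::add_edges(g, c(1, 11))
  igraph::V(g)$name <- sprintf("v%02d", 1:20)
  part <- detect_modules(g)
  expect_equal(length(part$sizes), 2)
  expect_equal(sort(part$sizes), c(10, 10))
  expect_equal(length(unique(part$assignment[1:10])), 1)

  # complete graph: a single module
  full <- igraph::make_full_graph(8)
  igraph::V(full)$name <- paste0("n", 1:8)
  expect_equal(length(detect_modules(full)$sizes), 1)

  # planted partition benchmark, scored by adjusted Rand index
  bench <- generate_modular_graph(c(30, 30, 30), p_in = 0.5, p_out = 0.01,
                                  seed = 17)
  part <- detect_modules(bench$graph)
  ari <- mclust::adjustedRandIndex(part$assignment[names(bench$labels)],
                                   bench$labels)
  expect_gt(ari, 0.8)
})

test_that("module partitions beat the trivial partition and cover all nodes", {
  bench <- generate_modular_graph(c(20, 20), p_in = 0.6, p_out = 0.05, seed = 3)
  part <- detect_modules(bench$graph)
  expect_equal(sum(part$sizes), igraph::vcount(bench$graph))
  expect_length(part$assignment, igraph::vcount(bench$graph))
  trivial <- igraph::modularity(bench$graph,
                                rep(1, igraph::vcount(bench$graph)),
                                weights = igraph::E(bench$graph)$weight)
  expect_gte(part$modularity, trivial)
})

test_that("edge betweenness counts tied shortest paths fractionally", {
  # path A -> B -> C: both edges serve 2 ordered pairs
  path <- igraph::graph_from_edgelist(rbind(c("A", "B"), c("B", "C")),
                                      directed = TRUE)
  eb <- edge_betweenness_scores(path)
  expect_equal(unname(eb), c(2, 2))
  expect_equal(names(eb), c("A->B", "B->C"))

  # directed triangle: full symmetry (each edge serves 3 ordered pairs)
  tri <- igraph::graph_from_edgelist(rbind(c("A", "B"), c("B", "C"), c("C", "A")),
                                     directed = TRUE)
  expect_equal(unname(edge_betweenness_scores(tri)), rep(3, 3))

  # random digraphs against the exhaustive enumeration oracle
  for (s in 1:20) {
    g <- random_digraph(sample(4:8, 1), 0.35, seed = 300 + s)
    if (igraph::ecount(g) == 0) next
    expect_equal(unname(edge_betweenness_scores(g)), brute_edge_betweenness(g),
                 tolerance = 1e-12)
  }
})

test_that("total betweenness equals the sum of pairwise shortest-path lengths", {
  for (s in 1:5) {
    g <- random_digraph(7, 0.3, seed = 50 + s)
    if (igraph::ecount(g) == 0) next
    d <- igraph::distances(g, mode = "out")
    diag(d) <- Inf
    expect_equal(sum(edge_betweenness_scores(g)), sum(d[is.finite(d)]),
                 tolerance = 1e-10)
  }
})

test_that("core extraction keeps the edges strictly above the betweenness quantile", {
  # 200 edges with distinct betweenness values: the 99% quantile keeps 2
  edges <- edges_df(paste0("TF", sprintf("%03d", 1:200)),
                    paste0("g", sprintf("%03d", 1:200)))
  net <- make_grn(edges)
  eb_order <- paste0(net$edges$regulator, "->", net$edges$target)
  fake_eb <- setNames(as.numeric(1:200), eb_order)
  # the selected edges end in gene nodes, which the core should not touch
  expect_warning(core <- extract_core(net, quantile = 0.99, betweenness = fake_eb),
                 "non-regulator")
  expect_equal(nrow(core$edges), 2)
  expect_equal(core$edge_fraction, 0.01)
  expect_true(all(core$edges$betweenness > core$threshold))

  # quantile 0 keeps everything above the minimum
  suppressWarnings(core0 <- extract_core(net, quantile = 0, betweenness = fake_eb))
  expect_equal(nrow(core0$edges), 199)

  expect_error(extract_core(net, quantile = 1), "quantile")
  expect_error(extract_core(net, quantile = -0.1), "quantile")
})

test_that("core edges over-represent betweenness on a scale-free network", {
  g <- generate_scalefree_digraph(400, 1000, seed = 4)
  el <- igraph::as_edgelist(g)
  edges <- edges_df(el[, 1], el[, 2], from_class = "TF", to_class = "gene")
  # regulator class wins for nodes that appear on both sides
  net <- make_grn(edges)
  eb <- edge_betweenness_scores(net)
  suppressWarnings(core <- extract_core(net, 0.99, eb))
  expect_gte(core$betweenness_fraction, core$edge_fraction)
  expect_gt(core$betweenness_fraction, 0)
  expect_true(core$edge_fraction >= 0.005 && core$edge_fraction <= 0.015)
})

test_that("feedforward and feedback loops are counted per motif", {
  ffl <- igraph::graph_from_edgelist(rbind(c("A", "B"), c("B", "C"), c("A", "C")),
                                     directed = TRUE)
  expect_equal(count_loops(ffl), c(feedforward = 1L, feedback = 0L))

  two <- igraph::graph_from_edgelist(rbind(c("A", "B"), c("B", "A")),
                                     directed = TRUE)
  expect_equal(count_loops(two), c(feedforward = 0L, feedback = 1L))

  for (s in 1:6) {
    g <- random_digraph(10, 0.25, seed = 900 + s)
    expect_equal(count_loops(g), brute_count_loops(g))
  }
})

test_that("removing the core rarely disconnects the global network", {
  intact <- 0L
  n_seeds <- 10L
  for (s in seq_len(n_seeds)) {
    g <- generate_scalefree_digraph(600, 1500, seed = 700 + s)
    eb <- edge_betweenness_scores(g)
    thr <- quantile(eb, 0.99, names = FALSE)
    before <- igraph::count_components(g, mode = "weak")
    pruned <- igraph::delete_edges(g, which(eb > thr))
    after <- igraph::count_components(pruned, mode = "weak")
    if (before == after) intact <- intact + 1L
  }
  expect_gte(intact, ceiling(0.9 * n_seeds))
})
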