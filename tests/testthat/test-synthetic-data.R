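test_that("the generator is fully deterministic under a fixed seed", {
  cfg <- synthetic_config(n_genes = 60, n_tfs = 6, n_mirnas = 4, seed = 33)
  a <- generate_panel(cfg)
  b <- generate_panel(cfg)
  expect_identical(a, b)

  g1 <- generate_scalefree_digraph(50, 120, seed = 2)
  g2 <- generate_scalefree_digraph(50, 120, seed = 2)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))

  m1 <- generate_modular_graph(c(10, 10), 0.8, 0.1, seed = 2)
  m2 <- generate_modular_graph(c(10, 10), 0.8, 0.1, seed = 2)
  expect_identical(igraph::as_edgelist(m1$graph), igraph::as_edgelist(m2$graph))
  expect_identical(igraph::E(m1$graph)$weight, igraph::E(m2$graph)$weight)
})

test_that("configuration validation rejects out-of-range parameters", {
  expect_error(synthetic_config(tf_signal = 1.2), "\\(0, 1\\)")
  expect_error(synthetic_config(mirna_signal = 0), "\\(0, 1\\)")
  expect_error(synthetic_config(decoy_edge_fraction = 1), "decoy")
  expect_error(synthetic_config(n_genes = 0), "positive")
  expect_error(generate_scalefree_digraph(10, 5), "n_edges")
  expect_error(generate_modular_graph(c(5, 5), 0.1, 0.5), "exceed")
})

test_that("without decoys every candidate edge is a planted edge", {
  b <- generate_panel(synthetic_config(n_genes = 80, n_tfs = 8, n_mirnas = 6,
                                       decoy_edge_fraction = 0, seed = 2))
  expect_setequal(paste(b$interactions$regulator, b$interactions$target),
                  paste(b$truth$true_edges$regulator, b$truth$true_edges$target))
})

test_that("planted miRNA correlations come out negative at the planted magnitude", {
  b <- generate_panel(synthetic_config(n_genes = 400, n_tfs = 15, n_mirnas = 15,
                                       mirna_signal = 0.9, outlier_fraction = 0,
                                       seed = 8))
  lr <- log2(b$panel$tu / b$panel$an)
  rownames(lr) <- b$panel$probe_map$entity_id
  mir_edges <- b$truth$true_edges[grepl("^mir", b$truth$true_edges$regulator), ]
  expect_gte(nrow(mir_edges), 100)
  r <- vapply(seq_len(nrow(mir_edges)), function(i) {
    cor(lr[mir_edges$regulator[i], ], lr[mir_edges$target[i], ])
  }, numeric(1))
  expect_true(all(r < 0))
  expect_lt(abs(mean(abs(r)) - 0.9), 0.1)
})

test_that("empirical correlations converge to the planted values", {
  b <- generate_panel(synthetic_config(n_genes = 200, n_tfs = 10, n_mirnas = 8,
                                       n_patients = 500, outlier_fraction = 0,
                                       seed = 12))
  lr <- log2(b$panel$tu / b$panel$an)
  rownames(lr) <- b$panel$probe_map$entity_id
  te <- b$truth$true_edges
  r <- vapply(seq_len(nrow(te)), function(i) {
    cor(lr[te$regulator[i], ], lr[te$target[i], ])
  }, numeric(1))
  expect_lt(mean(abs(r - te$planted_r)), 0.05)
})

test_that("strong planted miRNA edges almost never flip sign at cohort size", {
  b <- generate_panel(synthetic_config(n_genes = 500, n_tfs = 10, n_mirnas = 20,
                                       mirna_signal = 0.5, n_patients = 96,
                                       outlier_fraction = 0, seed = 14))
  lr <- log2(b$panel$tu / b$panel$an)
  rownames(lr) <- b$panel$probe_map$entity_id
  mir_edges <- b$truth$true_edges[grepl("^mir", b$truth$true_edges$regulator), ]
  r <- vapply(seq_len(nrow(mir_edges)), function(i) {
    cor(lr[mir_edges$regulator[i], ], lr[mir_edges$target[i], ])
  }, numeric(1))
  expect_lte(mean(r >= 0), 0.01)
})

test_that("generated truth is internally consistent", {
  cfg <- synthetic_config(n_genes = 100, n_tfs = 10, n_mirnas = 6,
                          outlier_fraction = 0.1, seed = 4)
  b <- generate_panel(cfg)
  # module labels cover every entity
  expect_false(anyNA(b$truth$module_labels))
  expect_length(b$truth$module_labels, 116)
  # all planted miRNA edges are negative by construction
  mir <- grepl("^mir", b$truth$true_edges$regulator)
  expect_true(all(b$truth$true_edges$planted_r[mir] < 0))
  # decoy bookkeeping: candidates = true edges + decoys at the set fraction
  n_true <- nrow(b$truth$true_edges)
  expect_equal(nrow(b$interactions), n_true + round(n_true * 0.5 / 0.5))
  # outliers recorded with in-range sample indices
  expect_true(all(b$truth$outlier_positions$sample %in% seq_len(cfg$n_patients)))
  expect_gt(nrow(b$truth$outlier_positions), 0)
  # intensities strictly positive
  expect_true(all(b$panel$tu > 0) && all(b$panel$an > 0))
})

test_that("the scale-free digraph is connected with heavy-tailed out-degrees", {
  g <- generate_scalefree_digraph(10, 9, seed = 1)
  expect_equal(igraph::ecount(g), 9)
  expect_true(igraph::is_connected(g, mode = "weak"))

  g2 <- generate_scalefree_digraph(1700, 4200, seed = 3)
  expect_true(igraph::is_connected(g2, mode = "weak"))
  outdeg <- igraph::degree(g2, mode = "out")
  nz <- outdeg[outdeg > 0]
  expect_gte(max(nz), 5 * stats::median(nz))
})

test_that("planted partitions produce the expected block structure", {
  two <- generate_modular_graph(c(10, 10), p_in = 1, p_out = 0, seed = 5)
  expect_equal(igraph::count_components(two$graph), 2)
  expect_equal(igraph::ecount(two$graph), 2 * choose(10, 2))
  expect_true(all(igraph::E(two$graph)$weight > 0 &
                    igraph::E(two$graph)$weight <= 1))

  one <- generate_modular_graph(30, p_in = 1, p_out = 0, seed = 5)
  expect_equal(length(unique(one$labels)), 1)
  expect_equal(length(detect_modules(one$graph)$sizes), 1)
})

test_that("panel bundles round-trip through the TSV writers", {
  b <- generate_panel(synthetic_config(n_genes = 40, n_tfs = 5, n_mirnas = 3,
                                       seed = 9))
  dir <- file.path(tempdir(), "bundle_roundtrip")
  paths <- write_panel(b, dir)
  tu <- read_expression_matrix(paths[["tu"]])
  expect_equal(tu, b$panel$tu, tolerance = 1e-10)
  pm <- read_probe_map(paths[["probe_map"]])
  expect_equal(pm, b$panel$probe_map)
  back <- load_interactions(paths[["interactions"]], "predicted")
  expect_setequal(paste(back$regulator, back$target),
                  paste(b$interactions$regulator, b$interactions$target))
  truth <- read.delim(paths[["truth"]])
  expect_equal(sum(truth$is_true), nrow(b$truth$true_edges))
})
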