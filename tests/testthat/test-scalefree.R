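star_graph <- function(n) {
  igraph::graph_from_edgelist(cbind("hub", paste0("leaf", seq_len(n - 1))),
                              directed = TRUE)
}

test_that("degree distributions count nonzero degrees only", {
  g <- star_graph(6)
  out <- degree_distribution(g, "out")
  expect_equal(out$k, 5)          # only the hub has out-degree
  expect_equal(out$p, 1)
  inn <- degree_distribution(g, "in")
  expect_equal(inn$k, 1)          # leaves each receive one edge
  expect_equal(inn$p, 1)

  ring <- igraph::make_ring(5, directed = TRUE)
  for (dir in c("in", "out")) {
    d <- degree_distribution(ring, dir)
    expect_equal(d$k, 1)
    expect_equal(d$p, 1)
  }

  pair <- igraph::graph_from_edgelist(cbind("a", "b"), directed = TRUE)
  d <- degree_distribution(pair, "out")
  expect_equal(d$k, 1)
  expect_equal(d$p, 1)            # the sink is excluded from the support
})

test_that("noise-free power laws are recovered exactly", {
  k <- 1:50
  fit <- fit_power_law(as_degree_distribution(k, k^-2))
  expect_equal(unname(fit$params["gamma"]), 2.0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1.0, tolerance = 1e-9)

  fit13 <- fit_power_law(as_degree_distribution(1:30, (1:30)^-1.3))
  expect_equal(unname(fit13$params["gamma"]), 1.3, tolerance = 1e-9)
  expect_equal(fit13$r_squared, 1.0, tolerance = 1e-9)

  # flat distribution: zero slope with the R^2 = 0 degeneracy convention
  flat <- fit_power_law(as_degree_distribution(1:20, rep(1 / 20, 20)))
  expect_equal(unname(flat$params["gamma"]), 0, tolerance = 1e-9)
  expect_equal(flat$r_squared, 0)

  # too few support points
  expect_equal(fit_power_law(as_degree_distribution(1:2, c(0.6, 0.4)))$r_squared, 0)
})

test_that("noise-free truncated power laws are recovered exactly", {
  k <- 1:40
  fit <- fit_truncated_power_law(as_degree_distribution(k, k^-1.5 * exp(-0.1 * k)))
  expect_equal(unname(fit$params["lambda"]), 1.5, tolerance = 1e-9)
  expect_equal(unname(fit$params["alpha_trunc"]), 0.1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1.0, tolerance = 1e-9)

  # nested-model identities: a pure power law has no truncation, a pure
  # exponential has no power-law part
  pure_pl <- fit_truncated_power_law(as_degree_distribution(k, k^-2.2))
  expect_equal(unname(pure_pl$params["alpha_trunc"]), 0, tolerance = 1e-9)
  expect_equal(unname(pure_pl$params["lambda"]), 2.2, tolerance = 1e-9)

  pure_exp <- fit_truncated_power_law(as_degree_distribution(k, exp(-0.5 * k)))
  expect_equal(unname(pure_exp$params["lambda"]), 0, tolerance = 1e-9)
  expect_equal(unname(pure_exp$params["alpha_trunc"]), 0.5, tolerance = 1e-9)
})

test_that("the truncated model never fits worse than the power law", {
  for (s in 1:100) {
    set.seed(s)
    support <- sort(sample(1:60, sample(4:20, 1)))
    p <- runif(length(support))
    dist <- as_degree_distribution(support, p / sum(p))
    expect_gte(fit_truncated_power_law(dist)$r_squared,
               fit_power_law(dist)$r_squared - 1e-12)
  }
})

test_that("cutoff scans shrink the network monotonically and keep empty grid points", {
  b <- generate_panel(synthetic_config(n_genes = 150, n_tfs = 12, n_mirnas = 8,
                                       seed = 5))
  ratios <- merge_probes(compute_ratios(b$panel), b$panel$probe_map)
  scored <- score_edges(b$interactions, ratios)
  scan <- scan_cutoffs(b$interactions, ratios, "TF",
                       grid = seq(0, 0.9, by = 0.05), scored = scored)
  expect_true(all(diff(scan$n_edges) <= 0))
  expect_true(all(diff(scan$n_nodes) <= 0))
  # high cutoffs empty the network but stay on the grid with R^2 = 0
  top <- scan[scan$cutoff == max(scan$cutoff), ]
  if (top$n_edges == 0) {
    expect_equal(top$r2_in, 0)
    expect_equal(top$r2_out, 0)
  }

  one <- scan_cutoffs(b$interactions, ratios, "miRNA", grid = 0.3,
                      scored = scored)
  expect_equal(nrow(one), 1)

  expect_error(scan_cutoffs(b$interactions, ratios, "TF", grid = c(0.5, 0.2)),
               "increasing")
})

test_that("steady-state cutoff selection follows the tol/window rule", {
  mk <- function(r2) {
    structure(data.frame(regulator_class = "TF",
                         cutoff = seq(0, by = 0.1, length.out = length(r2)),
                         r2_in = r2, r2_out = r2,
                         model_in = "power_law", model_out = "power_law",
                         n_nodes = 10L, n_edges = 10L, n_regulators = 2L),
              class = c("cutoff_scan", "data.frame"))
  }
  # worked example: first point whose 2 successors stay within 0.05
  expect_equal(select_cutoff(mk(c(0.0, 0.2, 0.8, 0.85, 0.86, 0.86)),
                             tol = 0.05, window = 2), 0.3)
  # constant curves: the first grid point qualifies
  expect_equal(select_cutoff(mk(rep(0.7, 5))), 0)
  # strictly increasing beyond tol: fallback to argmax of min(r2)
  expect_warning(sel <- select_cutoff(mk(c(0.1, 0.3, 0.5, 0.7, 0.9))),
                 "falling back")
  expect_equal(sel, 0.4)
})

test_that("cutoff selection ignores grid points above the steady state", {
  base <- c(0.0, 0.2, 0.8, 0.85, 0.86, 0.86)
  mk <- function(r2) {
    structure(data.frame(regulator_class = "TF",
                         cutoff = seq(0, by = 0.1, length.out = length(r2)),
                         r2_in = r2, r2_out = r2,
                         model_in = "power_law", model_out = "power_law",
                         n_nodes = 10L, n_edges = 10L, n_regulators = 2L),
              class = c("cutoff_scan", "data.frame"))
  }
  sel <- select_cutoff(mk(base), tol = 0.05, window = 2)
  for (extra in list(0.87, c(0.8, 0.2), c(0.9, 0.9, 0.1))) {
    expect_equal(select_cutoff(mk(c(base, extra)), tol = 0.05, window = 2), sel)
  }
})

test_that("the synthetic scale-free digraph passes its own topology test", {
  g <- generate_scalefree_digraph(1700, 4200, seed = 9)
  dist <- degree_distribution(g, "out")
  expect_gt(fit_power_law(dist)$r_squared, 0.8)
})
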