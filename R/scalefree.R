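#' Empirical degree distribution of a directed network
#'
#' Relative frequencies of in- or out-degrees over the nodes with degree at
#' least 1 in that direction; zero-degree nodes are excluded from the fit
#' support (a node with no outgoing regulation carries no information about
#' the out-degree tail).
#'
#' @param network A `grn` (see [build_grn()]) or an igraph graph.
#' @param direction `"in"` or `"out"`.
#' @return A `degree_distribution` object: list with `direction`, `k`
#'   (sorted degrees with nonzero frequency) and `p` (relative frequencies
#'   summing to 1).
#' @export
degree_distribution <- function(network, direction = c("in", "out")) {
  direction <- match.arg(direction)
  g <- if (inherits(network, "grn")) network$graph else network
  stopifnot(igraph::is_igraph(g))
  if (igraph::vcount(g) == 0) stop("empty network")
  deg <- igraph::degree(g, mode = direction)
  deg <- deg[deg >= 1]
  if (length(deg) == 0) stop("all ", direction, "-degrees are zero")
  tab <- table(deg)
  as_degree_distribution(as.numeric(names(tab)), as.numeric(tab) / sum(tab),
                         direction)
}

#' Build a degree distribution from explicit frequencies
#'
#' Mostly useful for fitting reference shapes (exact power laws, truncated
#' power laws) without materializing a graph.
#'
#' @param k Strictly positive degrees (support).
#' @param p Matching relative frequencies; rescaled to sum to 1.
#' @param direction Label only; `"in"` or `"out"`.
#' @return A `degree_distribution`.
#' @export
as_degree_distribution <- function(k, p, direction = "out") {
  stopifnot(length(k) == length(p), all(k >= 1), all(p > 0))
  o <- order(k)
  structure(list(direction = direction, k = k[o], p = p[o] / sum(p)),
            class = "degree_distribution")
}

# Shared R^2 convention: OLS on log-transformed frequencies; degenerate
# cases (too few support points, or constant log-frequencies so the total
# sum of squares is zero) report r_squared = 0 rather than failing -- the
# same convention under which a candidate network with no expression
# filtering shows up as "completely not power-law".
fit_loglog <- function(dist, model, min_support) {
  stopifnot(inherits(dist, "degree_distribution"))
  degenerate <- function() {
    params <- if (model == "power_law") c(gamma = NA_real_)
              else c(lambda = NA_real_, alpha_trunc = NA_real_)
    structure(list(model = model, params = params, r_squared = 0),
              class = "degree_fit")
  }
  if (length(dist$k) < min_support) return(degenerate())
  lp <- log(dist$p)
  flat <- max(lp) - min(lp) < .Machine$double.eps^0.5
  if (model == "power_law") {
    fit <- lm(lp ~ log(dist$k))
    params <- c(gamma = -unname(stats::coef(fit)[2]))
  } else {
    fit <- lm(lp ~ log(dist$k) + dist$k)
    params <- c(lambda = -unname(stats::coef(fit)[2]),
                alpha_trunc = -unname(stats::coef(fit)[3]))
  }
  if (anyNA(params)) return(degenerate())
  r2 <- if (flat) 0 else suppressWarnings(summary(fit)$r.squared)
  structure(list(model = model, params = params, r_squared = r2),
            class = "degree_fit")
}

#' Fit a power-law degree distribution
#'
#' Least-squares line on `(log k, log P(k))`: `P(k) ~ k^-gamma` so the
#' exponent is minus the slope, and the goodness-of-fit is the R-squared of
#' the regression. Fewer than 3 support points, or a flat distribution,
#' report `r_squared = 0`.
#'
#' @param dist A `degree_distribution`.
#' @return A `degree_fit`: list with `model = "power_law"`,
#'   `params["gamma"]`, `r_squared`.
#' @export
fit_power_law <- function(dist) fit_loglog(dist, "power_law", min_support = 3)

#' Fit an exponentially truncated power-law degree distribution
#'
#' Least squares of `log P(k)` on `(log k, k)`: `P(k) ~ k^-lambda e^(-alpha k)`
#' is log-linear in both regressors, so the exponents are recovered exactly
#' on noise-free input. Because the model nests the pure power law, its
#' R-squared is never below [fit_power_law()]'s on the same distribution.
#'
#' @param dist A `degree_distribution` with at least 4 support points.
#' @return A `degree_fit` with `params[c("lambda", "alpha_trunc")]`.
#' @export
fit_truncated_power_law <- function(dist) {
  fit_loglog(dist, "truncated_power_law", min_support = 4)
}

#' @export
print.degree_fit <- function(x, ...) {
  cat("degree_fit:", x$model, " R^2 =", format(x$r_squared, digits = 4), "\n ",
      paste(names(x$params), "=", format(x$params, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

# Best R^2 over the two candidate scale-free models for one direction.
best_fit <- function(g, direction) {
  dist <- tryCatch(degree_distribution(g, direction), error = function(e) NULL)
  if (is.null(dist)) {
    return(list(r2 = 0, model = NA_character_))
  }
  pl <- fit_power_law(dist)
  tr <- fit_truncated_power_law(dist)
  if (tr$r_squared >= pl$r_squared) list(r2 = tr$r_squared, model = tr$model)
  else list(r2 = pl$r_squared, model = pl$model)
}

#' Scan correlation cutoffs under the scale-free topological criterion
#'
#' For one regulator class, sweeps a grid of correlation cutoffs; at each
#' cutoff it builds the class-restricted GRN (only edges whose regulator is
#' of that class, all three acceptance conditions applied), fits both the
#' power-law and truncated power-law models to the in- and out-degree
#' distributions, and records the better R-squared per direction together
#' with the network size. Edge scoring is cutoff-independent and is done
#' once.
#'
#' @param candidates An [interaction_set()].
#' @param ratios Entity-level `ratio_matrix`.
#' @param regulator_class `"TF"` or `"miRNA"`.
#' @param grid Strictly increasing cutoffs in `[0, 1)`; default 0 to 0.9 in
#'   steps of 0.05.
#' @param cooks_threshold,min_samples Passed to [score_edges()].
#' @param scored Optional precomputed [score_edges()] result.
#' @return A data frame of class `cutoff_scan` with columns
#'   `regulator_class`, `cutoff`, `r2_in`, `r2_out`, `model_in`,
#'   `model_out`, `n_nodes`, `n_edges`, `n_regulators`.
#' @export
scan_cutoffs <- function(candidates, ratios, regulator_class = c("TF", "miRNA"),
                         grid = seq(0, 0.9, by = 0.05), cooks_threshold = 0.5,
                         min_samples = 10, scored = NULL) {
  regulator_class <- match.arg(regulator_class)
  if (any(grid < 0 | grid >= 1) || is.unsorted(grid, strictly = TRUE)) {
    stop("`grid` must be strictly increasing within [0, 1)")
  }
  if (is.null(scored)) {
    scored <- score_edges(candidates, ratios, cooks_threshold, min_samples)
  }
  scored <- scored[scored$regulator_class == regulator_class, , drop = FALSE]
  rows <- lapply(grid, function(cutoff) {
    passed <- scored$scorable &
      (scored$regulator_class != "miRNA" | scored$r < 0) &
      abs(scored$r) > cutoff
    edges <- scored[passed, , drop = FALSE]
    if (nrow(edges) == 0) {
      return(data.frame(regulator_class = regulator_class, cutoff = cutoff,
                        r2_in = 0, r2_out = 0,
                        model_in = NA_character_, model_out = NA_character_,
                        n_nodes = 0L, n_edges = 0L, n_regulators = 0L,
                        stringsAsFactors = FALSE))
    }
    g <- igraph::graph_from_data_frame(edges[, c("regulator", "target")],
                                       directed = TRUE)
    fin <- best_fit(g, "in"); fout <- best_fit(g, "out")
    data.frame(regulator_class = regulator_class, cutoff = cutoff,
               r2_in = fin$r2, r2_out = fout$r2,
               model_in = fin$model, model_out = fout$model,
               n_nodes = igraph::vcount(g), n_edges = nrow(edges),
               n_regulators = length(unique(edges$regulator)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cutoff_scan", "data.frame")
  out
}

#' Select the cutoff where the scale-free fit first reaches a steady state
#'
#' Returns the smallest scanned cutoff `c` such that, for both the
#' in-degree and out-degree R-squared curves, every one of the next
#' `window` grid points stays within `tol` of the value at `c`. Grid points
#' with fewer than `window` successors cannot qualify. If no point
#' qualifies, falls back (with a warning) to the cutoff maximizing
#' `min(r2_in, r2_out)`.
#'
#' @param scan A `cutoff_scan` from [scan_cutoffs()].
#' @param tol Steady-state tolerance on R-squared (default 0.05).
#' @param window Number of subsequent grid points that must stay within
#'   `tol` (default 2).
#' @return The selected cutoff value.
#' @export
select_cutoff <- function(scan, tol = 0.05, window = 2) {
  stopifnot(inherits(scan, "cutoff_scan"), nrow(scan) >= 1, tol >= 0, window >= 1)
  scan <- scan[order(scan$cutoff), , drop = FALSE]
  n <- nrow(scan)
  for (i in seq_len(n)) {
    if (i + window > n) break
    ahead <- (i + 1):(i + window)
    ok_in <- all(abs(scan$r2_in[ahead] - scan$r2_in[i]) <= tol)
    ok_out <- all(abs(scan$r2_out[ahead] - scan$r2_out[i]) <= tol)
    if (ok_in && ok_out) return(scan$cutoff[i])
  }
  warning("no steady state found; falling back to argmax of min(r2_in, r2_out)")
  scan$cutoff[which.max(pmin(scan$r2_in, scan$r2_out))]
}
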