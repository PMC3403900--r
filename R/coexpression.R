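#' Cook's distance for a regulator ~ target regression
#'
#' For a candidate regulation, the regulator's profile `y` is regressed on
#' the target's profile `x` (univariate least squares with intercept) and
#' each sample's Cook's distance is computed in closed form:
#' `D_i = e_i^2 / (2 s^2) * h_i / (1 - h_i)^2` with leverage
#' `h_i = 1/n + (x_i - mean(x))^2 / Sxx` and `s^2 = RSS / (n - 2)`.
#' This equals the normalized shift in fitted values when sample `i` is
#' refitted out (the leave-one-out definition).
#'
#' @param x Target profile (numeric).
#' @param y Regulator profile, same length.
#' @return Numeric vector of Cook's distances; all zero for a perfect fit.
#'   `NULL` if `x` has zero variance (no regression possible).
#' @export
pair_cooks_distance <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  n <- length(x)
  mx <- mean(x)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) return(NULL)
  b <- sum((x - mx) * (y - mean(y))) / sxx
  e <- y - (mean(y) + b * (x - mx))
  h <- 1 / n + (x - mx)^2 / sxx
  s2 <- sum(e^2) / (n - 2)
  if (s2 == 0) return(numeric(n))
  e^2 / (2 * s2) * h / (1 - h)^2
}

#' Outlying samples of a regulator-target pair
#'
#' Samples whose Cook's distance in the regulator-on-target regression
#' exceeds `threshold` (default 0.5) are flagged as outliers, to be removed
#' before the Pearson correlation is computed.
#'
#' @inheritParams pair_cooks_distance
#' @param threshold Cook's distance above which a sample is an outlier.
#' @return Integer vector of outlier indices (possibly empty). If `x` has
#'   zero variance no regression is possible: the result is empty with
#'   attribute `scorable = FALSE`.
#' @export
cooks_outliers <- function(x, y, threshold = 0.5) {
  d <- pair_cooks_distance(x, y)
  if (is.null(d)) {
    return(structure(integer(0), scorable = FALSE))
  }
  structure(which(d > threshold), scorable = TRUE)
}

#' Outlier-robust Pearson correlation for one candidate edge
#'
#' Removes Cook's-distance outliers ([cooks_outliers()]) in a single pass,
#' then computes the Pearson correlation on the retained samples.
#'
#' @inheritParams cooks_outliers
#' @param min_samples Minimum retained samples required for a usable
#'   correlation (default 10).
#' @return List with `r`, `n_used`, `outliers` (removed indices),
#'   `scorable` (logical) and `reason` (why unscorable, or `NA`).
#' @export
robust_pearson <- function(x, y, threshold = 0.5, min_samples = 10) {
  out <- cooks_outliers(x, y, threshold)
  if (!attr(out, "scorable")) {
    return(list(r = NA_real_, n_used = 0L, outliers = integer(0),
                scorable = FALSE, reason = "zero variance in target profile"))
  }
  keep <- setdiff(seq_along(x), out)
  if (length(keep) < min_samples) {
    return(list(r = NA_real_, n_used = length(keep), outliers = as.integer(out),
                scorable = FALSE, reason = "too few samples after outlier removal"))
  }
  xs <- x[keep]; ys <- y[keep]
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    return(list(r = NA_real_, n_used = length(keep), outliers = as.integer(out),
                scorable = FALSE, reason = "zero variance after outlier removal"))
  }
  list(r = cor(xs, ys), n_used = length(keep), outliers = as.integer(out),
       scorable = TRUE, reason = NA_character_)
}

#' Score every candidate edge by robust correlation
#'
#' Runs [robust_pearson()] for each candidate regulation, taking the
#' regulator's entity-level log-ratio profile as `y` and the target's as
#' `x`. Candidates whose endpoints are missing from the ratio matrix are
#' skipped with a logged count and appear with `scorable = FALSE`.
#'
#' @param candidates An [interaction_set()].
#' @param ratios Entity-level `ratio_matrix` (see [merge_probes()]).
#' @param cooks_threshold Cook's distance cutoff for outliers.
#' @param min_samples Minimum retained samples per pair.
#' @return Data frame: the candidate columns plus `r`, `n_used`,
#'   `n_outliers`, `scorable`.
#' @export
score_edges <- function(candidates, ratios, cooks_threshold = 0.5,
                        min_samples = 10) {
  stopifnot(inherits(candidates, "interaction_set"),
            inherits(ratios, "ratio_matrix"))
  v <- ratios$values
  n <- nrow(candidates)
  r <- rep(NA_real_, n); n_used <- integer(n); n_out <- integer(n)
  ok <- logical(n)
  missing_profile <- 0L
  for (i in seq_len(n)) {
    reg <- candidates$regulator[i]; tgt <- candidates$target[i]
    if (!(reg %in% rownames(v)) || !(tgt %in% rownames(v))) {
      missing_profile <- missing_profile + 1L
      next
    }
    sc <- robust_pearson(v[tgt, ], v[reg, ], cooks_threshold, min_samples)
    r[i] <- sc$r; n_used[i] <- sc$n_used
    n_out[i] <- length(sc$outliers); ok[i] <- sc$scorable
  }
  if (missing_profile > 0) {
    message("skipped ", missing_profile, " candidate(s) without expression profiles")
  }
  out <- as.data.frame(candidates)
  out$r <- r; out$n_used <- n_used; out$n_outliers <- n_out; out$scorable <- ok
  out
}

#' Build the gene regulatory network from scored candidates
#'
#' An edge enters the GRN when all three acceptance conditions hold:
#' \enumerate{
#'   \item it exists in the candidate network (predicted or experimentally
#'     supported);
#'   \item if the regulator is a miRNA, its correlation with the target is
#'     negative (TF correlations may have either sign);
#'   \item the absolute correlation exceeds the cutoff of the regulator's
#'     class.
#' }
#' Default cutoffs are 0.6 for TFs and 0.45 for miRNAs; see
#' [scan_cutoffs()]/[select_cutoff()] for choosing them by the scale-free
#' topological criterion.
#'
#' @param candidates An [interaction_set()].
#' @param ratios Entity-level `ratio_matrix`.
#' @param class_cutoffs Named numeric vector `c(TF = ..., miRNA = ...)`,
#'   each in `[0, 1)`.
#' @param cooks_threshold,min_samples Passed to [score_edges()].
#' @param scored Optional precomputed [score_edges()] result (the scoring is
#'   cutoff-independent, so scans reuse it).
#' @return A `grn` object: list with `graph` (directed igraph, edge
#'   attributes `r`, `n_used`, `predicted`, `experimental`; vertex attribute
#'   `class`), `edges` (accepted-edge data frame), `class_cutoffs`, and
#'   `nodes` (data frame `id`, `class`).
#' @export
build_grn <- function(candidates, ratios, class_cutoffs = c(TF = 0.6, miRNA = 0.45),
                      cooks_threshold = 0.5, min_samples = 10, scored = NULL) {
  if (!all(c("TF", "miRNA") %in% names(class_cutoffs))) {
    stop("`class_cutoffs` must be named with TF and miRNA")
  }
  if (any(class_cutoffs < 0 | class_cutoffs >= 1)) {
    stop("cutoffs must lie in [0, 1)")
  }
  if (is.null(scored)) {
    scored <- score_edges(candidates, ratios, cooks_threshold, min_samples)
  }
  cut <- class_cutoffs[scored$regulator_class]
  passed <- scored$scorable &
    (scored$regulator_class != "miRNA" | scored$r < 0) &
    abs(scored$r) > cut
  edges <- scored[passed, , drop = FALSE]
  rownames(edges) <- NULL
  grn_from_edges(edges, class_cutoffs)
}

# Assemble the grn object from an accepted-edge data frame. Node classes
# come from the regulator_class/target_class columns; an entity seen as a
# regulator keeps its regulator class.
grn_from_edges <- function(edges, class_cutoffs) {
  node_class <- c(setNames(edges$target_class, edges$target),
                  setNames(edges$regulator_class, edges$regulator))
  node_class <- node_class[!duplicated(names(node_class))]
  nodes <- data.frame(id = as.character(names(node_class)),
                      class = as.character(unname(node_class)),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  g <- igraph::graph_from_data_frame(
    d = edges[, c("regulator", "target", "r", "n_used", "predicted", "experimental")],
    directed = TRUE, vertices = nodes)
  structure(list(graph = g, edges = edges, class_cutoffs = class_cutoffs,
                 nodes = nodes),
            class = "grn")
}

#' @export
print.grn <- function(x, ...) {
  cat("grn:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges",
      "(cutoffs TF =", x$class_cutoffs[["TF"]],
      ", miRNA =", x$class_cutoffs[["miRNA"]], ")\n")
  invisible(x)
}
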