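#' Largest weakly-connected component of a GRN
#'
#' Connectivity ignores edge direction: with miRNA/TF sources and gene
#' sinks, strong connectivity would shatter a regulatory network. Ties in
#' component size are broken deterministically in favor of the component
#' containing the lexicographically smallest node id.
#'
#' @param net A `grn` from [build_grn()].
#' @return The induced `grn` on the largest component, with attribute
#'   `component_fraction` (retained node share of the input).
#' @export
largest_component <- function(net) {
  stopifnot(inherits(net, "grn"))
  g <- net$graph
  if (igraph::vcount(g) == 0) stop("empty network")
  comp <- igraph::components(g, mode = "weak")
  biggest <- which(comp$csize == max(comp$csize))
  if (length(biggest) > 1) {
    firsts <- vapply(biggest, function(m) {
      min(igraph::V(g)$name[comp$membership == m])
    }, character(1))
    biggest <- biggest[order(firsts)[1]]
  }
  keep_nodes <- igraph::V(g)$name[comp$membership == biggest]
  keep_edges <- net$edges$regulator %in% keep_nodes & net$edges$target %in% keep_nodes
  edges <- net$edges[keep_edges, , drop = FALSE]
  rownames(edges) <- NULL
  out <- grn_from_edges(edges, net$class_cutoffs)
  # isolated nodes of the component cannot occur: every node in a grn is an
  # edge endpoint, so the component is fully recoverable from its edges
  attr(out, "component_fraction") <- length(keep_nodes) / igraph::vcount(g)
  out
}

#' Detect network modules by random walks (walktrap)
#'
#' Community detection on the undirected view of the GRN, with the absolute
#' correlation of each regulation as the edge weight. Walktrap merges nodes
#' whose short random walks (length `steps`, default 4) have similar
#' distributions, and the partition with maximal modularity is returned.
#'
#' @param net A `grn`, or an igraph graph (then `weights` applies).
#' @param weights Edge weights; defaults to `|r|` for a `grn` and to the
#'   graph's `weight` attribute (or 1) otherwise.
#' @param steps Random-walk length.
#' @return A `module_partition`: list with `assignment` (named integer
#'   vector node -> module id, modules numbered by decreasing size),
#'   `sizes`, `modularity`, and `regulators` (per-module regulator ids; only
#'   for `grn` input).
#' @export
detect_modules <- function(net, weights = NULL, steps = 4) {
  is_grn <- inherits(net, "grn")
  g <- if (is_grn) net$graph else net
  stopifnot(igraph::is_igraph(g))
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  if (is.null(weights)) {
    weights <- if (is_grn) abs(igraph::E(g)$r)
    else if ("weight" %in% igraph::edge_attr_names(g)) igraph::E(g)$weight
    else rep(1, igraph::ecount(g))
  }
  if (igraph::ecount(g) > 0 && any(weights <= 0)) stop("weights must be positive")
  gu <- igraph::as_undirected(g, mode = "collapse",
                              edge.attr.comb = list(weight = "max", "ignore"))
  igraph::E(gu)$weight <- collapse_weights(g, gu, weights)
  wt <- igraph::cluster_walktrap(gu, weights = igraph::E(gu)$weight, steps = steps)
  memb <- igraph::membership(wt)
  # renumber modules by decreasing size (ties by smallest member id)
  sizes <- table(memb)
  first_id <- vapply(names(sizes), function(m) {
    min(names(memb)[memb == as.integer(m)])
  }, character(1))
  ord <- order(-as.integer(sizes), first_id)
  renum <- setNames(seq_along(ord), names(sizes)[ord])
  assignment <- setNames(as.integer(renum[as.character(memb)]), names(memb))
  sizes <- as.integer(table(assignment))
  regulators <- NULL
  if (is_grn) {
    reg_ids <- net$nodes$id[net$nodes$class %in% c("TF", "miRNA")]
    regulators <- lapply(seq_along(sizes), function(m) {
      intersect(names(assignment)[assignment == m], reg_ids)
    })
  }
  structure(list(assignment = assignment, sizes = sizes,
                 modularity = igraph::modularity(gu, memb,
                                                 weights = igraph::E(gu)$weight),
                 regulators = regulators),
            class = "module_partition")
}

# Map per-directed-edge weights onto the collapsed undirected graph by
# taking the max over reciprocal pairs.
collapse_weights <- function(g, gu, weights) {
  if (igraph::ecount(gu) == 0) return(numeric(0))
  el <- igraph::as_edgelist(g, names = TRUE)
  key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  elu <- igraph::as_edgelist(gu, names = TRUE)
  keyu <- paste(pmin(elu[, 1], elu[, 2]), pmax(elu[, 1], elu[, 2]))
  as.numeric(tapply(weights, key, max)[keyu])
}

#' @export
print.module_partition <- function(x, ...) {
  cat("module_partition:", length(x$sizes), "modules, sizes",
      paste(head(x$sizes, 10), collapse = " "),
      "; modularity", format(x$modularity, digits = 4), "\n")
  invisible(x)
}

#' Edge-betweenness of every regulation
#'
#' The betweenness of an edge is the number of shortest paths between
#' ordered node pairs that traverse it, with ties split equally: if a pair
#' has several shortest paths, each contributes its fraction. Paths are
#' directed and unweighted (hop counts) by default; set `directed = FALSE`
#' to treat regulations as undirected links.
#'
#' @param net A `grn` or igraph graph.
#' @param directed Follow edge directions (default `TRUE`).
#' @return Numeric vector of betweenness values, in the graph's edge order
#'   (for a `grn`, the row order of `net$edges`), named `regulator->target`.
#' @export
edge_betweenness_scores <- function(net, directed = TRUE) {
  g <- if (inherits(net, "grn")) net$graph else net
  stopifnot(igraph::is_igraph(g))
  eb <- igraph::edge_betweenness(g, directed = directed, weights = NA)
  el <- igraph::as_edgelist(g, names = TRUE)
  setNames(eb, paste0(el[, 1], "->", el[, 2]))
}

#' Extract the core network of top-betweenness regulations
#'
#' Computes the empirical `quantile` (default 0.99, linear interpolation)
#' of the edge-betweenness values of the whole network and keeps the edges
#' strictly above it. The threshold is taken over all edges first; if a
#' retained edge touches a non-regulator node (class `"gene"`) a warning is
#' raised, since the expected core connects only TFs and miRNAs.
#'
#' @param net A `grn`, normally the [largest_component()] of the global
#'   network.
#' @param quantile Quantile level in `[0, 1)`.
#' @param betweenness Optional precomputed [edge_betweenness_scores()]
#'   vector for `net`.
#' @return A `core_network`: list with `edges` (core edge data frame with a
#'   `betweenness` column), `graph`, `threshold`, `quantile`,
#'   `edge_fraction` (core share of all edges) and `betweenness_fraction`
#'   (core share of total betweenness).
#' @export
extract_core <- function(net, quantile = 0.99, betweenness = NULL) {
  stopifnot(inherits(net, "grn"))
  if (!is.numeric(quantile) || length(quantile) != 1 ||
      quantile < 0 || quantile >= 1) {
    stop("`quantile` must be a single value in [0, 1)")
  }
  if (is.null(betweenness)) betweenness <- edge_betweenness_scores(net)
  stopifnot(length(betweenness) == nrow(net$edges))
  threshold <- stats::quantile(betweenness, quantile, names = FALSE, type = 7)
  keep <- betweenness > threshold
  edges <- net$edges[keep, , drop = FALSE]
  edges$betweenness <- betweenness[keep]
  edges <- edges[order(-edges$betweenness), , drop = FALSE]
  rownames(edges) <- NULL
  cls <- setNames(net$nodes$class, net$nodes$id)
  nonreg <- unique(c(edges$regulator, edges$target))
  nonreg <- nonreg[cls[nonreg] == "gene"]
  if (length(nonreg) > 0) {
    warning("core network touches non-regulator node(s): ",
            paste(head(nonreg, 5), collapse = ", "))
  }
  g <- igraph::subgraph_from_edges(net$graph, igraph::E(net$graph)[keep],
                                   delete.vertices = TRUE)
  structure(list(edges = edges, graph = g, threshold = threshold,
                 quantile = quantile,
                 edge_fraction = sum(keep) / length(keep),
                 betweenness_fraction = sum(betweenness[keep]) / sum(betweenness)),
            class = "core_network")
}

#' @export
print.core_network <- function(x, ...) {
  cat("core_network:", igraph::vcount(x$graph), "nodes,", nrow(x$edges),
      "edges (", format(100 * x$edge_fraction, digits = 3), "% of edges,",
      format(100 * x$betweenness_fraction, digits = 3), "% of betweenness)\n")
  invisible(x)
}

#' Count feedforward and feedback loops
#'
#' Feedforward loops are ordered triples with edges `A->B`, `B->C`, `A->C`
#' all present; feedback loops are directed cycles of length 2 or 3. Each
#' motif is counted once per node set and edge configuration (the two
#' orientations of a 3-cycle count separately; its three rotations do not).
#'
#' @param net A `core_network`, `grn`, or igraph graph.
#' @return Named integer vector `c(feedforward = ..., feedback = ...)`.
#' @export
count_loops <- function(net) {
  g <- if (inherits(net, "core_network") || inherits(net, "grn")) net$graph else net
  stopifnot(igraph::is_igraph(g))
  if (igraph::vcount(g) == 0) return(c(feedforward = 0L, feedback = 0L))
  a <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE))
  a <- (a > 0) * 1
  ffl <- sum((a %*% a) * a)
  two_cycles <- sum(a * t(a)) / 2
  three_cycles <- sum(diag(a %*% a %*% a)) / 3
  c(feedforward = as.integer(ffl),
    feedback = as.integer(two_cycles + three_cycles))
}
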