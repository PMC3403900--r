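# Independent brute-force oracles. Each recomputes a quantity from first
# principles (refits, exhaustive enumeration) without touching the code
# paths it is used to check.

# Cook's distance by literal leave-one-out refitting: for each sample i,
# refit the regression without it and measure the normalized shift in all
# fitted values.
loo_cooks_oracle <- function(x, y) {
  n <- length(x)
  full <- lm(y ~ x)
  s2 <- sum(resid(full)^2) / (n - 2)
  yhat <- fitted(full)
  vapply(seq_len(n), function(i) {
    f <- lm(y[-i] ~ x[-i])
    yhat_i <- coef(f)[1] + coef(f)[2] * x
    sum((yhat - yhat_i)^2) / (2 * s2)
  }, numeric(1))
}

# Directed unweighted edge betweenness by exhaustive shortest-path
# enumeration: BFS distances per source, recursive enumeration of every
# shortest path per ordered pair, each path crediting 1/(number of tied
# paths) to each of its edges.
brute_edge_betweenness <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  adj <- lapply(seq_len(n), function(v) el[el[, 1] == v, 2])
  eb <- setNames(numeric(nrow(el)), paste(el[, 1], el[, 2]))
  bfs_dist <- function(s) {
    d <- rep(Inf, n); d[s] <- 0; q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in adj[[v]]) if (!is.finite(d[w])) { d[w] <- d[v] + 1; q <- c(q, w) }
    }
    d
  }
  # enumerate forward: shortest s->t paths follow exactly the edges v->w
  # with dist_s[w] == dist_s[v] + 1, never overshooting dist_s[t]
  for (s in seq_len(n)) {
    d <- bfs_dist(s)
    for (t in seq_len(n)) {
      if (t == s || !is.finite(d[t])) next
      paths <- list()
      walk <- function(v, trail) {
        if (v == t) { paths[[length(paths) + 1]] <<- trail; return(invisible()) }
        for (w in adj[[v]]) {
          if (d[w] == d[v] + 1 && d[w] <= d[t]) walk(w, c(trail, w))
        }
      }
      walk(s, s)
      share <- 1 / length(paths)
      for (pth in paths) {
        for (i in seq_len(length(pth) - 1)) {
          key <- paste(pth[i], pth[i + 1])
          eb[key] <- eb[key] + share
        }
      }
    }
  }
  unname(eb)
}

# Loop counting by exhaustive enumeration over node pairs and triples.
brute_count_loops <- function(g) {
  n <- igraph::vcount(g)
  a <- as.matrix(igraph::as_adjacency_matrix(g)) > 0
  ffl <- 0L; fb2 <- 0L; fb3 <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && a[i, j] && a[j, i]) fb2 <- fb2 + 1L
    if (i == j) next
    for (k in seq_len(n)) {
      if (k == i || k == j) next
      if (a[i, j] && a[j, k] && a[i, k]) ffl <- ffl + 1L
    }
  }
  # 3-cycles: each counted once per cyclic orientation
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i < j && i < k && j != k && a[i, j] && a[j, k] && a[k, i]) fb3 <- fb3 + 1L
  }
  c(feedforward = ffl, feedback = fb2 + fb3)
}

# Hypergeometric upper-tail p by exhaustive enumeration of all possible
# query draws from a small background.
brute_hypergeom <- function(background, term, query_size, observed_overlap) {
  draws <- utils::combn(background, query_size, simplify = FALSE)
  hits <- vapply(draws, function(d) length(intersect(d, term)) >= observed_overlap,
                 logical(1))
  mean(hits)
}

# Seeded random digraph without self-loops.
random_digraph <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n) < p, n, n)
  diag(a) <- FALSE
  igraph::graph_from_adjacency_matrix(a, mode = "directed")
}
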