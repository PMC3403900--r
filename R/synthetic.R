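#' Configuration for the synthetic paired-expression benchmark
#'
#' Defines the study conditions emulated by [generate_panel()]: a cohort of
#' paired tumor / adjacent non-tumor profiles (default 96 patients), TF and
#' miRNA regulators whose planted regulator-target correlations differ in
#' strength (TF regulation stronger than miRNA regulation, miRNA
#' correlations negative), decoy candidate edges, and occasional outlier
#' samples.
#'
#' @param n_genes,n_tfs,n_mirnas Entity counts.
#' @param n_patients Number of patient pairs (default 96).
#' @param tf_signal Planted absolute Pearson correlation for TF-regulated
#'   targets, in (0, 1).
#' @param mirna_signal Planted absolute correlation for miRNA-regulated
#'   targets, in (0, 1); conventionally below `tf_signal`.
#' @param decoy_edge_fraction Fraction of the candidate network made of
#'   decoy (unplanted) edges, in `[0, 1)`.
#' @param outlier_fraction Fraction of planted gene-target edges that get
#'   one far-displaced sample in the target profile, in `[0, 1]`.
#' @param n_modules Number of regulator modules (labels only).
#' @param seed Integer seed; fully determines the output.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 300, n_tfs = 25, n_mirnas = 15,
                             n_patients = 96, tf_signal = 0.8,
                             mirna_signal = 0.6, decoy_edge_fraction = 0.5,
                             outlier_fraction = 0.05, n_modules = 4, seed = 1) {
  cfg <- list(n_genes = n_genes, n_tfs = n_tfs, n_mirnas = n_mirnas,
              n_patients = n_patients, tf_signal = tf_signal,
              mirna_signal = mirna_signal,
              decoy_edge_fraction = decoy_edge_fraction,
              outlier_fraction = outlier_fraction, n_modules = n_modules,
              seed = seed)
  counts <- cfg[c("n_genes", "n_tfs", "n_mirnas", "n_patients", "n_modules")]
  if (any(vapply(counts, function(x) x < 1 || x != round(x), logical(1)))) {
    stop("entity, patient and module counts must be positive integers")
  }
  if (tf_signal <= 0 || tf_signal >= 1 || mirna_signal <= 0 || mirna_signal >= 1) {
    stop("`tf_signal` and `mirna_signal` must lie strictly in (0, 1)")
  }
  if (decoy_edge_fraction < 0 || decoy_edge_fraction >= 1) {
    stop("`decoy_edge_fraction` must lie in [0, 1)")
  }
  if (outlier_fraction < 0 || outlier_fraction > 1) {
    stop("`outlier_fraction` must lie in [0, 1]")
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic paired expression panel with planted regulations
#'
#' Builds, from one seed, everything the pipeline consumes plus the ground
#' truth: a strictly positive TU/AN intensity panel, a candidate interaction
#' set (planted edges plus uniform decoys), and the planted truth.
#'
#' Profiles are generated on the log2 scale and exponentiated, so
#' intensities are positive and roughly log-normal. Each target's log-ratio
#' profile shares a latent factor with its regulator's profile with loading
#' equal to the planted correlation, so the expected Pearson correlation of
#' the pair equals the planted value. Regulator out-degrees follow a
#' preferential-attachment (heavy-tailed) rule, and the regulator layer is
#' itself wired: every TF after the first is regulated by an earlier TF and
#' every miRNA by a TF, so the planted network forms one connected
#' regulatory hierarchy (TF->TF, TF->miRNA, TF->gene, miRNA->gene edges). miRNA-planted correlations
#' are negative; TF-planted correlations take either sign. Each entity
#' additionally gets a tumor/normal mean shift (SD 0.7 on the log2 scale)
#' so differential statistics have dysregulation to detect; mean shifts do
#' not alter Pearson correlations. Outliers replace one sample of a target
#' profile with a point 8 SD away.
#'
#' @param config A [synthetic_config()].
#' @return List with `panel` ([expression_panel()], one probe per entity),
#'   `interactions` ([interaction_set()], true edges plus decoys; a random
#'   15% of true edges additionally flagged experimental), and `truth`
#'   (list: `true_edges` data frame with `regulator`, `target`,
#'   `planted_r`; `module_labels` named vector; `outlier_positions` data
#'   frame with `regulator`, `target`, `sample`).
#' @export
generate_panel <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  tf_ids <- sprintf("TF%03d", seq_len(config$n_tfs))
  mir_ids <- sprintf("mir%03d", seq_len(config$n_mirnas))
  gene_ids <- sprintf("g%04d", seq_len(config$n_genes))
  reg_ids <- c(tf_ids, mir_ids)
  all_ids <- c(reg_ids, gene_ids)
  np <- config$n_patients

  profiles <- matrix(NA_real_, nrow = length(all_ids), ncol = np,
                     dimnames = list(all_ids, sprintf("P%03d", seq_len(np))))
  profiles[tf_ids[1], ] <- rnorm(np)

  module_labels <- setNames(rep(NA_integer_, length(all_ids)), all_ids)
  module_labels[tf_ids] <- rep_len(seq_len(config$n_modules), config$n_tfs)

  outdeg <- setNames(numeric(length(reg_ids)), reg_ids)
  edges <- list()
  plant <- function(regulator, target, r_abs, sign) {
    z <- profiles[regulator, ]
    z <- (z - mean(z)) / stats::sd(z)
    profiles[target, ] <<- sign * r_abs * z + sqrt(1 - r_abs^2) * rnorm(np)
    outdeg[regulator] <<- outdeg[regulator] + 1
    edges[[length(edges) + 1L]] <<- data.frame(
      regulator = regulator, target = target, planted_r = sign * r_abs,
      stringsAsFactors = FALSE)
    if (is.na(module_labels[target])) {
      module_labels[target] <<- module_labels[regulator]
    }
  }
  # TFs regulate each other: every TF after the first is controlled by a
  # preferentially chosen earlier TF, connecting the regulator layer
  for (i in seq_len(config$n_tfs)[-1]) {
    older <- tf_ids[seq_len(i - 1)]
    parent <- if (length(older) == 1) older
              else sample(older, 1, prob = outdeg[older] + 1)
    plant(parent, tf_ids[i], config$tf_signal, sample(c(-1, 1), 1))
  }
  # each miRNA is transcriptionally controlled by one TF
  for (m in mir_ids) {
    parent <- if (config$n_tfs == 1) tf_ids
              else sample(tf_ids, 1, prob = outdeg[tf_ids] + 1)
    plant(parent, m, config$tf_signal, sample(c(-1, 1), 1))
  }
  # each gene is regulated by one regulator, chosen preferentially
  for (g in gene_ids) {
    parent <- sample(reg_ids, 1, prob = outdeg + 1)
    if (parent %in% mir_ids) {
      plant(parent, g, config$mirna_signal, -1)
    } else {
      plant(parent, g, config$tf_signal, sample(c(-1, 1), 1))
    }
  }
  true_edges <- do.call(rbind, edges)

  # outliers: displace one sample of a gene-target profile by 8 SD
  gene_edge_idx <- which(true_edges$target %in% gene_ids)
  n_outlier <- floor(config$outlier_fraction * length(gene_edge_idx))
  outlier_positions <- data.frame(regulator = character(), target = character(),
                                  sample = integer(), stringsAsFactors = FALSE)
  if (n_outlier > 0) {
    hit <- sample(gene_edge_idx, n_outlier)
    samples <- sample.int(np, n_outlier, replace = TRUE)
    for (j in seq_len(n_outlier)) {
      tgt <- true_edges$target[hit[j]]
      profiles[tgt, samples[j]] <- 8
    }
    outlier_positions <- data.frame(regulator = true_edges$regulator[hit],
                                    target = true_edges$target[hit],
                                    sample = samples, stringsAsFactors = FALSE)
  }

  # tumor/normal dysregulation: per-entity mean shifts of the log-ratio,
  # independent of the co-expression structure (Pearson r is location
  # invariant), so differential statistics have signal to find
  shift <- rnorm(length(all_ids), mean = 0, sd = 0.7)
  profiles <- profiles + shift

  # candidate set: true edges plus uniform decoys among unplanted pairs
  classes <- setNames(c(rep("TF", config$n_tfs), rep("miRNA", config$n_mirnas),
                        rep("gene", config$n_genes)), all_ids)
  f <- config$decoy_edge_fraction
  n_decoy <- round(f / (1 - f) * nrow(true_edges))
  decoys <- draw_decoys(n_decoy, reg_ids, all_ids, classes,
                        paste(true_edges$regulator, true_edges$target))
  cand <- rbind(true_edges[c("regulator", "target")], decoys)
  cand$regulator_class <- classes[cand$regulator]
  cand$target_class <- classes[cand$target]
  cand$predicted <- TRUE
  cand$experimental <- c(runif(nrow(true_edges)) < 0.15,
                         rep(FALSE, nrow(decoys)))
  cand$source <- "synthetic"
  interactions <- interaction_set(cand)

  # intensity panel: baseline per entity, small patient noise on AN,
  # TU = AN shifted by the planted log-ratio profile
  baseline <- rnorm(length(all_ids), mean = 8, sd = 1)
  an_log <- baseline + matrix(rnorm(length(all_ids) * np, sd = 0.15), ncol = np)
  tu_log <- an_log + profiles
  probe_ids <- paste0("p_", all_ids)
  tu <- 2^tu_log; an <- 2^an_log
  dimnames(tu) <- dimnames(an) <- list(probe_ids, colnames(profiles))
  probe_map <- data.frame(probe_id = probe_ids, entity_id = all_ids,
                          entity_class = unname(classes),
                          stringsAsFactors = FALSE)
  panel <- expression_panel(tu, an, probe_map)

  list(panel = panel, interactions = interactions,
       truth = list(true_edges = true_edges, module_labels = module_labels,
                    outlier_positions = outlier_positions))
}

draw_decoys <- function(n_decoy, reg_ids, all_ids, classes, true_keys) {
  out <- data.frame(regulator = character(), target = character(),
                    stringsAsFactors = FALSE)
  seen <- character(0)
  while (nrow(out) < n_decoy) {
    need <- n_decoy - nrow(out)
    reg <- sample(reg_ids, 2 * need + 10, replace = TRUE)
    tgt <- sample(all_ids, 2 * need + 10, replace = TRUE)
    key <- paste(reg, tgt)
    ok <- reg != tgt &
      !(classes[reg] == "miRNA" & classes[tgt] == "miRNA") &
      !key %in% true_keys & !key %in% seen & !duplicated(key)
    add <- which(ok)[seq_len(min(need, sum(ok)))]
    seen <- c(seen, key[add])
    out <- rbind(out, data.frame(regulator = reg[add], target = tgt[add],
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Write a synthetic bundle to pipeline input files
#'
#' Serializes the generated panel, candidate network and truth into the
#' same TSV dialects the pipeline reads: `tu.tsv`, `an.tsv`,
#' `probe_map.tsv`, `interactions.tsv`, and `truth.tsv` (columns
#' `regulator`, `target`, `planted_r`, `is_true`, covering true edges and
#' decoys).
#'
#' @param bundle Output of [generate_panel()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_panel <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(tu = file.path(dir, "tu.tsv"), an = file.path(dir, "an.tsv"),
             probe_map = file.path(dir, "probe_map.tsv"),
             interactions = file.path(dir, "interactions.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_matrix_tsv(bundle$panel$tu, paths[["tu"]])
  write_matrix_tsv(bundle$panel$an, paths[["an"]])
  write.table(bundle$panel$probe_map, paths[["probe_map"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_interactions(bundle$interactions, paths[["interactions"]])
  truth <- bundle$truth$true_edges
  key <- paste(truth$regulator, truth$target)
  cand_key <- paste(bundle$interactions$regulator, bundle$interactions$target)
  all_truth <- data.frame(
    regulator = bundle$interactions$regulator,
    target = bundle$interactions$target,
    planted_r = truth$planted_r[match(cand_key, key)],
    is_true = cand_key %in% key, stringsAsFactors = FALSE)
  all_truth$planted_r[is.na(all_truth$planted_r)] <- 0
  write.table(all_truth, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' Inject displaced outlier samples into a profile
#'
#' Replaces `n` randomly chosen positions of `y` with values displaced
#' `magnitude` standard deviations from the mean (alternating sides), the
#' same corruption the panel generator applies.
#'
#' @param y Numeric profile.
#' @param n Number of outliers.
#' @param magnitude Displacement in SD units (default 8; at least 6 is
#'   needed for reliable Cook's-distance detection at threshold 0.5).
#' @return List with `y` (corrupted profile) and `positions`.
#' @export
inject_outliers <- function(y, n = 1, magnitude = 8) {
  stopifnot(n >= 1, n <= length(y), magnitude > 0)
  pos <- sample.int(length(y), n)
  side <- rep_len(c(1, -1), n)
  y[pos] <- mean(y) + side * magnitude * stats::sd(y)
  list(y = y, positions = pos)
}

#' Generate a weakly connected scale-free digraph
#'
#' Preferential-attachment growth oriented so that out-degrees are
#' heavy-tailed, mimicking a regulatory network where a few hub regulators
#' control many targets: each new node receives an edge from an existing
#' node chosen with probability proportional to out-degree + 1 (which also
#' guarantees weak connectivity), and the remaining edges are added with
#' preferentially chosen sources and uniform targets.
#'
#' @param n_nodes,n_edges Graph size; `n_edges` must lie between
#'   `n_nodes - 1` and `n_nodes * (n_nodes - 1)`.
#' @param seed Integer seed.
#' @return A directed igraph graph with character vertex names.
#' @export
generate_scalefree_digraph <- function(n_nodes, n_edges, seed = 1) {
  if (n_nodes < 2) stop("need at least 2 nodes")
  if (n_edges < n_nodes - 1 || n_edges > n_nodes * (n_nodes - 1)) {
    stop("`n_edges` must lie in [n_nodes - 1, n_nodes * (n_nodes - 1)]")
  }
  set.seed(seed)
  src <- integer(n_edges); dst <- integer(n_edges)
  outdeg <- numeric(n_nodes)
  for (i in 2:n_nodes) {
    s <- sample.int(i - 1L, 1L, prob = outdeg[seq_len(i - 1L)] + 1)
    src[i - 1L] <- s; dst[i - 1L] <- i
    outdeg[s] <- outdeg[s] + 1
  }
  m <- n_nodes - 1L
  seen <- new.env(hash = TRUE, size = n_edges)
  for (j in seq_len(m)) assign(paste(src[j], dst[j]), TRUE, envir = seen)
  while (m < n_edges) {
    s <- sample.int(n_nodes, 1L, prob = outdeg + 1)
    t <- sample.int(n_nodes, 1L)
    key <- paste(s, t)
    if (s != t && !exists(key, envir = seen, inherits = FALSE)) {
      m <- m + 1L; src[m] <- s; dst[m] <- t
      outdeg[s] <- outdeg[s] + 1
      assign(key, TRUE, envir = seen)
    }
  }
  ids <- sprintf("n%04d", seq_len(n_nodes))
  g <- igraph::graph_from_edgelist(cbind(ids[src], ids[dst]), directed = TRUE)
  igraph::permute(g, match(igraph::V(g)$name, ids))
}

#' Generate a planted-partition weighted graph
#'
#' Blocks of nodes connect with probability `p_in` inside a block and
#' `p_out` between blocks (undirected); edges get uniform weights in
#' (0, 1]. Used to benchmark [detect_modules()] against a known partition.
#'
#' @param block_sizes Integer vector of block sizes.
#' @param p_in,p_out Within- and between-block edge probabilities;
#'   `p_in > p_out` required.
#' @param seed Integer seed.
#' @return List with `graph` (weighted undirected igraph) and `labels`
#'   (integer block label per node, named).
#' @export
generate_modular_graph <- function(block_sizes, p_in, p_out, seed = 1) {
  stopifnot(length(block_sizes) >= 1, all(block_sizes >= 1))
  if (!(p_in > p_out)) stop("`p_in` must exceed `p_out`")
  if (p_in > 1 || p_out < 0) stop("probabilities must lie in [0, 1]")
  set.seed(seed)
  b <- length(block_sizes)
  pref <- matrix(p_out, b, b); diag(pref) <- p_in
  g <- igraph::sample_sbm(sum(block_sizes), pref.matrix = pref,
                          block.sizes = block_sizes, directed = FALSE)
  igraph::V(g)$name <- sprintf("v%03d", seq_len(sum(block_sizes)))
  if (igraph::ecount(g) > 0) {
    w <- runif(igraph::ecount(g))
    w[w == 0] <- 1   # keep weights in (0, 1]
    igraph::E(g)$weight <- w
  }
  labels <- setNames(rep(seq_len(b), block_sizes), igraph::V(g)$name)
  list(graph = g, labels = labels)
}
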