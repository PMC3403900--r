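#' Pipeline configuration
#'
#' Collects every input path and tunable parameter of the end-to-end run.
#' All defaults are the analysis defaults used throughout the package:
#' Cook's distance threshold 0.5, correlation cutoffs 0.6 (TF) / 0.45
#' (miRNA) when not scanned, core betweenness quantile 0.99, walktrap
#' length 4.
#'
#' @param tu_path,an_path,probe_map_path Expression inputs (TSV; see
#'   [read_expression_matrix()], [read_probe_map()]).
#' @param predicted_path,experimental_path Interaction adjacency lists
#'   (TSV; `experimental_path` may be `NULL`).
#' @param gmt_path Optional GMT annotation file; enables the enrichment
#'   stage.
#' @param out_dir Output directory for stage artifacts.
#' @param alpha Ratio penalty; `NULL` (default) computes it from the panel.
#' @param cooks_threshold Cook's distance outlier cutoff.
#' @param min_samples Minimum retained samples per scored pair.
#' @param grid,tol,window Cutoff scan grid and steady-state rule (see
#'   [scan_cutoffs()], [select_cutoff()]).
#' @param c_tf,c_mirna Fixed correlation cutoffs; when both are set the
#'   scan stage is skipped.
#' @param core_quantile Edge-betweenness quantile for the core network.
#' @param walk_steps Walktrap random-walk length.
#' @param seed Integer seed (the pipeline itself is deterministic; the seed
#'   is recorded and set for reproducibility of any downstream sampling).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(tu_path, an_path, probe_map_path, predicted_path,
                            experimental_path = NULL, gmt_path = NULL,
                            out_dir = "coregrn_out", alpha = NULL,
                            cooks_threshold = 0.5, min_samples = 10,
                            grid = seq(0, 0.9, by = 0.05), tol = 0.05,
                            window = 2, c_tf = NULL, c_mirna = NULL,
                            core_quantile = 0.99, walk_steps = 4, seed = 1) {
  cfg <- list(tu_path = tu_path, an_path = an_path,
              probe_map_path = probe_map_path, predicted_path = predicted_path,
              experimental_path = experimental_path, gmt_path = gmt_path,
              out_dir = out_dir, alpha = alpha,
              cooks_threshold = cooks_threshold, min_samples = min_samples,
              grid = grid, tol = tol, window = window, c_tf = c_tf,
              c_mirna = c_mirna, core_quantile = core_quantile,
              walk_steps = walk_steps, seed = seed)
  if (!is.null(alpha) && alpha <= 0) stop("`alpha` must be positive")
  if (cooks_threshold <= 0) stop("`cooks_threshold` must be positive")
  if (min_samples < 4) stop("`min_samples` must be at least 4")
  if (any(grid < 0 | grid >= 1)) stop("`grid` must lie in [0, 1)")
  for (cc in c(c_tf, c_mirna)) {
    if (!is.null(cc) && (cc < 0 || cc >= 1)) stop("cutoffs must lie in [0, 1)")
  }
  if (core_quantile < 0 || core_quantile >= 1) {
    stop("`core_quantile` must lie in [0, 1)")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML round-trip is lossless for every field, so a written
#' configuration re-runs identically.
#'
#' @param path YAML file path.
#' @return For `read_pipeline_config()`, a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$grid <- as.numeric(raw$grid)
  do.call(pipeline_config, raw)
}

#' @param config A [pipeline_config()].
#' @rdname read_pipeline_config
#' @return For `write_pipeline_config()`, `path` invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full GRN construction and core-extraction pipeline
#'
#' Executes, in order: penalized ratio computation and probe merging;
#' candidate network assembly and restriction to measured entities; edge
#' scoring; per-class cutoff scans and steady-state selection (skipped when
#' both cutoffs are fixed in the config); GRN construction; largest
#' component; walktrap modules; edge betweenness; core extraction; loop
#' counting; and, when a GMT file is configured, per-module
#' over-representation analysis. Every stage writes a plain TSV/JSON
#' artifact into `config$out_dir` so any stage can be inspected or re-run
#' standalone; a failure halts with the stage's name while earlier
#' artifacts remain on disk.
#'
#' @param config A [pipeline_config()].
#' @return The artifact manifest: list with `paths` (named vector of
#'   written files) and `summary` (the summary statistics also written as
#'   JSON: node/edge counts by class, experimental-evidence edge count,
#'   component fraction, module count and coverage, selected cutoffs, core
#'   edge and betweenness fractions, loop counts, modularity).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  paths <- c()

  panel <- stage("expression", {
    expression_panel(read_expression_matrix(config$tu_path),
                     read_expression_matrix(config$an_path),
                     read_probe_map(config$probe_map_path))
  })
  ratios <- stage("expression", {
    alpha <- if (is.null(config$alpha)) compute_alpha(panel) else config$alpha
    merge_probes(compute_ratios(panel, alpha), panel$probe_map)
  })
  stats_df <- stage("expression", differential_stats(ratios))
  write_matrix_tsv(ratios$values, p("ratios.tsv"), id_name = "entity")
  write.table(stats_df, p("stats.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, ratios = p("ratios.tsv"), stats = p("stats.tsv"))

  candidates <- stage("candidate_network", {
    pred <- load_interactions(config$predicted_path, "predicted")
    cand <- if (!is.null(config$experimental_path)) {
      merge_sets(pred, load_interactions(config$experimental_path, "experimental"))
    } else pred
    restrict_to_measured(cand, rownames(ratios$values))
  })

  scored <- stage("coexpression", {
    score_edges(candidates, ratios, config$cooks_threshold, config$min_samples)
  })
  scored_out <- scored
  write.table(scored_out, p("scored_edges.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths <- c(paths, scored_edges = p("scored_edges.tsv"))

  scanned <- is.null(config$c_tf) || is.null(config$c_mirna)
  cutoffs <- c(TF = config$c_tf %||% NA_real_, miRNA = config$c_mirna %||% NA_real_)
  if (scanned) {
    for (cls in c("TF", "miRNA")) {
      scan <- stage("scalefree_cutoff", {
        scan_cutoffs(candidates, ratios, cls, grid = config$grid,
                     scored = scored)
      })
      f <- p(sprintf("cutoff_scan_%s.tsv", cls))
      write.table(scan, f, sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, setNames(f, paste0("scan_", cls)))
      if (is.na(cutoffs[[cls]])) {
        cutoffs[[cls]] <- stage("scalefree_cutoff",
                                select_cutoff(scan, config$tol, config$window))
      }
    }
  }

  net <- stage("build_grn", {
    build_grn(candidates, ratios, class_cutoffs = cutoffs, scored = scored)
  })
  comp <- stage("largest_component", largest_component(net))
  write_interactions(interaction_set(comp$edges), p("grn_edges.tsv"))
  paths <- c(paths, grn_edges = p("grn_edges.tsv"))

  modules <- stage("detect_modules", detect_modules(comp, steps = config$walk_steps))
  mod_df <- data.frame(node = names(modules$assignment),
                       class = setNames(comp$nodes$class, comp$nodes$id)[names(modules$assignment)],
                       module_id = unname(modules$assignment),
                       stringsAsFactors = FALSE)
  write.table(mod_df, p("modules.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, modules = p("modules.tsv"))

  eb <- stage("edge_betweenness", edge_betweenness_scores(comp))
  core <- stage("extract_core", extract_core(comp, config$core_quantile, eb))
  write.table(core$edges, p("core_edges.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths <- c(paths, core_edges = p("core_edges.tsv"))
  loops <- stage("count_loops", count_loops(core))

  if (!is.null(config$gmt_path)) {
    enr <- stage("enrichment", {
      ann <- read_gmt(config$gmt_path)
      top <- seq_len(min(6, length(modules$sizes)))
      rows <- lapply(top, function(m) {
        members <- names(modules$assignment)[modules$assignment == m]
        genes <- intersect(members, ann$background)
        if (length(genes) == 0) return(NULL)
        res <- hypergeom_enrich(genes, ann)
        if (nrow(res) == 0) return(NULL)
        cbind(module = m, res)
      })
      do.call(rbind, rows)
    })
    if (!is.null(enr)) {
      write.table(enr, p("enrichment.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      paths <- c(paths, enrichment = p("enrichment.tsv"))
    }
  }

  edge_class <- ifelse(comp$edges$regulator_class == "miRNA", "miRNA->gene",
                       ifelse(comp$edges$target_class == "miRNA",
                              "TF->miRNA", "TF->gene"))
  six <- seq_len(min(6, length(modules$sizes)))
  summary <- list(
    seed = config$seed,
    alpha = ratios$alpha,
    cutoffs = list(TF = unname(cutoffs[["TF"]]), miRNA = unname(cutoffs[["miRNA"]]),
                   scanned = scanned),
    n_nodes_global = nrow(net$nodes),
    n_nodes = nrow(comp$nodes),
    n_edges = nrow(comp$edges),
    n_regulators = list(TF = sum(comp$nodes$class == "TF"),
                        miRNA = sum(comp$nodes$class == "miRNA")),
    edges_by_class = as.list(table(edge_class)),
    experimental_edges = sum(comp$edges$experimental),
    component_fraction = attr(comp, "component_fraction"),
    n_modules = length(modules$sizes),
    module_coverage = sum(modules$sizes[six]) / sum(modules$sizes),
    modularity = modules$modularity,
    core = list(n_edges = nrow(core$edges),
                n_nodes = igraph::vcount(core$graph),
                edge_fraction = core$edge_fraction,
                betweenness_fraction = core$betweenness_fraction,
                feedforward = unname(loops[["feedforward"]]),
                feedback = unname(loops[["feedback"]])))
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths <- c(paths, summary = p("summary.json"))
  list(paths = paths, summary = summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
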