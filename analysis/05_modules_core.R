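#!/usr/bin/env Rscript
# Stage 5: modules and the core network.
#
# Walktrap community detection on the largest component (weights |r|),
# directed unweighted edge betweenness, extraction of the core as the
# edges above the 99% betweenness quantile, and loop-motif counts.

suppressPackageStartupMessages(library(coregrn))

ratios <- as_ratio_matrix(read_expression_matrix("results/ratios.tsv"),
                          alpha = as.numeric(readLines("results/alpha.txt")))
candidates <- load_interactions("results/sim/interactions.tsv", "predicted")
candidates <- restrict_to_measured(candidates, rownames(ratios$values))
scored <- read.delim("results/scored_edges.tsv")
net <- build_grn(candidates, ratios, class_cutoffs = c(TF = 0.6, miRNA = 0.45),
                 scored = scored)
comp <- largest_component(net)

modules <- detect_modules(comp)
mod_df <- data.frame(node = names(modules$assignment),
                     class = setNames(comp$nodes$class, comp$nodes$id)[names(modules$assignment)],
                     module_id = unname(modules$assignment))
write.table(mod_df, "results/modules.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
six <- seq_len(min(6, length(modules$sizes)))
message(length(modules$sizes), " modules, modularity ",
        signif(modules$modularity, 3), "; the ", length(six),
        " largest cover ", round(100 * sum(modules$sizes[six]) /
                                   sum(modules$sizes), 1), "% of nodes")
for (m in six) {
  message("  module ", m, " (", modules$sizes[m], " nodes): regulators ",
          paste(head(modules$regulators[[m]], 6), collapse = ", "))
}

eb <- edge_betweenness_scores(comp)
core <- tryCatch(extract_core(comp, quantile = 0.99, betweenness = eb),
                 warning = function(w) {
                   message("note: ", conditionMessage(w))
                   suppressWarnings(extract_core(comp, 0.99, eb))
                 })
write.table(core$edges, "results/core_edges.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
loops <- count_loops(core)
message(sprintf(paste0("core: %d edges (%.2f%% of edges, %.1f%% of total ",
                       "betweenness), %d feedforward / %d feedback loops"),
                nrow(core$edges), 100 * core$edge_fraction,
                100 * core$betweenness_fraction,
                loops[["feedforward"]], loops[["feedback"]]))

summary <- list(
  n_nodes = nrow(comp$nodes), n_edges = nrow(comp$edges),
  modularity = modules$modularity, n_modules = length(modules$sizes),
  module_coverage_top6 = sum(modules$sizes[six]) / sum(modules$sizes),
  core_edges = nrow(core$edges), core_edge_fraction = core$edge_fraction,
  core_betweenness_fraction = core$betweenness_fraction,
  feedforward = unname(loops[["feedforward"]]),
  feedback = unname(loops[["feedback"]]))
jsonlite::write_json(summary, "results/network_summary.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("wrote results/network_summary.json")
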