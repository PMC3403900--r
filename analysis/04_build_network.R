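#!/usr/bin/env Rscript
# Stage 4: build the gene regulatory network and benchmark it against the
# planted truth.
#
# Applies the three acceptance conditions (candidate membership, negative
# miRNA correlation, |r| above the per-class cutoff) at the reference
# cutoffs 0.6 (TF) / 0.45 (miRNA), extracts the largest weakly connected
# component, and - because this cohort is synthetic - scores planted-edge
# recovery.

suppressPackageStartupMessages(library(coregrn))

sim <- "results/sim"
ratios <- as_ratio_matrix(read_expression_matrix("results/ratios.tsv"),
                          alpha = as.numeric(readLines("results/alpha.txt")))
candidates <- load_interactions(file.path(sim, "interactions.tsv"), "predicted")
candidates <- restrict_to_measured(candidates, rownames(ratios$values))
scored <- read.delim("results/scored_edges.tsv")

cutoffs <- c(TF = 0.6, miRNA = 0.45)
net <- build_grn(candidates, ratios, class_cutoffs = cutoffs, scored = scored)
comp <- largest_component(net)
write_interactions(interaction_set(comp$edges), "results/grn_edges.tsv")
write.table(comp$edges, "results/grn_edges_scored.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message("global GRN: ", nrow(net$nodes), " nodes, ", nrow(net$edges), " edges")
message("largest component: ", nrow(comp$nodes), " nodes (",
        round(100 * attr(comp, "component_fraction"), 1), "% of nodes), ",
        nrow(comp$edges), " edges")
cls <- ifelse(comp$edges$regulator_class == "miRNA", "miRNA->gene",
              ifelse(comp$edges$target_class == "miRNA", "TF->miRNA", "TF->gene"))
message("edge classes: ", paste(names(table(cls)), table(cls),
                                sep = "=", collapse = ", "))
message("experimentally supported edges: ", sum(comp$edges$experimental))

truth <- read.delim(file.path(sim, "truth.tsv"))
found <- paste(net$edges$regulator, net$edges$target)
planted <- paste(truth$regulator, truth$target)[truth$is_true]
message(sprintf("planted-edge recovery: precision %.3f, recall %.3f",
                mean(found %in% planted), mean(planted %in% found)))
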