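#!/usr/bin/env Rscript
# Stage 3: correlation-cutoff selection by the scale-free criterion.
#
# Scores every candidate edge once (Cook's outlier removal + Pearson),
# then sweeps the cutoff grid separately for TF- and miRNA-regulated
# subnetworks, fitting power-law and truncated power-law models to the in-
# and out-degree distributions, and picks the cutoff where both R^2 curves
# first reach a steady state.

suppressPackageStartupMessages(library(coregrn))

sim <- "results/sim"
ratios <- as_ratio_matrix(read_expression_matrix("results/ratios.tsv"),
                          alpha = as.numeric(readLines("results/alpha.txt")))
candidates <- load_interactions(file.path(sim, "interactions.tsv"), "predicted")
candidates <- restrict_to_measured(candidates, rownames(ratios$values))

scored <- score_edges(candidates, ratios)
write.table(scored, "results/scored_edges.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sum(scored$scorable), "/", nrow(scored), " candidate edges scorable; ",
        sum(scored$n_outliers), " outlier samples removed in total")

selected <- c(TF = NA_real_, miRNA = NA_real_)
scans <- list()
for (cls in c("TF", "miRNA")) {
  scan <- scan_cutoffs(candidates, ratios, cls, scored = scored)
  scans[[cls]] <- scan
  write.table(scan, sprintf("results/cutoff_scan_%s.tsv", cls), sep = "\t",
              quote = FALSE, row.names = FALSE)
  selected[[cls]] <- tryCatch(select_cutoff(scan),
                              warning = function(w) {
                                message(cls, ": ", conditionMessage(w))
                                suppressWarnings(select_cutoff(scan))
                              })
  message(cls, ": steady-state cutoff ", selected[[cls]])
}
yaml::write_yaml(as.list(selected), "results/selected_cutoffs.yaml")

# R^2-vs-cutoff panel (the cutoff-selection diagnostic figure)
if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  df <- do.call(rbind, scans)
  long <- rbind(
    data.frame(class = df$regulator_class, cutoff = df$cutoff,
               direction = "in", r2 = df$r2_in),
    data.frame(class = df$regulator_class, cutoff = df$cutoff,
               direction = "out", r2 = df$r2_out))
  p <- ggplot(long, aes(cutoff, r2, color = direction)) +
    geom_line() + geom_point(size = 1) +
    facet_wrap(~class) +
    labs(x = "|correlation| cutoff", y = expression(R^2),
         title = "Scale-free goodness-of-fit across correlation cutoffs") +
    theme_bw()
  dir.create("results/figures", showWarnings = FALSE)
  ggsave("results/figures/cutoff_scan.png", p, width = 7, height = 3.2, dpi = 150)
  message("wrote results/figures/cutoff_scan.png")
}
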