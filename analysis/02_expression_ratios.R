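#!/usr/bin/env Rscript
# Stage 2: penalized tumor/normal log-ratios and differential statistics.
#
# Computes the penalty alpha from the pooled 25% intensity quantiles,
# converts paired intensities to log2((TU + a)/(AN + a)), merges probes to
# entities, and reports per-entity one-sample t statistics.

suppressPackageStartupMessages(library(coregrn))

sim <- "results/sim"
panel <- expression_panel(read_expression_matrix(file.path(sim, "tu.tsv")),
                          read_expression_matrix(file.path(sim, "an.tsv")),
                          read_probe_map(file.path(sim, "probe_map.tsv")))
alpha <- compute_alpha(panel)
ratios <- merge_probes(compute_ratios(panel, alpha), panel$probe_map)
stats_df <- differential_stats(ratios)

write_matrix_tsv(ratios$values, "results/ratios.tsv", id_name = "entity")
writeLines(as.character(alpha), "results/alpha.txt")
write.table(stats_df, "results/stats.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message("penalty alpha = ", signif(alpha, 6))
message("entities: ", nrow(ratios$values), " x ", ncol(ratios$values), " patients")
sig <- stats_df[!is.na(stats_df$p) & stats_df$p < 1e-6, ]
message(nrow(sig), " entities differential at p < 1e-6 (",
        sum(sig$t > 0), " up, ", sum(sig$t < 0), " down)")
top <- sig[order(sig$p), ][1:min(5, nrow(sig)), ]
message("strongest: ", paste(top$entity, collapse = ", "))
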