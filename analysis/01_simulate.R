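#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Generates a paired tumor / adjacent non-tumor intensity panel for 96
# patients with planted TF and miRNA regulations (TF correlations 0.8 of
# either sign, miRNA correlations -0.6), a candidate network that is half
# decoys, and 5% of gene-target edges corrupted by one 8-SD outlier
# sample. Everything downstream runs from the files written here.

suppressPackageStartupMessages(library(coregrn))

out <- "results/sim"
cfg <- synthetic_config(n_genes = 300, n_tfs = 25, n_mirnas = 15,
                        n_patients = 96, tf_signal = 0.8, mirna_signal = 0.6,
                        decoy_edge_fraction = 0.5, outlier_fraction = 0.05,
                        n_modules = 4, seed = 20260926)
bundle <- generate_panel(cfg)
paths <- write_panel(bundle, out)
labs <- bundle$truth$module_labels
write.table(data.frame(entity = names(labs), planted_module = unname(labs)),
            file.path(out, "module_labels.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

message("cohort: ", ncol(bundle$panel$tu), " patient pairs, ",
        nrow(bundle$panel$tu), " probes")
message("candidate network: ", nrow(bundle$interactions), " edges (",
        nrow(bundle$truth$true_edges), " planted, ",
        nrow(bundle$interactions) - nrow(bundle$truth$true_edges), " decoys)")
message("outlier-corrupted edges: ", nrow(bundle$truth$outlier_positions))
message("wrote: ", paste(paths, collapse = ", "))
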