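#!/usr/bin/env Rscript
# Stage 6: over-representation analysis of the detected modules.
#
# Builds a toy annotation collection from the planted module labels (one
# gene set per planted module) and asks whether the detected modules are
# enriched for them - on synthetic data this doubles as a check that
# detected modules align with the planted regulator groups. With real
# data, point read_gmt() at GO/KEGG GMT files instead.

suppressPackageStartupMessages(library(coregrn))

mods <- read.delim("results/modules.tsv")
labels <- read.delim("results/sim/module_labels.tsv")

# gene sets = planted modules, taken from the generator's labels
ann <- annotation_collection(
  split(labels$entity, paste0("PLANTED", labels$planted_module)),
  background = labels$entity)

rows <- lapply(sort(unique(mods$module_id)), function(m) {
  members <- mods$node[mods$module_id == m]
  res <- suppressWarnings(hypergeom_enrich(members, ann))
  if (nrow(res) == 0) return(NULL)
  cbind(module = m, res)
})
enr <- do.call(rbind, rows)
write.table(enr, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

hits <- enr[enr$fdr < 0.01, ]
message(nrow(hits), " module/term pairs enriched at FDR < 0.01")
for (m in sort(unique(hits$module))) {
  best <- hits[hits$module == m, ][1, ]
  message(sprintf("  detected module %d <-> %s (overlap %d/%d, FDR %.2e)",
                  m, best$term, best$overlap, best$term_size, best$fdr))
}
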