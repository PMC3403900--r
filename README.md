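# coregrn

Construction and dissection of gene regulatory networks (GRNs) with both
transcription factor (TF) and microRNA (miRNA) regulators, from paired
tumor / adjacent non-tumor expression data.

Candidate interactions alone (sequence-based target predictions, curated
experimental regulations) are noisy and tissue-agnostic; expression
correlation alone cannot tell direct from indirect regulation. coregrn
intersects the two: a candidate edge `regulator -> target` enters the GRN
only if

1. it exists in the candidate network (predicted or experimentally
   supported),
2. the regulator-target correlation is negative when the regulator is a
   miRNA (miRNAs repress; TF correlations may take either sign), and
3. the absolute Pearson correlation — computed after removing samples
   with Cook's distance > 0.5 in a per-pair `regulator ~ target`
   regression — exceeds the cutoff of the regulator's class.

Expression enters as penalized paired log-ratios,
`log2((TU + a) / (AN + a))` with
`a = (q0.25(TU) + q0.25(AN)) / 2`, which keeps ratios of small intensities
tame. Per-class correlation cutoffs (defaults: 0.6 for TFs, 0.45 for
miRNAs) can be chosen by the **scale-free topological criterion**: sweep
the cutoff grid, fit each network's in-/out-degree distributions to
`P(k) ~ k^-gamma` and `P(k) ~ k^-lambda * exp(-alpha*k)` by least squares
on log frequencies, and take the first cutoff where both R² curves reach a
steady state. Downstream, the package extracts the largest weak component,
detects modules with walktrap (edge weights |r|), and isolates the **core
GRN** — the edges strictly above the 99% quantile of directed
edge-betweenness, the thin set of regulations that carries most of the
network's shortest-path traffic. A hypergeometric + Benjamini–Hochberg
over-representation module handles gene-set annotation (GMT files).

A fully seeded synthetic-data generator plants known regulations
(TF signal 0.8, miRNA signal −0.6, decoy candidates, outlier samples,
heavy-tailed out-degrees, a connected regulator hierarchy) so every stage
is exercised and benchmarked end to end without any external downloads.

## Worked example

The `analysis/` directory is a numbered workflow over the package; running
it end to end on the built-in synthetic cohort:

```sh
Rscript analysis/01_simulate.R          # 96 patient pairs, 678 candidate edges
Rscript analysis/02_expression_ratios.R
Rscript analysis/03_scan_cutoffs.R
Rscript analysis/04_build_network.R
Rscript analysis/05_modules_core.R
Rscript analysis/06_enrichment.R
```

prints, among other things:

```
penalty alpha = 140.881
151 entities differential at p < 1e-6 (92 up, 59 down)
678/678 candidate edges scorable; 52 outlier samples removed in total
global GRN: 339 nodes, 370 edges
largest component: 339 nodes (100% of nodes), 370 edges
edge classes: miRNA->gene=51, TF->gene=303, TF->miRNA=16
planted-edge recovery: precision 0.914, recall 0.997
16 modules, modularity 0.817; the 6 largest cover 61.7% of nodes
core: 4 edges (1.08% of edges, 35.5% of total betweenness)
```

Read: the co-expression filter keeps 370 of 678 candidates, recovering
planted regulations at precision 0.91 / recall 1.00 while the 339
decoys are almost entirely rejected; the accepted network is one connected
component; walktrap's largest modules line up with the planted regulator
groups (stage 6 confirms each detected module is enriched for exactly one
planted gene set); and the core — ~1% of edges — carries over a third of
all betweenness, i.e. it is the traffic backbone of the network. Stage
artifacts (ratio matrix, scored edges, cutoff-scan tables and figure,
module and core edge lists, summary JSON) land under `results/`.

The same machinery runs on real data by pointing
`pipeline_config()`/`run_pipeline()` (or the individual stage functions)
at your own TSV intensity matrices, probe map, interaction adjacency
lists, and GMT annotations.

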