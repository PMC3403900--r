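---
title: "Methods: building and dissecting TF/miRNA regulatory networks from paired expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and dissecting TF/miRNA regulatory networks from paired expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

coregrn reconstructs a gene regulatory network (GRN) whose regulators are
transcription factors (TFs) and microRNAs (miRNAs), from two ingredients: a
*candidate network* of possible regulator-target interactions (sequence
predictions plus experimentally supported regulations, supplied as files),
and paired tumor (TU) / adjacent non-tumor (AN) expression profiles that
decide which candidates are actually active in the tissue at hand. This
vignette records the model, its tunable parameters, and the numerical and
design choices behind the implementation.

## The expression model

Paired designs allow each patient to act as their own control. For probe
$i$ and patient $j$ we form the penalized log-ratio

$$\mathrm{ratio}_{ij} = \log_2 \frac{\mathrm{TU}_{ij} + \alpha}{\mathrm{AN}_{ij} + \alpha},
\qquad
\alpha = \frac{q_{0.25}(\mathrm{TU}) + q_{0.25}(\mathrm{AN})}{2},$$

where each $q_{0.25}$ is the 25% quantile pooled over *every entry* of the
respective intensity matrix. The penalty keeps ratios of two small (hence
noisy) intensities from exploding; as $\alpha \to \infty$ all ratios shrink
to 0, and swapping TU and AN exactly negates the matrix (both are tested
properties). Two readings of the quantile are possible — pooled over the
whole matrix, or per patient and then averaged. The formula writes a single
scalar per tissue class, so the pooled reading is implemented; `alpha` can
also be fixed explicitly in the pipeline configuration. Quantiles use R's
default linear interpolation between order statistics (`type = 7`)
throughout the package, including the core-network quantile below.

Probes are merged to entities *after* the ratio computation by averaging
probe rows (so the entity value is the mean of probe ratios, not the ratio
of mean intensities), and per-entity differential statistics are one-sample
two-sided t-tests of the log-ratios against zero: positive $t$ means
up-regulation in tumor. Zero-variance rows are reported as `NA`, never an
error.

## The co-expression filter

A candidate regulation `regulator -> target` survives when all three
conditions hold:

1. it exists in the candidate network (predicted or experimentally
   supported);
2. if the regulator is a miRNA, the correlation with its target is
   negative (miRNAs repress their targets post-transcriptionally; TF
   correlations may take either sign, since TFs activate or repress);
3. the absolute Pearson correlation exceeds the cutoff of the regulator's
   class.

Correlations are made outlier-robust per pair: with the regulator profile
as response $y$ and the target profile as predictor $x$, a univariate
regression is fitted and samples with Cook's distance $D > 0.5$ are
removed, in a single pass, before computing Pearson's $r$ on the rest.
Cook's distance is computed in closed form
($D_i = e_i^2 h_i / (2 s^2 (1-h_i)^2)$) and is pinned in the tests against
a brute-force leave-one-out refitting oracle to $10^{-10}$. Choices worth
recording:

* The regression orientation is $y$ (regulator) on $x$ (target). Cook's
  distances are orientation-sensitive, so the orientation is fixed and
  documented rather than left to chance.
* Outlier removal happens once; there is no iteration to convergence.
* Pairs with fewer than `min_samples = 10` retained samples, or zero
  variance, are *unscorable*: they are dropped with a logged count, never
  imputed. The floor guards against nonsense correlations computed on a
  handful of points; it is a package default, not a quantity estimated
  from data.
* No sign constraint is applied to TF→miRNA edges: a TF may induce or
  repress a miRNA, and condition 2 concerns only miRNA regulators.

## Choosing the cutoffs: the scale-free criterion

TF and miRNA regulation strengths differ systematically, so the two
classes get independent cutoffs (defaults 0.6 for TFs, 0.45 for miRNAs).
To choose them from data, `scan_cutoffs()` sweeps a grid (default 0 to 0.9
in steps of 0.05) and, at each cutoff, builds the class-restricted network
and fits its in- and out-degree distributions to

$$P(k) \sim k^{-\gamma}
\quad\text{and}\quad
P(k) \sim k^{-\lambda} e^{-\alpha k},$$

by ordinary least squares on the log-transformed relative frequencies
(raw, unbinned, over degrees $k \ge 1$; zero-degree nodes carry no tail
information). OLS on logs is used deliberately: it yields an $R^2$ in
$[0,1]$ as the goodness-of-fit scale, recovers the exponents exactly on
noise-free input, and the truncated model nests the power law, so its
$R^2$ can never be lower — both facts are asserted in the tests.
Maximum-likelihood power-law machinery (Clauset-style) produces no natural
$R^2$ and is out of scope. Degenerate fits (fewer than 3, respectively 4,
support points, or flat distributions) report $R^2 = 0$, the same
convention under which an unfiltered candidate network shows up as
"completely not scale-free".

The selected cutoff is where the $R^2$ curves *first reach a steady
state*: the smallest grid cutoff whose next `window = 2` grid points stay
within `tol = 0.05` for both the in- and the out-direction. Grid points
with fewer than `window` successors cannot qualify, and appending grid
points above the selected steady state cannot change the selection. If no
point qualifies the scan falls back, with a warning, to the cutoff
maximizing $\min(R^2_{in}, R^2_{out})$. The per-direction $R^2$ is the
better of the two model fits, reading the fit of either admissible shape
as evidence of scale-freeness.

## Network analysis

* **Largest component.** Connectivity is weak (direction-ignoring):
  regulatory networks have sources (TFs, miRNAs) and sinks (genes), so
  strong connectivity would shatter them. Size ties are broken toward the
  component containing the lexicographically smallest node id.
* **Modules.** Walktrap community detection (random walks of length 4,
  partition at maximal modularity) on the undirected view, with $|r|$ as
  edge weights; the cited algorithm is defined for undirected weighted
  graphs. Reciprocal edge pairs collapse to one undirected edge carrying
  the larger weight.
* **Edge betweenness.** Shortest directed unweighted paths between all
  ordered node pairs, with tied geodesics split fractionally. The
  directed/fractional convention is pinned against an exhaustive
  enumeration oracle on small graphs; an undirected mode sits behind
  `directed = FALSE` since hop-count betweenness on a regulation graph can
  be read either way.
* **Core network.** The threshold is the empirical 0.99 quantile of *all*
  edge betweenness values; the core keeps edges strictly above it
  ("larger than", not "at least"). The regulator-only character of the
  core is *observed, not imposed*: thresholding happens before any
  node-type restriction, and a core edge touching a gene raises a warning
  rather than being filtered away. This matches a core that covers almost
  exactly $1 - 0.99$ of edges when betweenness values are distinct.
* **Loops.** Feedforward loops are ordered triples with edges $A\to B$,
  $B \to C$, $A \to C$; feedback loops are directed cycles of length 2 or
  3, counted once per node set and edge configuration (the two
  orientations of a triangle count separately, rotations do not). Both
  counts are oracle-checked by exhaustive enumeration.

## Over-representation analysis

Module gene lists (or miRNA lists) are tested against user-supplied GMT
annotation collections with the one-sided hypergeometric upper-tail test,
and FDRs are Benjamini–Hochberg adjusted. The hypergeometric test is the
generic stand-in for external web tools whose database snapshots are not
reproducible; it is oracle-checkable (the tests compare against exhaustive
enumeration of draws on a toy universe). Query ids outside the declared
background are dropped with a warning, since the test conditions on the
background universe.

## The synthetic cohort

`generate_panel()` produces everything the pipeline consumes plus the
ground truth, from one seed:

* 96 patient pairs by default — a realistic paired-cohort size for this
  kind of tumor study.
* Intensities are generated on the log2 scale and exponentiated
  (positive, roughly log-normal, like RMA output), with entity baselines
  around $2^8$ and small (SD 0.15) per-patient technical noise on the AN
  side.
* Correlation planting uses a shared latent factor: a target's log-ratio
  profile is $\rho \cdot z_{reg} + \sqrt{1-\rho^2}\,\varepsilon$ with
  $z_{reg}$ the standardized regulator profile, so the expected Pearson
  correlation *is* the planted $\rho$. TF regulations use
  $|\rho| = 0.8$ with random sign; miRNA regulations use $\rho = -0.6$
  (regulation strength differs between the classes, with miRNA
  correlations negative by construction).
* The regulator layer forms one hierarchy: every TF after the first is
  regulated by an earlier, preferentially chosen TF, and every miRNA by a
  TF; genes attach to regulators by preferential attachment, making
  out-degrees heavy-tailed and the planted network weakly connected.
* Each entity gets a tumor/normal mean shift (SD 0.7 on the log2 scale),
  so differential statistics have dysregulation to find; mean shifts do
  not alter Pearson correlations.
* 5% of gene-target edges get one sample of the target profile replaced
  by a point 8 SD out — far enough that Cook's distance detection at
  threshold 0.5 is guaranteed in practice (6 SD is already reliably
  flagged).
* The candidate network is the planted edges plus an equal number of
  uniform decoys (50% decoy fraction), excluding self-loops and
  miRNA→miRNA pairs; 15% of planted edges are additionally flagged as
  experimentally supported, for bookkeeping realism.

What the generator does *not* emulate: probe-level artifacts, batch
effects, RMA normalization itself, indirect correlations between entities
that share no planted edge (decoys are truly null), co-regulation of one
target by several regulators, and the database biases of real candidate
networks. Passing tests therefore demonstrate that the machinery recovers
structure it was designed to detect under controlled conditions, not that
it would perform identically on real cohorts.

Two companion generators serve the topology code: a preferential-attachment
digraph with a fixed node and edge count (growth phase guarantees weak
connectivity; extra edges choose sources preferentially, keeping
out-degrees heavy-tailed), and a planted-partition (stochastic block model)
graph with uniform $(0,1]$ edge weights for the module-recovery benchmark.

## Problem sizes and numerical conventions

The test suite and analysis scripts run at deliberately modest sizes — a
340-entity, 96-patient cohort with ~680 candidate edges for the pipeline
benchmarks; 1700 nodes / 4200 edges for the topology benchmark (the scale
of the real network the method was designed around); 90-node
planted-partition graphs for module recovery — chosen so the whole suite
completes in seconds while each statistical check retains comfortable
margins (e.g., planted-edge recovery precision and recall sit near 0.91
and 1.0 against a 0.8 acceptance bar). Further conventions:

* all quantiles: linear interpolation, `type = 7`;
* Cook's distance for a perfect fit ($s^2 = 0$): all zero, no outliers;
* `select_cutoff` on a scan shorter than `window + 1`: fallback rule;
* empty networks during a scan keep their grid row with $R^2 = 0$ and
  size 0;
* module ids are renumbered by decreasing size (ties by smallest member
  id) so partitions are stable across runs.

## Limitations

The co-expression filter is marginal (per-pair): it cannot distinguish
direct from indirect regulation, which is exactly why candidate-network
membership is condition 1. Partial correlation, multivariate regression
and mutual-information scoring are deliberate non-goals. The scale-free
criterion assumes the true tissue network is approximately scale-free; for
networks where that assumption fails, the steady-state rule still returns
a cutoff but its biological justification is weaker (the scan table and
figure are written out so the curves can be inspected). Enrichment ships
no annotation databases; results depend entirely on the GMT files
supplied.
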