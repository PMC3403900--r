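Package: coregrn
Title: Core Gene Regulatory Network Construction from Paired Tumor/Normal
    Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds transcription-factor and microRNA gene regulatory
    networks from paired tumor / adjacent non-tumor expression matrices.
    Candidate regulator-target interactions (sequence-predicted and
    experimentally supported) are filtered by an outlier-robust
    co-expression model: penalized log2 tumor/normal ratios, Cook's
    distance outlier removal, and per-regulator-class correlation cutoffs
    selected by a scale-free topological criterion. Downstream analyses
    extract the largest connected component, detect modules with the
    walktrap random-walk algorithm, and isolate a core network of top
    edge-betweenness regulations, with generic hypergeometric
    over-representation analysis for module gene lists. A synthetic-data
    generator with planted regulations exercises every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    fgsea,
    ggplot2,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
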