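Package: gfconcord
Title: Multi-Omics Concordance Analysis of Germfree versus Conventional Intestine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparing germfree (GF) and conventionally
    raised (C) mouse intestine across transcriptome, proteome and cross-study
    meta-analysis layers. Implements two-colour microarray preprocessing
    (background capping, net-intensity flooring, replicate collapsing,
    intra-array LOWESS and inter-array LOESS normalization), reference-free
    ANOVA with array effects and post hoc pairwise contrasts, three-way
    factorial ANOVA with per-parameter minimum q values, iTRAQ-style protein
    group quantification with central-tendency normalization, directional
    cross-study meta-analysis, construction of concordant / discordant /
    invariant gene sets, right-tailed Fisher pathway enrichment with
    direction classification, exact binomial intraset-concordance and
    Mann-Whitney interset-discordance statistics, pathway-overlap networks,
    and per-strain standardized hierarchical clustering. A synthetic-data
    generator with planted ground truth makes every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    igraph,
    withr
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite
Config/testthat/edition: 3
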