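Package: rhizonet
Title: Diversity, Biomarker and Co-Occurrence Network Analysis of
    Rhizosphere Microbiomes under Continuous Monocropping
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of amplicon-derived OTU tables from
    continuous-monocropping (monoculture chronosequence) rhizosphere
    studies: per-mille normalization and prevalence filtering, taxonomic
    aggregation, core/pan-OTU partitions, alpha diversity with
    rarefaction, Bray-Curtis and weighted UniFrac distances, PCoA,
    PERMANOVA and RDA, Wilcoxon rank-sum differential-abundance
    screening with Benjamini-Hochberg correction, random-forest
    biomarker selection with cross-validated feature elimination, and
    Spearman co-occurrence network inference with topology summaries and
    Zi-Pi (within-module degree / participation coefficient) node-role
    classification. Includes a synthetic-data generator with known
    ground truth (planted correlation modules, year-informative taxa)
    for end-to-end recovery testing, and a config-driven pipeline
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    mclust,
    permute,
    randomForest,
    stats,
    tools,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
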