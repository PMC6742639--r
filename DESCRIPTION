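Package: mipror
Title: Metaproteomic Analysis of In Vitro Gut Microbiome Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for MetaLab-style metaproteomic
    tables from in vitro gut microbiome culture studies. Assigns peptides a
    taxonomic lineage by lowest common ancestor, derives species biomass
    contributions from summed peptide intensities, rolls protein-group LFQ
    intensities up to COG categories, KEGG pathways and within-pathway enzyme
    fractions, builds per-sample taxon-function coupled profiles and their
    between-sample Pearson stability correlations, runs ordination and
    ANOSIM on Bray-Curtis dissimilarities, selects treatment-responsive
    features with PLS-DA VIP scores, and quantifies in vitro-in vivo
    concordance of drug-induced changes. Ships a ground-truthed synthetic
    metaproteome generator so every stage is testable without raw mass
    spectrometry data.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
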