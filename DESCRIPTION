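Package: gutassembly
Title: Enterotype Discovery and Community Assembly Analysis for Gut
    Microbiome ASV Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidyverse-native tools for the community ecology of gut
    microbiomes profiled by 16S amplicon sequence variants (ASVs):
    table-level preprocessing (low-count filtering, rarefaction, genus
    aggregation), enterotype discovery by partitioning around medoids over
    Bray-Curtis dissimilarity with Calinski-Harabasz model selection,
    alpha/beta diversity contrasts (Shannon, Gini-Simpson, PCoA, ANOSIM,
    rank-sum tests), Spearman co-occurrence networks with topology
    summaries, Sloan neutral community model fitting with 95% occurrence
    bands, phylogenetic (betaMNTD/betaNTI) and taxonomic (Raup-Crick)
    null models with Stegen-style five-process assembly partitioning, and
    Mantel tests against host and environmental factors.  A suite of
    synthetic-data generators with known ground truth (enterotype
    mixtures, Sloan-neutral communities, trait-based habitat filtering on
    a phylogeny) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    cluster,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vegan,
    withr
Suggests:
    optparse,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
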