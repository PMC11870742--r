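Package: antigenome
Title: Phage-Display Autoantigen Discovery with Synthetic Serological Screens
Version: 0.1.0
Authors@R:
    person("Antigenome", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing large-fragment phage-display serological
    screens of the kind used for agnostic autoantigen discovery. The package
    models the full desk-side pipeline: in-silico two-plasmid open reading
    frame screening and library complexity QC, fragment-to-antigen count
    aggregation and normalisation against an unselected input library,
    binary selection calls with replicate and batch QC, a Kruskal-Wallis /
    Benjamini-Hochberg differential-selection cascade with split-set
    reproducibility and subgroup overlap algebra, antigenicity sequence
    scales (Chou-Fasman, Emini, Parker, Kyte-Doolittle, isoelectric point)
    with GSEA-style running-sum enrichment, and L1-penalised logistic
    biomarker models with nested cross-validation, variance-based effect
    decomposition and Shapley attribution. A seeded synthetic-data module
    generates proteomes, fragment libraries, serum reactivity profiles and
    sequencing counts with known ground truth for calibration and power
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
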