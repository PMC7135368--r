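Package: dockbench
Title: Ligand-Enrichment and Structural-Accuracy Benchmarking of Receptor Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for retrospective evaluation of receptor structure models
    used in virtual screening, with an emphasis on G protein-coupled receptor
    homology models. Computes semi-log ROC enrichment metrics (logAUC and the
    adjusted aLogAUC) from ligand/decoy docking score tables, best-score
    ensemble enrichment over sets of binding-site models, chemotype-subset
    enrichment, region-restricted backbone and symmetry-corrected side-chain
    RMSD metrics, region-restricted sequence identity from pairwise
    alignments, geometric classification of docked binding modes, and the
    summary statistics (quantiles, Pearson correlation, improvement
    fractions) used to compare templates. A synthetic-data module generates
    score tables with analytically known enrichment, correlated model
    ensembles, perturbed structures, toy complexes and toy alignments so the
    whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
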