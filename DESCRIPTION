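Package: torcscan
Title: Phylogenetic Profiling of TOR Complex Components Across Eukaryotes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping the presence and absence of TORC1/TORC2
    scaffold components (TOR, LST8, RAPTOR, RICTOR, SIN1) across eukaryotic
    proteomes and for inferring lineage-specific complex losses. Implements
    profile construction from reference alignments, position-specific local
    alignment scoring with bit-score confidence tiers, HMMER domtblout
    ingestion, rule-based complex-presence calls, completeness-aware
    phylogenetic-outlier rescue from short peptide fragments, Dollo
    (irreversible-loss) ancestral reconstruction with independent-loss
    counting on taxonomy trees, and trophic-strategy composition summaries.
    Includes a synthetic-data generator that emulates the full input regime
    (clade-structured taxonomy trees, planted irreversible losses, divergent
    homologs among decoys, degraded proteomes, translated short reads,
    trophic labels) so the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    jsonlite,
    Biostrings,
    generics,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
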