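Package: bcrdev
Title: B-Cell Receptor Repertoire Analysis Across Early Developmental Subsets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing immunoglobulin heavy- and light-chain
    repertoires across early human B-cell developmental subsets (pre-B,
    immature, transitional, naive). Reads AIRR-style annotated rearrangement
    tables, applies CDR3 length and productivity filters, collapses PCR
    duplicates by Levenshtein clustering of CDR3 nucleotide sequences with
    modal-representative selection, computes a CDR3 physicochemical
    descriptor battery (GRAVY, Boman index, molecular weight, isoelectric
    point, aliphatic index, amino-acid class composition and the ten Kidera
    factors), builds per-donor gene and family usage tables with
    ANOVA/Wilcoxon comparisons and mixed-model likelihood-ratio tests, and
    performs per-donor-mean PCA with a label-permutation control and
    Minkowski power-4 hierarchical clustering. A seeded V(D)J recombination
    simulator with PCR duplication and sequencing error provides ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    lme4,
    ape,
    Biostrings,
    withr,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
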