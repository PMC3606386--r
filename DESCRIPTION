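Package: lgthunter
Title: Detection and Characterization of Bacterial-to-Insect Lateral Gene
    Transfers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting and characterizing ancient
    bacterial-to-eukaryote lateral gene transfers (LGT) in genome assemblies.
    Provides a differential-homology genome screen built on a self-contained
    seed-and-extend local alignment engine with Karlin-Altschul E-value
    statistics, reciprocal-best-hit orthology and microsynteny corroboration,
    pairwise dN/dS estimation by Nei-Gojobori counting and maximum likelihood
    under a Goldman-Yang codon model with F3x4 frequencies, neighbor-joining
    phylogenetic placement with bootstrap support, degenerate primer design
    with in-silico PCR for taxonomic surveys, and a synthetic genome simulator
    that generates ground-truthed fixtures for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
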