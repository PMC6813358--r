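Package: ccbreakr
Title: Nucleotide-Resolution Mapping and Analysis of Covalent Protein-Linked DNA Breaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for strand-specific, nucleotide-resolution mapping of
    covalent protein-linked DNA break termini (topoisomerase and Spo11
    cleavage complexes) from paired-end sequencing alignments, together
    with downstream statistics: depth normalisation, spike-in calibration,
    background-noise estimation, Watson-Crick strand-offset analysis,
    cognate/noncognate fractionation by the exact two-sample Poisson test,
    and dyad-centred, signal-weighted DNA sequence composition profiling.
    A synthetic-data module simulates genomes, cleavage events and
    paired-end reads with known ground truth so every pipeline stage can
    be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    optparse,
    withr
Config/testthat/edition: 3
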