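Package: stuckenia
Title: Species Identification in Stuckenia Pondweeds from ITS1-ITS2 Barcodes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A DNA-barcoding pipeline for the aquatic macrophyte genus
    Stuckenia (Potamogetonaceae) based on the nuclear ribosomal ITS1-ITS2
    region. Reads and validates IUPAC FASTA sequences, builds progressive
    multiple alignments with affine gap scoring, computes uncorrected
    p-distance and Tamura-Nei (TN93) distance matrices, reconstructs
    bootstrap-supported neighbor-joining trees, profiles pairwise
    differences into indel and substitution-run events, counts CfoI
    (GCGC) restriction sites in silico, and calls species (S. vaginata,
    S. pectinata types A and B, S. macrocarpa, S. chakassiensis) from a
    context-anchored diagnostic-position key, including detection of
    interspecific hybrids from IUPAC ambiguity additivity and reporting
    of morphology/molecule discordance. A seeded synthetic-haplotype
    generator reproduces the known difference structure of the locus so
    the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
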