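Package: transchrom
Title: Trans-Acting Genetic Control of Chromatin State and 3D Contacts
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse how a trans-acting locus coordinates
    heterochromatin (H3K9me3), active chromatin (H3K27ac, ATAC
    accessibility), gene expression and 3D contact frequency across inbred
    mouse strains, F1 hybrids and reciprocal congenic lines.  Implements
    TMM normalization, confidence filtering and exact negative-binomial
    differential testing for HiChIP PET-count and peak-count matrices,
    QTL-target integration (anchor overlap classification, permutation
    enrichment, strength-effect correlation, allele concordance, factor
    binding enrichment), a discordant-chromatin-state signature contrast,
    spatial region-associated-differential (RAD) binomial enrichment of
    peaks around TSSs, F1 dominance-coefficient estimation, and
    direction-prediction validation in reciprocal congenics.  A seeded
    synthetic-data generator emulates the five-strain multi-omic design
    with negative-binomial counts and ground-truth tables for parameter
    recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR
Config/testthat/edition: 3
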