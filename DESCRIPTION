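Package: autozyg
Title: Autozygosity, Homozygosity Estimators and Effective Population Size
    in Small Pedigreed Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to assess autozygosity in small, shallow-pedigree
    populations typed on SNP arrays. Computes pedigree-based inbreeding
    (Meuwissen-Luo), coancestry, equivalent discrete generations and
    realized effective population size; detects runs of homozygosity (ROH)
    and heterozygosity-rich regions (HRR) with a consecutive-runs scan;
    derives four per-individual genomic homozygosity estimators (F_ROH,
    F_HRR, Li-Horvitz F_LH, Yang F_YAN) relative to a declared base
    population; adjusts them for base-population homozygosity and
    jackknifes over autosomes; computes individual and pairwise increases
    in homozygosity, genomic effective population sizes per cohort and
    their root-mean-squared error against genealogical references; and
    includes a gene-dropping simulator (pedigree plus recombining SNP
    genotypes with tracked identity-by-descent) so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    readxl,
    optparse,
    yaml,
    IRanges
Config/testthat/edition: 3
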