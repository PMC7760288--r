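Package: rohne
Title: Runs of Homozygosity, Genomic Inbreeding and LD-Based Effective
    Population Size from SNP-Array Genotypes
Version: 1.0.0
Authors@R:
    person("rohne", "developers", email = "rohne-dev@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing genetic diversity in small livestock
    populations from medium-density SNP-array genotypes: PLINK PED/MAP
    input and output with marker quality control (call rate, minor allele
    frequency, exact Hardy-Weinberg test, LD pruning), sliding-window
    detection of runs of homozygosity (ROH) with size-class labelling,
    genomic inbreeding coefficients (F_ROH) globally, cumulatively by
    minimum segment length and per chromosome, linkage-disequilibrium
    based estimation of the historical effective population size
    trajectory, and overlap of ROH with candidate selection regions in
    BED format. Includes forward Wright-Fisher simulation and direct
    ROH-implant generators so every stage can be validated against known
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
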