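Package: admixkit
Title: Admixture Analysis of SNP Genotype Data with f-Statistics, Drift
    Trees and Coalescent Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting and quantifying population admixture from
    diploid biallelic SNP genotypes, motivated by the analysis of gene flow
    between European and Chinese pig populations. Reads and merges PLINK-1
    binary and VCF genotype data; performs call-rate and minor-allele
    frequency filtering, windowed linkage-disequilibrium pruning and
    method-of-moments relatedness (pi-hat) exclusion; runs drift-normalised
    principal component analysis; computes f2, f3 and f4 statistics with
    weighted block-jackknife standard errors, three-population admixture
    scans and F4-ratio ancestry-proportion estimates; fits ADMIXTURE-model
    ancestry fractions by expectation maximisation with cross-validation;
    reconstructs population drift trees by neighbour joining with a
    variance-explained statistic; and includes a structured-coalescent
    simulator of multi-population demographies with split events and timed
    directed migration pulses so every stage can be exercised on synthetic
    60K-chip-like data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    pracma,
    vcfR,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
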