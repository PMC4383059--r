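Package: episcan
Title: Exhaustive Bitwise Scanning for SNP Interactions in Case/Control GWAS
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Exhaustive k-way SNP interaction analysis for case/control
    genome-wide association studies. Genotypes are bit-sliced into per-genotype,
    per-phenotype-class binary vectors so that k-way contingency tables reduce
    to bitwise AND and population counts, and each table is scored with
    Pearson's chi-squared test (or any user-registered contingency-table
    statistic). The full set of C(m,k) SNP tuples is enumerated through the
    combinatorial number system (combinadics), partitioned evenly across
    parallel workers, and merged deterministically. Includes a haplotype-mosaic
    genotype simulator with optional embedded penetrance effects, and a
    benchmarking harness for strong-scaling measurement (speedup, efficiency)
    and runtime projection across hardware configurations and interaction
    orders.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    parallel,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
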