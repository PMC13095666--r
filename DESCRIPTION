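Package: scmito
Title: Single-Cell Mitochondrial Heteroplasmy, Copy Number and Bottleneck
    Variance Analysis for CRISPR Perturbation Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing pooled CRISPR perturbation screens in
    heteroplasmic cells profiled by single-cell multiome sequencing.
    Assigns guide RNAs to cell barcodes with MAPQ filtering and a
    read-dominance rule, calls per-cell mitochondrial heteroplasmy by
    combining allele counts across linked SNVs with cis/trans haplotype
    orientation, estimates relative mtDNA copy number from per-cell
    coverage, and decides whether heteroplasmy-variance changes in
    depleted groups are explained by a read-depth sampling bottleneck
    using depth-matched binomial resampling, closed-form variance
    oracles and quantile regression of variance against 1/depth.
    Includes residualized nuclear PCA response statistics, a fully
    seeded synthetic cohort generator with known ground truth, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse
Config/testthat/edition: 3
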