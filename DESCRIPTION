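Package: popscape
Title: Demographic Inference, Effective Sex Ratio, and Linked-Selection
    Scans from Population Genomic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the processes that shape genomic
    landscapes of diversity and divergence in two- and three-population
    systems. Implements a seeded structured-coalescent simulator with
    per-locus migration and effective-size classes, X-linked loci and
    sex-specific depth profiles; VCF site filtering, distance thinning,
    coverage-based sexing and outgroup polarization; unfolded joint site
    frequency spectra with multinomial resampling; a 34-scenario family
    of two-population divergence models (isolation, migration, ancient
    migration and secondary contact, with exponential growth,
    background-selection size classes and heterogeneous migration)
    fitted by Poisson composite likelihood and compared by AIC; a
    hierarchical Bayesian drift model contrasting autosomal and X-linked
    allele frequencies on a three-leaf population tree to estimate
    per-branch effective sex ratios; and windowed summary statistics
    (nucleotide diversity, Tajima's D, Hudson's F_ST, d_XY, genotype r2,
    the ZZ statistic, and derived-allele-frequency profiles) for
    linked-selection scans.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    vcfR,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
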