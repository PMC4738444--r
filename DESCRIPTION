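Package: lambdascan
Title: Type I Error and Genomic Inflation Diagnostics for Product-Term
    SNP-SNP Interaction Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for measuring and interpreting type I error of
    product-term SNP-by-genome interaction scans on quantitative traits.
    Simulates null-hypothesis genotype and phenotype datasets under
    Hardy-Weinberg equilibrium, runs SNP-by-genome interaction scans with
    ordinary least squares or heteroskedasticity-consistent (HC0/HC3)
    sandwich covariance inference and sparse two-locus cell filtering,
    computes the interaction-term genomic inflation factor and Q-Q plot
    coordinates, provides heteroskedasticity and leverage diagnostics, and
    locates an observed inflation factor within a simulation-based
    empirical null distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    sandwich,
    jsonlite
Config/testthat/edition: 3
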