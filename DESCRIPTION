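Package: dyadsem
Title: Maternal and Fetal Genetic Effects from Mother-Offspring Dyads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Structural equation model for partitioning the association
    between a genetic variant and a perinatal phenotype into maternal and
    fetal effects when genotypes are observed in only one generation.
    Latent relative genotypes are tied to the observed genotype by fixed
    Mendelian transmission paths; estimation is by full-information maximum
    likelihood over observation patterns, from raw mother-offspring records,
    covariance summaries, or unconditional association summary statistics.
    Includes Wald, likelihood-ratio and two-degrees-of-freedom tests,
    linear-model comparators, a Mendelian dyad simulator with shared
    confounding, measurement error and missingness designs, and a
    Monte-Carlo harness for bias, power and type-1-error studies.
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
    metafor,
    withr,
    optparse
Config/testthat/edition: 3
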