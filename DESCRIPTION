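Package: markerGxE
Title: Spurious Gene-Environment Interaction from Marker Misclassification
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic and simulation machinery for studying how
    gene-environment dependence combined with imperfect linkage
    disequilibrium between a genotyped marker and an unmeasured causal
    variant induces a spurious marker-by-exposure statistical interaction.
    Provides haplotype-frequency algebra (D', r-squared, Hardy-Weinberg
    diploid expansion), a forward bias calculator on the risk-ratio scale,
    marginalization of causal-variant generalized linear models to the
    marker scale with checks of the no-interaction conditions, an inverse
    sensitivity analysis recovering causal risk ratios compatible with
    observed stratum-specific marker effects, a Wald-test sample-size
    calculator for multiplicative interaction in case-control designs, and
    a seeded individual-level simulator with an in-package IRLS fitter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
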