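Package: localcov
Title: Local Genetic Covariance Tests and the TWAS Null Hypothesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying what transcriptome-wide association studies
    (TWAS) actually test. Implements, on a pruned principal-component basis,
    the method-of-moments estimator of local genetic covariance between gene
    expression and an outcome phenotype, a variance-corrected test of zero
    local genetic covariance, and the conditioned TWAS-style test that treats
    the predicted expression component as fixed. A synthetic genotype and
    trait simulator generates expression/outcome pairs under the null of no
    local genetic covariance (and under the TWAS null), and grid runners
    estimate empirical type-1-error rates, inflation ratios, and the
    standard-error deflation that links the two tests, together with the
    analytic p-value bias it induces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
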