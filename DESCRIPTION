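Package: triadlrt
Title: Likelihood-Based Association Tests for Case-Parent Triads, Dyads
    and Monads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Family-based tests of association between a di-allelic marker
    and a disease, for samples ascertained through an affected child and
    containing any mixture of complete case-parent triads, parent-child
    dyads and affected singleton monads.  Conditional genotype
    probabilities are derived under Hardy-Weinberg equilibrium and random
    mating, a multinomial likelihood in the allele frequency and the
    genotype relative risks is maximized directly (no imputation of
    missing parents), and likelihood ratio tests are provided under
    unrestricted, dominant, recessive, multiplicative and additive
    risk models, together with the transmission disequilibrium test and a
    combined triad-plus-dyad score test.  A multinomial simulation engine
    estimates empirical type I error rates and power.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
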