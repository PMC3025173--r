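Package: famlik
Title: Multinomial Likelihood Models for Maternal, Imprinting and
    Child Genotype Effects in Nuclear Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimation of child genotype, maternal genotype,
    parent-of-origin (imprinting) and maternal-fetal genotype
    interaction effects on disease risk from case/parent trios,
    case/mother duos, other partial nuclear-family structures, and
    optional control samples, by direct maximisation of multinomial
    likelihoods over genotype-combination cell counts.  Includes
    conversions between published penetrance parameterisations,
    mating-type stratification and Hardy-Weinberg nuisance models,
    apparent genotype-relative-risk calculators, a synthetic family
    data generator with rejection sampling under a multiplicative
    penetrance model, and a replicated simulation harness for bias,
    power and type-I-error studies.
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
    yaml
Config/testthat/edition: 3
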