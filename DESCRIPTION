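Package: mutscreen
Title: Quantitative Genetics of Mutation Screens for Life Span
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for large-scale screens of induced mutations
    (e.g. P-element insertion lines in a co-isogenic Drosophila background)
    phenotyped for life span and related fitness traits. Provides
    variance-component ANOVA on replicate-vial means with method-of-moments
    estimation under unbalanced designs, broad-sense mutational heritability
    and cross-sex genetic correlations, confidence-interval and Dunnett
    many-to-one screening against a common control, standardized mutational
    effects and sex-effect classification, half-diallel combining-ability
    (Griffing Method 4, Model 1) analysis of epistasis with GCA/SCA
    estimates, standard errors and ANOVA partitions, Pearson mutational
    correlations for pleiotropy with tests against zero and unity, and a
    seed-reproducible synthetic-data generator so every stage admits
    parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mvtnorm,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    jsonlite
Config/testthat/edition: 3
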