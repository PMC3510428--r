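Package: longsig
Title: Genetic Signatures of Exceptional Longevity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Bayesian case-control analysis of extreme-longevity cohorts:
    per-SNP Dirichlet-multinomial Bayes factors with LD pruning of the
    ranked panel, forward-built nested naive-Bayes classifiers with a
    sensitivity/specificity stopping rule and ensemble prediction,
    per-subject genetic risk profiles with Bayesian model-based clustering
    into genetic signatures, a liability-threshold heritability solver
    driven by disease prevalence and sibling relative risk, and a
    disease-allele burden comparison between cases and controls. Includes
    a synthetic cohort generator (Hardy-Weinberg genotypes, block LD,
    planted class-graded effects) so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pracma,
    yaml
Config/testthat/edition: 3
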