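Package: fragpop
Title: Molecular and Quantitative Genetic Analysis of Fragmented Plant Populations
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dominant-marker (RAPD/AFLP) population
    genetics and common-garden quantitative genetics of fragmented plant
    populations.  Estimates allele frequencies from dominant band phenotypes
    under inbreeding with a Bayesian nonuniform-prior estimator, computes Nei's
    gene diversity, the percentage of polymorphic loci, AFLP-SURV-style F_ST
    with permutation tests, pairwise F_ST and population distinctness, and
    AMOVA on band phenotypes.  Fits nested variance components to common-garden
    family data and derives heritability, evolvability, additive genetic
    standard deviation and Q_ST under a mixed-mating kinship weight, with
    jackknife confidence intervals.  Builds geographic, climatic and
    Mahalanobis trait distance matrices and tests isolation by distance and
    drift versus diversifying selection with sequential permutation
    regressions.  Includes a synthetic-data generator (Balding-Nichols markers,
    nested trait models, climate gradients) so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    igraph,
    geosphere,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
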