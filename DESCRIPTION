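Package: triomr
Title: Within-Family Mendelian Randomization for Parent-Child Trios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating dynastic (genetic nurture) effects of
    parental exposures on child outcomes with mother-father-child trios.
    Provides a seeded trio cohort simulator with Mendelian transmission,
    rank-based assortative mating, and dynastic, direct-genetic and
    pleiotropic phenotype effects; LD clumping and effect-size-weighted
    polygenic index construction from GWAS summary statistics; a
    within-family multivariable two-stage least squares estimator with
    family-clustered standard errors and Sanderson-Windmeijer conditional F
    diagnostics; per-SNP trio-adjusted outcome associations and
    pleiotropy-robust summary-data Mendelian randomization estimators (IVW,
    MR-Egger, weighted median, weighted mode); and a Monte-Carlo bias study
    across assortative-mating strengths.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    sandwich,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
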