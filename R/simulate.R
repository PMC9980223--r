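#' Create a simulation configuration
#'
#' Validated constructor for [SimConfig-class]. The defaults reproduce the
#' restricted generative model used in the assortative-mating bias study: one
#' biallelic SNP at frequency 0.5, parental exposure equal to own genotype
#' plus standard normal noise, child outcome equal to the sum of both parental
#' phenotypes (coefficient 1 each) plus standard normal noise, no direct
#' genetic effect and no pleiotropy.
#'
#' @param nCouples number of mother-father pairs to simulate.
#' @param nSnps number of independent biallelic variants.
#' @param alleleFreqs effect-allele frequency (scalar recycled, or one value
#'   per variant), strictly inside (0, 1).
#' @param assortmentPhi genotype weight \eqn{\phi} in the latent assortment
#'   score, in `[0, 1]`; 0 is random mating, 1 matches spouses on genotype
#'   rank alone.
#' @param dynasticMother,dynasticFather coefficients of the mother's and
#'   father's exposure phenotype in the child-outcome model.
#' @param directEffect per-SNP effect of the child's own dosage on the
#'   outcome.
#' @param pleiotropyMean,pleiotropySd per-SNP pleiotropic effects of child
#'   dosage on the outcome are drawn from
#'   `N(pleiotropyMean, pleiotropySd^2)`; both 0 disables pleiotropy.
#' @param exposureEffect effect of a parent's dosage on their own exposure;
#'   a scalar (recycled across variants) or one value per variant.
#' @param noiseSdExposure,noiseSdOutcome noise SDs (> 0).
#' @param seed integer root seed; stage streams (genotypes, assortment,
#'   transmission, pleiotropy, phenotype noise) are derived from it so runs
#'   are bit-reproducible.
#' @return A validated [SimConfig-class] object.
#' @examples
#' simConfig(nCouples = 100, assortmentPhi = 0.5, seed = 1)
#' @export
simConfig <- function(nCouples, nSnps = 1, alleleFreqs = 0.5,
                      assortmentPhi = 0, dynasticMother = 1,
                      dynasticFather = 1, directEffect = 0,
                      pleiotropyMean = 0, pleiotropySd = 0,
                      exposureEffect = 1, noiseSdExposure = 1,
                      noiseSdOutcome = 1, seed = 1) {
  new("SimConfig",
      nCouples = as.integer(nCouples), nSnps = as.integer(nSnps),
      alleleFreqs = as.numeric(alleleFreqs),
      assortmentPhi = as.numeric(assortmentPhi),
      dynasticMother = as.numeric(dynasticMother),
      dynasticFather = as.numeric(dynasticFather),
      directEffect = as.numeric(directEffect),
      pleiotropyMean = as.numeric(pleiotropyMean),
      pleiotropySd = as.numeric(pleiotropySd),
      exposureEffect = as.numeric(exposureEffect),
      noiseSdExposure = as.numeric(noiseSdExposure),
      noiseSdOutcome = as.numeric(noiseSdOutcome),
      seed = as.integer(seed))
}

.freqs <- function(config) {
  f <- config@alleleFreqs
  if (length(f) == 1L) rep(f, config@nSnps) else f
}

.genotype_matrix <- function(n, freqs, ids) {
  p <- length(freqs)
  g <- matrix(stats::rbinom(n * p, 2L, rep(freqs, each = n)), nrow = n,
              ncol = p)
  storage.mode(g) <- "integer"
  dimnames(g) <- list(NULL, ids)
  g
}

#' Simulate parental genotype pools
#'
#' Draws independent biallelic dosages for `nCouples` mothers and `nCouples`
#' fathers: each dosage is Binomial(2, allele frequency), i.e.
#' Hardy-Weinberg proportions at every locus.
#'
#' @param config a [SimConfig-class].
#' @return list with integer dosage matrices `mother` and `father`
#'   (couples x variants).
#' @export
simulateParentalGenotypes <- function(config) {
  validObject(config)
  n <- config@nCouples
  freqs <- .freqs(config)
  ids <- paste0("snp", seq_len(config@nSnps))
  .with_seed(.stage_seed(config@seed, "parental_genotypes"), {
    list(mother = .genotype_matrix(n, freqs, ids),
         father = .genotype_matrix(n, freqs, ids))
  })
}

#' Pair mothers and fathers by assortative mating
#'
#' Computes a latent assortment score for every individual,
#' \eqn{a = \phi z(g) + (1 - \phi) v}, where \eqn{z(g)} is the standardized
#' mean genotype across variants and \eqn{v} is standard normal noise, then
#' pairs the pools by rank: the mother with the r-th smallest score marries
#' the father with the r-th smallest score. `phi = 0` is random mating;
#' `phi = 1` matches on genotype alone.
#'
#' @param mothers,fathers dosage matrices (couples x variants) with equal row
#'   counts.
#' @param phi genotype weight in `[0, 1]`.
#' @param seed integer seed for the noise draws.
#' @return integer vector `pairing`: `pairing[i]` is the row of `fathers`
#'   married to row `i` of `mothers`; always a permutation of `1:n`.
#' @export
assortCouples <- function(mothers, fathers, phi, seed = 1) {
  if (nrow(mothers) != nrow(fathers))
    stop("mothers and fathers must have equal numbers of rows")
  .assert_scalar_number(phi, "phi", 0, 1)
  n <- nrow(mothers)
  if (n == 0L) return(integer(0))
  .with_seed(.stage_seed(seed, "assortment"), {
    am <- phi * .standardize(rowMeans(mothers)) +
      (1 - phi) * stats::rnorm(n)
    af <- phi * .standardize(rowMeans(fathers)) +
      (1 - phi) * stats::rnorm(n)
    pairing <- integer(n)
    pairing[order(am)] <- order(af)
    pairing
  })
}

#' Transmit genotypes from parents to children
#'
#' At each locus the child receives one allele drawn uniformly from each
#' parent's two alleles, so the transmitted allele count from a parent with
#' dosage `g` is Bernoulli(`g/2`) and
#' `E[child | parents] = (g_m + g_f) / 2`.
#'
#' @param mothers,fathers dosage matrices (couples x variants).
#' @param pairing permutation vector from [assortCouples()]; mother `i` is
#'   paired with father `pairing[i]`.
#' @param seed integer seed.
#' @return integer child dosage matrix aligned to the mothers' rows.
#' @export
transmitGenotypes <- function(mothers, fathers, pairing, seed = 1) {
  n <- nrow(mothers)
  if (length(pairing) != n || (n > 0L && !setequal(pairing, seq_len(n))))
    stop("pairing must be a permutation matching every mother to a father")
  fathers <- fathers[pairing, , drop = FALSE]
  p <- ncol(mothers)
  .with_seed(.stage_seed(seed, "transmission"), {
    child <- matrix(
      stats::rbinom(n * p, 1L, as.numeric(mothers) / 2) +
        stats::rbinom(n * p, 1L, as.numeric(fathers) / 2),
      nrow = n, ncol = p)
    storage.mode(child) <- "integer"
    colnames(child) <- colnames(mothers)
    child
  })
}

#' Generate exposure and outcome phenotypes for a trio cohort
#'
#' Fills a genotyped [TrioCohort-class] with phenotypes under the generative
#' model: each parent's exposure is
#' `x = g \%*\% exposureEffect + N(0, noiseSdExposure^2)` (scalar effects
#' recycled across variants); the child
#' outcome is
#' `y = dynasticMother * x_m + dynasticFather * x_f +
#'  g_child \%*\% (directEffect + alpha) + N(0, noiseSdOutcome^2)` with
#' per-SNP pleiotropic effects `alpha ~ N(pleiotropyMean, pleiotropySd^2)`.
#' Setting `alpha` to zero (the default) reproduces the restricted
#' dynastic-effects-only model.
#'
#' @param cohort a [TrioCohort-class] with dosage assays present.
#' @param config a [SimConfig-class]; noise streams are derived from
#'   `config@seed`.
#' @return the cohort with `exposure_mother`, `exposure_father` and
#'   `outcome_child` columns filled in `colData`.
#' @export
generatePhenotypes <- function(cohort, config) {
  if (!is(cohort, "TrioCohort")) stop("cohort must be a TrioCohort")
  validObject(config)
  gm <- dosageMatrix(cohort, "mother")
  gf <- dosageMatrix(cohort, "father")
  gc <- dosageMatrix(cohort, "child")
  if (!nrow(gm) && config@nCouples > 0L)
    stop("cohort has no genotypes")
  n <- nrow(gm); p <- ncol(gm)
  alpha <- .with_seed(.stage_seed(config@seed, "pleiotropy"),
                      stats::rnorm(p, config@pleiotropyMean,
                                   config@pleiotropySd))
  noise <- .with_seed(.stage_seed(config@seed, "phenotype_noise"), {
    list(xm = stats::rnorm(n, 0, config@noiseSdExposure),
         xf = stats::rnorm(n, 0, config@noiseSdExposure),
         y = stats::rnorm(n, 0, config@noiseSdOutcome))
  })
  w_exp <- rep_len(config@exposureEffect, p)
  xm <- as.numeric(gm %*% w_exp) + noise$xm
  xf <- as.numeric(gf %*% w_exp) + noise$xf
  y <- config@dynasticMother * xm + config@dynasticFather * xf +
    as.numeric(gc %*% (config@directEffect + alpha)) + noise$y
  cd <- SummarizedExperiment::colData(cohort)
  cd$exposure_mother <- xm
  cd$exposure_father <- xf
  cd$outcome_child <- y
  SummarizedExperiment::colData(cohort) <- cd
  md <- S4Vectors::metadata(cohort)
  md$pleiotropy <- alpha
  S4Vectors::metadata(cohort) <- md
  cohort
}

#' Simulate a complete trio cohort
#'
#' Runs the full pipeline: parental genotype pools, assortative pairing,
#' Mendelian transmission, and phenotype generation. The configuration is
#' stored in the cohort's metadata as a provenance record; identical
#' configurations (including seed) give bit-identical cohorts.
#'
#' @param config a [SimConfig-class].
#' @return a [TrioCohort-class] with genotypes and phenotypes.
#' @examples
#' cohort <- simulateTrioCohort(simConfig(nCouples = 200, seed = 7))
#' cohort
#' @export
simulateTrioCohort <- function(config) {
  validObject(config)
  pools <- simulateParentalGenotypes(config)
  pairing <- assortCouples(pools$mother, pools$father, config@assortmentPhi,
                           seed = config@seed)
  child <- transmitGenotypes(pools$mother, pools$father, pairing,
                             seed = config@seed)
  father <- pools$father[pairing, , drop = FALSE]
  p <- config@nSnps
  variants <- data.frame(
    variant_id = paste0("snp", seq_len(p)),
    chromosome = rep(1L, p),
    position = seq_len(p) * 1e6,
    effect_allele = rep("A", p),
    other_allele = rep("G", p),
    eaf = .freqs(config),
    stringsAsFactors = FALSE)
  cohort <- TrioCohort(pools$mother, father, child, variants = variants,
                       config = config)
  generatePhenotypes(cohort, config)
}

#' Check Mendelian legality of a cohort's child genotypes
#'
#' A child dosage is legal when it can arise from one allele of each parent:
#' the transmitted count from a parent with dosage 0 or 2 is fixed (0 or 1),
#' so the child dosage must lie in
#' `[floor(g_m/2) + floor(g_f/2), ceiling(g_m/2) + ceiling(g_f/2)]`.
#'
#' @param cohort a [TrioCohort-class].
#' @return number of illegal child genotypes (0 for any Mendelian cohort).
#' @export
countMendelianViolations <- function(cohort) {
  gm <- dosageMatrix(cohort, "mother")
  gf <- dosageMatrix(cohort, "father")
  gc <- dosageMatrix(cohort, "child")
  lo <- floor(gm / 2) + floor(gf / 2)
  hi <- ceiling(gm / 2) + ceiling(gf / 2)
  sum(gc < lo | gc > hi)
}
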