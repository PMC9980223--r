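#' Simulation configuration for trio cohorts
#'
#' An S4 container for the parameters of the generative model: biallelic
#' genotypes for couples, spousal assortment on a latent genotype-plus-noise
#' score, Mendelian transmission to a child, a parental exposure driven by the
#' parent's own genotype, and a child outcome driven by the parental
#' phenotypes (dynastic effects), optionally the child's own genotype (direct
#' effect) and per-SNP pleiotropy.
#'
#' The defaults reproduce the restricted generative model used for the
#' assortative-mating bias analysis: one biallelic SNP, exposure equal to
#' genotype plus standard normal noise, child outcome equal to the sum of the
#' two parental phenotypes (coefficient 1 on each) plus standard normal noise,
#' no direct genetic effect and no pleiotropy.
#'
#' @slot nCouples number of mother-father pairs.
#' @slot nSnps number of biallelic variants.
#' @slot alleleFreqs effect-allele frequencies, strictly inside (0, 1);
#'   a scalar is recycled across variants.
#' @slot assortmentPhi weight \eqn{\phi \in [0, 1]} of the standardized
#'   genotype in the latent assortment score \eqn{a = \phi z(g) + (1-\phi) v}.
#' @slot dynasticMother,dynasticFather effect of each parent's exposure
#'   phenotype on the child outcome.
#' @slot directEffect per-SNP effect of the child's own dosage on the outcome.
#' @slot pleiotropyMean,pleiotropySd mean and SD of per-SNP pleiotropic
#'   effects of the child genotype on the outcome (both 0 disables pleiotropy).
#' @slot exposureEffect per-SNP effect of a parent's dosage on their exposure.
#' @slot noiseSdExposure,noiseSdOutcome SDs of the exposure and outcome noise.
#' @slot seed root seed; all stage-level streams are derived from it.
#'
#' @seealso [simConfig()], [simulateTrioCohort()]
#' @export
setClass("SimConfig",
  representation(
    nCouples = "integer",
    nSnps = "integer",
    alleleFreqs = "numeric",
    assortmentPhi = "numeric",
    dynasticMother = "numeric",
    dynasticFather = "numeric",
    directEffect = "numeric",
    pleiotropyMean = "numeric",
    pleiotropySd = "numeric",
    exposureEffect = "numeric",
    noiseSdExposure = "numeric",
    noiseSdOutcome = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (length(object@nCouples) != 1L || is.na(object@nCouples) ||
      object@nCouples < 0L)
    msg <- c(msg, "nCouples must be a single non-negative integer")
  if (length(object@nSnps) != 1L || is.na(object@nSnps) || object@nSnps < 1L)
    msg <- c(msg, "nSnps must be a single positive integer")
  f <- object@alleleFreqs
  if (!length(f) %in% c(1L, object@nSnps))
    msg <- c(msg, "alleleFreqs must have length 1 or nSnps")
  if (any(!is.finite(f)) || any(f <= 0) || any(f >= 1))
    msg <- c(msg, "allele frequencies must be strictly inside (0, 1)")
  phi <- object@assortmentPhi
  if (length(phi) != 1L || !is.finite(phi) || phi < 0 || phi > 1)
    msg <- c(msg, "assortmentPhi must be a single value in [0, 1]")
  if (!is.finite(object@pleiotropySd) || object@pleiotropySd < 0)
    msg <- c(msg, "pleiotropySd must be >= 0")
  if (!is.finite(object@noiseSdExposure) || object@noiseSdExposure <= 0)
    msg <- c(msg, "noiseSdExposure must be > 0")
  if (!is.finite(object@noiseSdOutcome) || object@noiseSdOutcome <= 0)
    msg <- c(msg, "noiseSdOutcome must be > 0")
  for (s in c("dynasticMother", "dynasticFather", "directEffect",
              "pleiotropyMean"))
    if (!is.finite(slot(object, s)))
      msg <- c(msg, paste(s, "must be finite"))
  ee <- object@exposureEffect
  if (!length(ee) %in% c(1L, object@nSnps) || any(!is.finite(ee)))
    msg <- c(msg, "exposureEffect must be finite, length 1 or nSnps")
  if (length(msg)) msg else TRUE
})

#' A cohort of genotyped mother-father-child trios
#'
#' `TrioCohort` extends [SummarizedExperiment::SummarizedExperiment] with
#' three aligned dosage assays named `"mother"`, `"father"` and `"child"`
#' (variants in rows, families in columns). Variant metadata (chromosome,
#' position, alleles, effect-allele frequency) live in `rowData`; family-level
#' phenotypes (`exposure_mother`, `exposure_father`, `outcome_child`) and
#' covariates live in `colData`; the generating [simConfig()] (for simulated
#' cohorts) is stored in `metadata(x)$config`.
#'
#' @seealso [TrioCohort()], [simulateTrioCohort()], [dosageMatrix()]
#' @export
setClass("TrioCohort", contains = "SummarizedExperiment")

setValidity("TrioCohort", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  need <- c("mother", "father", "child")
  if (!all(need %in% an))
    msg <- c(msg, "assays 'mother', 'father' and 'child' are required")
  else {
    for (role in need) {
      a <- SummarizedExperiment::assay(object, role)
      if (length(a) && (anyNA(a) || min(a) < 0 || max(a) > 2)) {
        msg <- c(msg, sprintf("dosages in assay '%s' must lie in [0, 2]",
                              role))
      }
    }
  }
  if (!"family_id" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'family_id' column")
  if (length(msg)) msg else TRUE
})

#' Trio regression design
#'
#' Aligned, complete-case columns for the individual-level estimators: a child
#' outcome, two parental exposures, two parental polygenic-index instruments,
#' the child polygenic index used as a conditioning covariate, optional extra
#' covariates and family cluster labels for the sandwich variance.
#'
#' @slot outcome child outcome, one value per family.
#' @slot exposureMother,exposureFather parental exposure phenotypes.
#' @slot pgiMother,pgiFather parental polygenic indices (the instruments).
#' @slot pgiChild child polygenic index (conditioning covariate).
#' @slot covariates numeric matrix of additional covariates (may have 0
#'   columns).
#' @slot cluster factor of family cluster labels.
#'
#' @seealso [trioDesign()], [fitWfMvmr()]
#' @export
setClass("TrioDesign",
  representation(
    outcome = "numeric",
    exposureMother = "numeric",
    exposureFather = "numeric",
    pgiMother = "numeric",
    pgiFather = "numeric",
    pgiChild = "numeric",
    covariates = "matrix",
    cluster = "factor"
  )
)

setValidity("TrioDesign", function(object) {
  n <- length(object@outcome)
  msg <- character()
  lens <- c(
    exposureMother = length(object@exposureMother),
    exposureFather = length(object@exposureFather),
    pgiMother = length(object@pgiMother),
    pgiFather = length(object@pgiFather),
    pgiChild = length(object@pgiChild),
    covariates = nrow(object@covariates),
    cluster = length(object@cluster)
  )
  if (any(lens != n))
    msg <- c(msg, "all design columns must have the same number of rows")
  vals <- c(object@outcome, object@exposureMother, object@exposureFather,
            object@pgiMother, object@pgiFather, object@pgiChild,
            object@covariates)
  if (anyNA(vals) || any(!is.finite(vals)))
    msg <- c(msg, "design contains missing or non-finite values")
  if (anyNA(object@cluster))
    msg <- c(msg, "cluster labels contain NA")
  if (length(msg)) msg else TRUE
})
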