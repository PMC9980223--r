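#' Construct a TrioCohort from dosage matrices
#'
#' Assembles aligned mother/father/child dosage matrices, variant metadata,
#' phenotypes and covariates into a [TrioCohort-class] object. Matrices are
#' supplied in the analysis orientation (families in rows, variants in
#' columns) and stored internally in the `SummarizedExperiment` orientation
#' (variants in rows).
#'
#' @param mother,father,child numeric matrices of allele dosages in `[0, 2]`,
#'   families x variants, with identical dimensions. Row `i` of the three
#'   matrices refers to the same family.
#' @param variants optional data.frame of per-variant metadata (one row per
#'   variant; e.g. `variant_id`, `chromosome`, `position`, `effect_allele`,
#'   `other_allele`, `eaf`). Defaults are generated when omitted.
#' @param phenotypes optional data.frame with columns `exposure_mother`,
#'   `exposure_father` and `outcome_child` (any subset), one row per family.
#' @param covariates optional numeric matrix/data.frame of family-level
#'   covariates.
#' @param familyIds character vector of family identifiers; defaults to
#'   `fam1, fam2, ...` or the rownames of `mother`.
#' @param config optional [SimConfig-class] recorded as provenance.
#'
#' @return A [TrioCohort-class] object.
#' @examples
#' gm <- matrix(c(0, 1, 2, 1), 2, 2)
#' gf <- matrix(c(1, 1, 0, 2), 2, 2)
#' gc <- matrix(c(0, 1, 1, 2), 2, 2)
#' TrioCohort(gm, gf, gc)
#' @export
TrioCohort <- function(mother, father, child, variants = NULL,
                       phenotypes = NULL, covariates = NULL,
                       familyIds = NULL, config = NULL) {
  mother <- as.matrix(mother); father <- as.matrix(father)
  child <- as.matrix(child)
  if (!all(dim(mother) == dim(father)) || !all(dim(mother) == dim(child)))
    stop("mother, father and child dosage matrices must share dimensions")
  n <- nrow(mother); p <- ncol(mother)
  if (is.null(familyIds)) {
    familyIds <- rownames(mother)
    if (is.null(familyIds))
      familyIds <- sprintf("fam%d", seq_len(n))  # length 0 when n = 0
  }
  if (anyDuplicated(familyIds))
    stop("family ids must be unique")
  if (is.null(variants)) {
    vid <- colnames(mother)
    if (is.null(vid)) vid <- paste0("snp", seq_len(p))
    variants <- data.frame(variant_id = vid, chromosome = rep(1L, p),
                           position = seq_len(p) * 1e6,
                           effect_allele = rep("A", p),
                           other_allele = rep("G", p),
                           stringsAsFactors = FALSE)
  }
  if (nrow(variants) != p)
    stop("variants must have one row per dosage column")
  cd <- S4Vectors::DataFrame(family_id = as.character(familyIds))
  if (!is.null(phenotypes)) {
    phenotypes <- as.data.frame(phenotypes)
    if (nrow(phenotypes) != n)
      stop("phenotypes must have one row per family")
    for (nm in colnames(phenotypes)) cd[[nm]] <- phenotypes[[nm]]
  }
  covNames <- character()
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n)
      stop("covariates must have one row per family")
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    covNames <- colnames(covariates)
    for (nm in covNames) cd[[nm]] <- covariates[, nm]
  }
  dimn <- list(variants$variant_id, as.character(familyIds))
  tm <- t(mother); tf <- t(father); tc <- t(child)
  dimnames(tm) <- dimnames(tf) <- dimnames(tc) <- dimn
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(mother = tm, father = tf, child = tc),
    rowData = variants, colData = cd,
    metadata = list(
      config = config,
      covariate_names = covNames,
      package_version = as.character(utils::packageVersion("triomr"))
    )
  )
  new("TrioCohort", se)
}

.role <- function(role) {
  match.arg(role, c("mother", "father", "child"))
}

#' Extract a dosage matrix in analysis orientation
#'
#' @param x a [TrioCohort-class].
#' @param role one of `"mother"`, `"father"`, `"child"`.
#' @param ... unused.
#' @return numeric matrix, families x variants, with family ids as rownames
#'   and variant ids as colnames.
#' @export
setMethod("dosageMatrix", "TrioCohort", function(x, role, ...) {
  t(SummarizedExperiment::assay(x, .role(role)))
})

#' TrioCohort accessors
#'
#' @param x a [TrioCohort-class].
#' @return `familyIds`: character vector; `nFamilies`, `nVariants`: integers;
#'   `variantInfo`, `phenotypes`: data.frames; `covariateMatrix`: numeric
#'   matrix (0 columns when no covariates were recorded); `simParams`: the
#'   generating [SimConfig-class] or `NULL`.
#' @name TrioCohort-accessors
NULL

#' @rdname TrioCohort-accessors
#' @export
setMethod("familyIds", "TrioCohort", function(x)
  as.character(SummarizedExperiment::colData(x)$family_id))

#' @rdname TrioCohort-accessors
#' @export
setMethod("nFamilies", "TrioCohort", function(x) ncol(x))

#' @rdname TrioCohort-accessors
#' @export
setMethod("nVariants", "TrioCohort", function(x) nrow(x))

#' @rdname TrioCohort-accessors
#' @export
setMethod("variantInfo", "TrioCohort", function(x)
  as.data.frame(SummarizedExperiment::rowData(x)))

#' @rdname TrioCohort-accessors
#' @export
setMethod("phenotypes", "TrioCohort", function(x) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  keep <- intersect(c("family_id", "exposure_mother", "exposure_father",
                      "outcome_child"), colnames(cd))
  cd[, keep, drop = FALSE]
})

#' @rdname TrioCohort-accessors
#' @export
setMethod("covariateMatrix", "TrioCohort", function(x) {
  nms <- S4Vectors::metadata(x)$covariate_names
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  if (is.null(nms) || !length(nms))
    return(matrix(numeric(0), nrow = ncol(x), ncol = 0))
  as.matrix(cd[, nms, drop = FALSE])
})

#' @rdname TrioCohort-accessors
#' @export
setMethod("simParams", "TrioCohort", function(x)
  S4Vectors::metadata(x)$config)

#' @describeIn TrioCohort-class compact display.
#' @param object a `TrioCohort`.
#' @export
setMethod("show", "TrioCohort", function(object) {
  cat("TrioCohort:", nFamilies(object), "trios x", nVariants(object),
      "variants\n")
  ph <- setdiff(colnames(SummarizedExperiment::colData(object)), "family_id")
  cat("  phenotypes/covariates:",
      if (length(ph)) paste(ph, collapse = ", ") else "<none>", "\n")
  cfg <- simParams(object)
  if (!is.null(cfg))
    cat(sprintf("  simulated (phi = %.2f, seed = %d)\n",
                cfg@assortmentPhi, cfg@seed))
  invisible(NULL)
})

#' @describeIn SimConfig-class compact display.
#' @param object a `SimConfig`.
#' @export
setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0(
    "SimConfig: %d couples, %d SNP(s), phi = %.2f\n",
    "  dynastic (m, f) = (%.2f, %.2f), direct = %.2f, ",
    "pleiotropy ~ N(%.2f, %.2f^2)\n",
    "  exposure effect = %.2f, noise SDs (x, y) = (%.2f, %.2f), seed = %d\n"),
    object@nCouples, object@nSnps, object@assortmentPhi,
    object@dynasticMother, object@dynasticFather, object@directEffect,
    object@pleiotropyMean, object@pleiotropySd, object@exposureEffect,
    object@noiseSdExposure, object@noiseSdOutcome, object@seed))
  invisible(NULL)
})
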