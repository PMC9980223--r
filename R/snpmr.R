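#' Per-SNP trio-adjusted outcome associations
#'
#' For each variant, fits a linear model of the child outcome on the child,
#' mother and father dosages at that variant plus the cohort covariates, with
#' CR0 family-clustered standard errors, and returns the coefficient on the
#' requested parent's dosage. The mutual adjustment for all three genotypes
#' isolates the parental (dynastic) path from transmitted-allele effects.
#' Variants that are monomorphic in any role are dropped with a warning.
#'
#' @param cohort a [TrioCohort-class] with phenotypes.
#' @param parent `"mother"` or `"father"`.
#' @return data.frame with one row per retained variant: `variant_id`,
#'   `effect_allele`, `other_allele`, `eaf` (child effect-allele frequency),
#'   `beta`, `se`, `n`, `parent`.
#' @export
estimateSnpOutcomeAssociations <- function(cohort,
                                           parent = c("mother", "father")) {
  parent <- match.arg(parent)
  if (nVariants(cohort) < 1L) stop("cohort has no variants")
  ph <- phenotypes(cohort)
  if (!"outcome_child" %in% colnames(ph))
    stop("cohort lacks the child outcome phenotype")
  y <- ph$outcome_child
  gm <- dosageMatrix(cohort, "mother")
  gf <- dosageMatrix(cohort, "father")
  gc_ <- dosageMatrix(cohort, "child")
  covs <- covariateMatrix(cohort)
  vi <- variantInfo(cohort)
  cl <- familyIds(cohort)
  target <- if (parent == "mother") "g_mother" else "g_father"
  rows <- vector("list", ncol(gm))
  dropped <- character()
  for (j in seq_len(ncol(gm))) {
    X <- cbind(`(Intercept)` = 1, g_child = gc_[, j], g_mother = gm[, j],
               g_father = gf[, j])
    if (ncol(covs)) X <- cbind(X, covs)
    if (stats::var(gc_[, j]) == 0 || stats::var(gm[, j]) == 0 ||
        stats::var(gf[, j]) == 0) {
      dropped <- c(dropped, vi$variant_id[j])
      next
    }
    fit <- .ols_cluster(X, y, cl)
    rows[[j]] <- data.frame(
      variant_id = vi$variant_id[j],
      effect_allele = vi$effect_allele[j],
      other_allele = vi$other_allele[j],
      eaf = mean(gc_[, j]) / 2,
      beta = fit$coef[[target]],
      se = sqrt(fit$vcov[target, target]),
      n = fit$n, parent = parent, stringsAsFactors = FALSE)
  }
  if (length(dropped))
    warning("dropped monomorphic variant(s): ",
            paste(dropped, collapse = ", "))
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no polymorphic variants available")
  rownames(out) <- NULL
  out
}

#' Per-SNP exposure associations from a cohort
#'
#' Simple per-variant regression of a parent's exposure on their own dosage
#' (with intercept), the within-cohort analogue of an external exposure GWAS.
#'
#' @param cohort a [TrioCohort-class] with phenotypes.
#' @param parent `"mother"` or `"father"`.
#' @return data.frame with `variant_id`, `effect_allele`, `other_allele`,
#'   `eaf`, `beta`, `se`, `n`.
#' @export
estimateSnpExposureAssociations <- function(cohort,
                                            parent = c("mother", "father")) {
  parent <- match.arg(parent)
  ph <- phenotypes(cohort)
  xcol <- paste0("exposure_", parent)
  if (!xcol %in% colnames(ph))
    stop("cohort lacks phenotype column ", xcol)
  x <- ph[[xcol]]
  g <- dosageMatrix(cohort, parent)
  vi <- variantInfo(cohort)
  cl <- familyIds(cohort)
  rows <- lapply(seq_len(ncol(g)), function(j) {
    if (stats::var(g[, j]) == 0) return(NULL)
    X <- cbind(`(Intercept)` = 1, g = g[, j])
    fit <- .ols_cluster(X, x, cl)
    data.frame(variant_id = vi$variant_id[j],
               effect_allele = vi$effect_allele[j],
               other_allele = vi$other_allele[j],
               eaf = mean(g[, j]) / 2,
               beta = fit$coef[["g"]], se = sqrt(fit$vcov["g", "g"]),
               n = fit$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no polymorphic variants available")
  rownames(out) <- NULL
  out
}

.complement <- function(a) {
  chartr("ACGTacgt", "TGCAtgca", a)
}

.is_palindromic <- function(a1, a2) .complement(a1) == a2

#' Harmonize exposure and outcome associations
#'
#' Aligns outcome associations to the exposure panel's effect allele before
#' summary-data MR. When the effect/other alleles are swapped (directly or on
#' the opposite strand) the outcome beta is negated; strand-ambiguous
#' palindromic variants (A/T, C/G) with effect-allele frequency inside
#' `freq_window` are dropped; allele pairs that cannot be reconciled are
#' dropped with a warning.
#'
#' @param exposure data.frame with `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se` and optionally `eaf` (e.g. from
#'   [readGwasSummary()] with `weight` renamed, or
#'   [estimateSnpExposureAssociations()]; a `weight` column is accepted as
#'   `beta`).
#' @param outcome data.frame in the dialect of
#'   [estimateSnpOutcomeAssociations()].
#' @param freq_window ambiguity window for palindromic variants (default
#'   `c(0.42, 0.58)`).
#' @return data.frame (`SnpAssociationSet`) with harmonized
#'   `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome`,
#'   `effect_allele`, `other_allele`, `flipped`; counts of flipped and
#'   dropped variants in attributes `n_flipped`, `n_dropped_palindromic`,
#'   `n_dropped_mismatch`.
#' @export
harmonize <- function(exposure, outcome, freq_window = c(0.42, 0.58)) {
  exposure <- as.data.frame(exposure)
  if (!"beta" %in% colnames(exposure) && "weight" %in% colnames(exposure))
    exposure$beta <- exposure$weight
  for (nm in c("variant_id", "effect_allele", "other_allele", "beta", "se"))
    if (!nm %in% colnames(exposure))
      stop("exposure associations lack column '", nm, "'")
  outcome <- as.data.frame(outcome)
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  if (!length(shared)) stop("no shared variant ids to harmonize")
  ex <- exposure[match(shared, exposure$variant_id), ]
  ou <- outcome[match(shared, outcome$variant_id), ]
  ea_x <- toupper(ex$effect_allele); oa_x <- toupper(ex$other_allele)
  ea_y <- toupper(ou$effect_allele); oa_y <- toupper(ou$other_allele)
  same <- ea_x == ea_y & oa_x == oa_y
  swapped <- ea_x == oa_y & oa_x == ea_y
  flipstrand <- .complement(ea_x) == ea_y & .complement(oa_x) == oa_y
  swapstrand <- .complement(ea_x) == oa_y & .complement(oa_x) == ea_y
  palindromic <- .is_palindromic(ea_x, oa_x)
  freq <- if ("eaf" %in% colnames(ex)) ex$eaf else ou$eaf
  ambiguous <- palindromic & !is.na(freq) & freq > freq_window[1] &
    freq < freq_window[2]
  keep_same <- (same | (flipstrand & !palindromic)) & !ambiguous
  keep_flip <- (swapped | (swapstrand & !palindromic)) & !ambiguous & !same
  mismatch <- !(same | swapped | flipstrand | swapstrand)
  if (any(mismatch))
    warning("dropped variant(s) with irreconcilable alleles: ",
            paste(shared[mismatch], collapse = ", "))
  keep <- (keep_same | keep_flip) & !mismatch
  sgn <- ifelse(keep_flip, -1, 1)
  out <- data.frame(
    variant_id = shared[keep],
    effect_allele = ea_x[keep], other_allele = oa_x[keep],
    beta_exposure = ex$beta[keep], se_exposure = ex$se[keep],
    beta_outcome = (sgn * ou$beta)[keep], se_outcome = ou$se[keep],
    eaf = if (is.null(freq)) NA_real_ else freq[keep],
    flipped = keep_flip[keep], stringsAsFactors = FALSE)
  attr(out, "n_flipped") <- sum(keep_flip & keep)
  attr(out, "n_dropped_palindromic") <- sum(ambiguous & !mismatch)
  attr(out, "n_dropped_mismatch") <- sum(mismatch)
  out
}

.check_assoc <- function(assoc, min_snps, estimator) {
  assoc <- as.data.frame(assoc)
  need <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  miss <- setdiff(need, colnames(assoc))
  if (length(miss))
    stop("association set lacks column(s): ", paste(miss, collapse = ", "))
  if (any(assoc$se_exposure <= 0) || any(assoc$se_outcome <= 0))
    stop("standard errors must be positive")
  if (nrow(assoc) < min_snps)
    stop(estimator, " requires at least ", min_snps, " SNPs (got ",
         nrow(assoc), "); use mrWaldRatio() for a single instrument")
  assoc
}

.mr_row <- function(estimator, estimate, se, q = NA_real_, q_df = NA_real_,
                    n_snps, intercept = NA_real_, intercept_se = NA_real_,
                    intercept_p = NA_real_) {
  ci <- .ci(estimate, se)
  data.frame(estimator = estimator, estimate = estimate, se = se,
             ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
             egger_intercept = intercept, egger_intercept_se = intercept_se,
             egger_intercept_p = intercept_p, q_stat = q, q_df = q_df,
             n_snps = n_snps, stringsAsFactors = FALSE)
}

#' Wald ratio for a single instrument
#'
#' `beta_outcome / beta_exposure`, with first-order delta-method SE
#' `se_outcome / |beta_exposure|`. Every summary estimator reduces to this
#' for one valid instrument.
#'
#' @param assoc one-row harmonized association set.
#' @return one-row summary-MR result data.frame.
#' @export
mrWaldRatio <- function(assoc) {
  assoc <- .check_assoc(assoc, 1L, "mrWaldRatio")
  if (nrow(assoc) != 1L) stop("mrWaldRatio takes exactly one SNP")
  est <- assoc$beta_outcome / assoc$beta_exposure
  se <- assoc$se_outcome / abs(assoc$beta_exposure)
  .mr_row("wald_ratio", est, se, n_snps = 1L)
}

#' Inverse-variance-weighted estimator
#'
#' Zero-intercept regression of outcome betas on exposure betas weighted by
#' `1/se_outcome^2`, i.e.
#' `sum(w b_x b_y) / sum(w b_x^2)`. The SE uses multiplicative random
#' effects: the weighted residual SD scales the fixed-effect SE but is
#' floored at 1 (never shrinks below fixed effects). Cochran's Q and its
#' degrees of freedom are reported.
#'
#' @param assoc harmonized association set with >= 2 SNPs.
#' @return one-row summary-MR result data.frame (estimator `"ivw"`).
#' @export
mrIvw <- function(assoc) {
  assoc <- .check_assoc(assoc, 2L, "mrIvw")
  w <- 1 / assoc$se_outcome^2
  fit <- stats::lm(beta_outcome ~ 0 + beta_exposure, data = assoc,
                   weights = w)
  est <- coef(fit)[["beta_exposure"]]
  n <- nrow(assoc)
  q <- sum(w * (assoc$beta_outcome - est * assoc$beta_exposure)^2)
  phi_scale <- max(1, sqrt(q / (n - 1)))
  se_fixed <- summary(fit)$coefficients["beta_exposure", "Std. Error"] /
    summary(fit)$sigma
  .mr_row("ivw", est, se_fixed * phi_scale, q = q, q_df = n - 1L, n_snps = n)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome betas on exposure betas with a free
#' intercept, exposure betas oriented non-negative (outcome betas reoriented
#' in tandem). The slope is the causal estimate under the InSIDE assumption;
#' the intercept estimates directional pleiotropy and carries its own t-test
#' (df `n - 2`). Multiplicative random-effects scaling as in [mrIvw()].
#'
#' @param assoc harmonized association set with >= 3 SNPs.
#' @return one-row summary-MR result data.frame (estimator `"egger"`).
#' @export
mrEgger <- function(assoc) {
  assoc <- .check_assoc(assoc, 3L, "mrEgger")
  s <- ifelse(assoc$beta_exposure < 0, -1, 1)
  bx <- assoc$beta_exposure * s
  by <- assoc$beta_outcome * s
  w <- 1 / assoc$se_outcome^2
  fit <- stats::lm(by ~ bx, weights = w)
  n <- nrow(assoc)
  cf <- summary(fit)$coefficients
  sigma <- summary(fit)$sigma
  q <- sum(w * residuals(fit)^2)
  phi_scale <- max(1, sqrt(q / (n - 2)))
  slope <- cf["bx", "Estimate"]
  slope_se <- cf["bx", "Std. Error"] / sigma * phi_scale
  int <- cf["(Intercept)", "Estimate"]
  int_se <- cf["(Intercept)", "Std. Error"] / sigma * phi_scale
  int_p <- 2 * stats::pt(abs(int / int_se), df = n - 2, lower.tail = FALSE)
  .mr_row("egger", slope, slope_se, q = q, q_df = n - 2L, n_snps = n,
          intercept = int, intercept_se = int_se, intercept_p = int_p)
}

# weighted interpolated 50th percentile of ordered ratios
.weighted_median_point <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  p <- cumsum(w) - w / 2
  if (p[1] >= 0.5) return(r[1])
  if (p[length(p)] <= 0.5) return(r[length(r)])
  hi <- which(p >= 0.5)[1]
  lo <- hi - 1L
  r[lo] + (r[hi] - r[lo]) * (0.5 - p[lo]) / (p[hi] - p[lo])
}

.boot_se <- function(assoc, point_fun, n_boot, seed) {
  ests <- .with_seed(.stage_seed(seed, "mr_bootstrap"), {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(nrow(assoc), assoc$beta_exposure,
                         assoc$se_exposure)
      by <- stats::rnorm(nrow(assoc), assoc$beta_outcome, assoc$se_outcome)
      point_fun(by / bx, bx)
    }, numeric(1))
  })
  stats::sd(ests)
}

#' Weighted median estimator
#'
#' Interpolated weighted 50th percentile of the per-SNP Wald ratios, with
#' weights proportional to the inverse first-order variance of each ratio
#' (`bx^2 / se_y^2`). Consistent when at least half of the weight comes from
#' valid instruments. SE by seeded parametric bootstrap, resampling exposure
#' and outcome betas from their normal sampling distributions.
#'
#' @param assoc harmonized association set with >= 3 SNPs.
#' @param n_boot bootstrap replicates (default 1000; fewer than 100 warns,
#'   fewer than 1 is an error).
#' @param seed bootstrap seed.
#' @return one-row summary-MR result data.frame (estimator
#'   `"weighted_median"`).
#' @export
mrWeightedMedian <- function(assoc, n_boot = 1000, seed = 1) {
  assoc <- .check_assoc(assoc, 3L, "mrWeightedMedian")
  if (n_boot < 1) stop("n_boot must be at least 1")
  if (n_boot < 100) warning("n_boot < 100 gives an unstable bootstrap SE")
  ratio_w <- function(bx) bx^2 / assoc$se_outcome^2
  est <- .weighted_median_point(assoc$beta_outcome / assoc$beta_exposure,
                                ratio_w(assoc$beta_exposure))
  se <- .boot_se(assoc, function(r, bx)
    .weighted_median_point(r, ratio_w(bx)), n_boot, seed)
  .mr_row("weighted_median", est, se, n_snps = nrow(assoc))
}

.weighted_mad <- function(x, w) {
  m <- .weighted_median_point(x, w)
  1.4826 * .weighted_median_point(abs(x - m), w)
}

.mode_point <- function(ratios, weights, h) {
  grid <- seq(min(ratios) - 3 * h, max(ratios) + 3 * h, length.out = 512)
  dens <- vapply(grid, function(g)
    sum(weights * stats::dnorm((g - ratios) / h)), numeric(1))
  grid[which.max(dens)]
}

#' Weighted mode estimator
#'
#' Mode of the weight-scaled Gaussian kernel density of the per-SNP Wald
#' ratios, consistent when the largest group of instruments shares the true
#' ratio (plurality-valid assumption). The bandwidth is
#' `bandwidth_factor` times a weighted-MAD default
#' (`0.9 * 1.4826 * weightedMAD * n^(-1/5)`); all-identical ratios return
#' that ratio for any bandwidth. SE by seeded parametric bootstrap.
#'
#' @param assoc harmonized association set with >= 3 SNPs.
#' @param bandwidth_factor multiplier on the default bandwidth (default 1;
#'   a zero bandwidth is an error).
#' @param n_boot,seed bootstrap control as in [mrWeightedMedian()].
#' @return one-row summary-MR result data.frame (estimator
#'   `"weighted_mode"`).
#' @export
mrWeightedMode <- function(assoc, bandwidth_factor = 1, n_boot = 1000,
                           seed = 1) {
  assoc <- .check_assoc(assoc, 3L, "mrWeightedMode")
  if (!is.finite(bandwidth_factor) || bandwidth_factor <= 0)
    stop("bandwidth is zero; bandwidth_factor must be positive")
  if (n_boot < 1) stop("n_boot must be at least 1")
  if (n_boot < 100) warning("n_boot < 100 gives an unstable bootstrap SE")
  ratios <- assoc$beta_outcome / assoc$beta_exposure
  weights <- assoc$beta_exposure^2 / assoc$se_outcome^2
  n <- length(ratios)
  point <- function(r, w) {
    s <- .weighted_mad(r, w)
    if (s == 0) return(.weighted_median_point(r, w))
    h <- bandwidth_factor * 0.9 * s * n^(-1 / 5)
    if (h <= 0) stop("bandwidth is zero; increase bandwidth_factor")
    .mode_point(r, w / sum(w), h)
  }
  est <- point(ratios, weights)
  se <- .boot_se(assoc, function(r, bx)
    point(r, bx^2 / assoc$se_outcome^2), n_boot, seed)
  .mr_row("weighted_mode", est, se, n_snps = nrow(assoc))
}

#' Run all summary-data MR estimators
#'
#' Applies IVW, MR-Egger, weighted median and weighted mode to the same
#' harmonized association set; with a single SNP, returns the Wald ratio.
#'
#' @param assoc harmonized association set.
#' @param n_boot,seed bootstrap control for median and mode.
#' @param bandwidth_factor mode bandwidth multiplier.
#' @return data.frame with one row per estimator.
#' @export
mrSummary <- function(assoc, n_boot = 1000, seed = 1, bandwidth_factor = 1) {
  assoc <- .check_assoc(assoc, 1L, "mrSummary")
  if (nrow(assoc) == 1L) return(mrWaldRatio(assoc))
  out <- mrIvw(assoc)
  if (nrow(assoc) >= 3L) {
    out <- rbind(out, mrEgger(assoc),
                 mrWeightedMedian(assoc, n_boot = n_boot, seed = seed),
                 mrWeightedMode(assoc, bandwidth_factor = bandwidth_factor,
                                n_boot = n_boot, seed = seed))
  }
  out
}
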