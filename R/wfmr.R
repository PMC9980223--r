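#' Assemble a trio regression design
#'
#' Low-level constructor for [TrioDesign-class]. Rows containing any missing
#' value are rejected (dropped with a warning): the estimators are
#' complete-case and never impute.
#'
#' @param outcome child outcome.
#' @param exposureMother,exposureFather parental exposures.
#' @param pgiMother,pgiFather parental polygenic indices (instruments).
#' @param pgiChild child polygenic index (conditioning covariate).
#' @param covariates optional numeric matrix/data.frame of extra covariates.
#' @param cluster family cluster labels; defaults to one cluster per row
#'   (each trio its own family).
#' @return a [TrioDesign-class].
#' @export
trioDesign <- function(outcome, exposureMother, exposureFather, pgiMother,
                       pgiFather, pgiChild, covariates = NULL,
                       cluster = NULL) {
  n <- length(outcome)
  if (is.null(covariates))
    covariates <- matrix(numeric(0), nrow = n, ncol = 0)
  covariates <- as.matrix(covariates)
  if (ncol(covariates) && is.null(colnames(covariates)))
    colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
  if (is.null(cluster)) cluster <- seq_len(n)
  cluster <- as.factor(cluster)
  df <- cbind(outcome, exposureMother, exposureFather, pgiMother, pgiFather,
              pgiChild, covariates)
  ok <- stats::complete.cases(df) & apply(is.finite(df), 1L, all) &
    !is.na(cluster)
  if (!all(ok)) {
    warning(sum(!ok), " incomplete row(s) rejected from the trio design")
  }
  new("TrioDesign",
      outcome = as.numeric(outcome[ok]),
      exposureMother = as.numeric(exposureMother[ok]),
      exposureFather = as.numeric(exposureFather[ok]),
      pgiMother = as.numeric(pgiMother[ok]),
      pgiFather = as.numeric(pgiFather[ok]),
      pgiChild = as.numeric(pgiChild[ok]),
      covariates = covariates[ok, , drop = FALSE],
      cluster = droplevels(cluster[ok]))
}

#' Build a trio design from a cohort
#'
#' Convenience wrapper: computes role-standardized polygenic indices with
#' [cohortPgis()] and assembles the [TrioDesign-class] from the cohort's
#' phenotypes, covariates, and family ids (one cluster per family).
#'
#' @param cohort a [TrioCohort-class] with phenotypes present.
#' @param panel optional [variantPanel()] passed to [cohortPgis()].
#' @return a [TrioDesign-class].
#' @export
cohortDesign <- function(cohort, panel = NULL) {
  ph <- phenotypes(cohort)
  need <- c("exposure_mother", "exposure_father", "outcome_child")
  miss <- setdiff(need, colnames(ph))
  if (length(miss))
    stop("cohort lacks phenotype column(s): ", paste(miss, collapse = ", "))
  pgis <- cohortPgis(cohort, panel)
  covs <- covariateMatrix(cohort)
  trioDesign(outcome = ph$outcome_child,
             exposureMother = ph$exposure_mother,
             exposureFather = ph$exposure_father,
             pgiMother = pgis$pgi_mother, pgiFather = pgis$pgi_father,
             pgiChild = pgis$pgi_child,
             covariates = if (ncol(covs)) covs else NULL,
             cluster = familyIds(cohort))
}

#' @describeIn TrioDesign-class compact display.
#' @param object a `TrioDesign`.
#' @export
setMethod("show", "TrioDesign", function(object) {
  cat("TrioDesign:", length(object@outcome), "trios,",
      ncol(object@covariates), "extra covariate(s),",
      nlevels(object@cluster), "clusters\n")
  invisible(NULL)
})

.design_n <- function(design) length(design@outcome)

.iv_row <- function(exposure, estimate, se, f = NA_real_, r2 = NA_real_,
                    n, estimator) {
  ci <- .ci(estimate, se)
  data.frame(exposure = exposure, estimate = estimate, se = se,
             ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
             conditional_F = f, partial_r2 = r2, n = n,
             estimator = estimator, stringsAsFactors = FALSE)
}

# one lm with cluster-robust vcov; returns .iv_row(s) for `targets`
.ols_fit_rows <- function(design, columns, targets, tag) {
  df <- data.frame(y = design@outcome, columns, design@covariates,
                   check.names = FALSE)
  fit <- stats::lm(y ~ ., data = df)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  V <- sandwich::vcovCL(fit, cluster = design@cluster, type = "HC0")
  out <- do.call(rbind, lapply(names(targets), function(par) {
    tg <- targets[[par]]
    .iv_row(par, coef(fit)[[tg]], sqrt(V[tg, tg]), n = .design_n(design),
            estimator = tag)
  }))
  rownames(out) <- NULL
  out
}

#' Phenotypic regression of the child outcome on parental exposures
#'
#' By default a single mutually adjusted linear regression of the child
#' outcome on both parental exposures and covariates, with CR0
#' cluster-robust (by family) standard errors — the phenotypic estimator
#' used for real-data analyses. With `perParent = TRUE`, each parent's
#' exposure is regressed separately with the other parent omitted: the naive
#' comparator whose estimate absorbs the correlated spouse's effect under
#' assortative mating, and the "ols" arm of the bias study.
#'
#' @param design a [TrioDesign-class].
#' @param perParent fit one regression per parent omitting the other
#'   parent's exposure (default `FALSE`, mutually adjusted).
#' @return data.frame with one row per parent: estimate, cluster-robust SE,
#'   95% CI, n, and estimator tag `"ols"`.
#' @export
fitPhenotypicOls <- function(design, perParent = FALSE) {
  xm <- design@exposureMother
  xf <- design@exposureFather
  if (!perParent) {
    return(.ols_fit_rows(design,
                         data.frame(exposureMother = xm, exposureFather = xf),
                         list(mother = "exposureMother",
                              father = "exposureFather"), "ols"))
  }
  rbind(
    .ols_fit_rows(design, data.frame(exposureMother = xm),
                  list(mother = "exposureMother"), "ols"),
    .ols_fit_rows(design, data.frame(exposureFather = xf),
                  list(father = "exposureFather"), "ols"))
}

# Two-stage least squares with exogenous columns W (incl. intercept),
# endogenous exposures X, excluded instruments Zexcl, cluster-robust CR0
# covariance computed from second-stage residuals at the *observed*
# exposures.
.tsls <- function(y, X, Zexcl, W, cluster) {
  Zfull <- cbind(W, Zexcl)
  Xfull <- cbind(W, X)
  qz <- qr(Zfull)
  # instrument-rank check after partialling out the exogenous block
  Mx <- qr.resid(qr(W), Zexcl)
  if (qr(Mx)$rank < ncol(X))
    stop("under-identified: fewer effective instruments (",
         qr(Mx)$rank, ") than exposures (", ncol(X), ")")
  Xhat <- qr.fitted(qz, Xfull)
  colnames(Xhat) <- colnames(Xfull)
  qx <- qr(Xhat)
  if (qx$rank < ncol(Xhat)) {
    bad <- colnames(Xhat)[qx$pivot[seq(qx$rank + 1L, ncol(Xhat))]]
    stop("projected design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qx, y)
  e <- as.numeric(y - Xfull %*% beta)
  A <- chol2inv(qr.R(qx))
  cl <- as.factor(cluster)
  G <- nlevels(cl)
  meat <- crossprod(rowsum(Xhat * e, cl))
  V <- A %*% meat %*% A * G / max(G - 1, 1)
  dimnames(V) <- list(colnames(Xfull), colnames(Xfull))
  names(beta) <- colnames(Xfull)
  list(coef = beta, vcov = V, residuals = e, n = length(y))
}

.wf_design_parts <- function(design, include_child_pgi) {
  W <- cbind(`(Intercept)` = rep(1, .design_n(design)))
  if (include_child_pgi) W <- cbind(W, pgiChild = design@pgiChild)
  if (ncol(design@covariates)) W <- cbind(W, design@covariates)
  list(
    y = design@outcome,
    X = cbind(exposureMother = design@exposureMother,
              exposureFather = design@exposureFather),
    Z = cbind(pgiMother = design@pgiMother, pgiFather = design@pgiFather),
    W = W)
}

.fit_iv <- function(design, include_child_pgi, tag) {
  parts <- .wf_design_parts(design, include_child_pgi)
  fit <- .tsls(parts$y, parts$X, parts$Z, parts$W, design@cluster)
  n <- .design_n(design)
  rows <- lapply(c(mother = "exposureMother", father = "exposureFather"),
                 function(nm) {
    par <- if (nm == "exposureMother") "mother" else "father"
    diag_ <- conditionalFStatistic(design, par,
                                   includeChildPgi = include_child_pgi)
    .iv_row(par, fit$coef[[nm]], sqrt(fit$vcov[nm, nm]),
            f = diag_$conditional_F, r2 = diag_$partial_r2, n = n,
            estimator = tag)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Within-family multivariable Mendelian randomization (trio 2SLS)
#'
#' Two-stage least squares with the mother's and father's polygenic indices
#' instrumenting their exposures, and the child's polygenic index included as
#' an exogenous covariate in both stages. Conditioning on the child's index
#' blocks the transmitted-allele path, so the parental instruments are valid
#' even under direct genetic effects and assortative mating. Standard errors
#' are CR0 cluster-robust by family, computed from second-stage residuals at
#' the observed (not fitted) exposures, with finite-sample factor
#' `G/(G-1)`.
#'
#' @param design a [TrioDesign-class].
#' @return data.frame with one row per parent: estimate, SE, 95% CI,
#'   Sanderson-Windmeijer conditional F, partial r-squared of the parent's
#'   instrument, n, and estimator tag `"wf_mr"`.
#' @seealso [fitStandardMr()], [conditionalFStatistic()]
#' @export
fitWfMvmr <- function(design) .fit_iv(design, TRUE, "wf_mr")

#' Conventional (non-within-family) Mendelian randomization comparator
#'
#' The standard MR analysis of each parent's exposure taken on its own: the
#' parent's polygenic index instruments their exposure in a just-identified
#' 2SLS, with neither the child's polygenic index nor the other parent in
#' the model (covariates are retained). Under assortative mating the
#' instrument correlates with the omitted spouse's exposure, and under
#' direct genetic effects with the transmitted-allele path, so this
#' estimator is biased in exactly the situations the within-family design
#' repairs. Reported diagnostics are the ordinary excluded-instrument F and
#' the partial r-squared of the parent's instrument given the covariates.
#'
#' @param design a [TrioDesign-class].
#' @return data.frame as in [fitWfMvmr()], estimator tag `"standard_mr"`.
#' @export
fitStandardMr <- function(design) {
  n <- .design_n(design)
  W <- cbind(`(Intercept)` = rep(1, n))
  if (ncol(design@covariates)) W <- cbind(W, design@covariates)
  rows <- lapply(c("mother", "father"), function(par) {
    x <- if (par == "mother") design@exposureMother else
      design@exposureFather
    z <- if (par == "mother") design@pgiMother else design@pgiFather
    X <- cbind(exposure = x)
    Z <- cbind(pgi = z)
    fit <- .tsls(design@outcome, X, Z, W, design@cluster)
    # ordinary first-stage F and partial r2 of the single instrument
    q0 <- qr(W); q1 <- qr(cbind(W, Z))
    rss0 <- sum(qr.resid(q0, x)^2)
    rss1 <- sum(qr.resid(q1, x)^2)
    f <- if (rss1 <= .Machine$double.eps * max(1, rss0)) 1e15
         else (rss0 - rss1) / (rss1 / (n - q1$rank))
    r2 <- if (rss0 <= 0) 0 else max(0, min(1, (rss0 - rss1) / rss0))
    .iv_row(par, fit$coef[["exposure"]],
            sqrt(fit$vcov["exposure", "exposure"]), f = min(f, 1e15),
            r2 = r2, n = n, estimator = "standard_mr")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sanderson-Windmeijer conditional F and partial r-squared
#'
#' Instrument strength for one exposure in the two-exposure system, after
#' accounting for the other exposure: (i) estimate the target exposure on the
#' other exposure (plus exogenous covariates) by 2SLS using both instruments;
#' (ii) regress the residualized exposure on the covariates and both
#' instruments; (iii) the conditional F is the instrument Wald statistic with
#' numerator degrees of freedom `k_Z - k_X + 1`. With a single exposure this
#' reduces to the ordinary excluded-instrument F. Also returns the partial
#' r-squared of the parent's own instrument given the child index, the other
#' parent's instrument and covariates.
#'
#' @param design a [TrioDesign-class].
#' @param exposure `"mother"` or `"father"`.
#' @param includeChildPgi include the child polygenic index among the
#'   exogenous covariates (as in the within-family estimator).
#' @param singleExposure treat the system as having only the requested
#'   exposure (ordinary first-stage F on both instruments); used for the
#'   single-exposure reduction.
#' @return list with `conditional_F`, `partial_r2`, `df1`, `df2`. A noiseless
#'   first stage reports a capped F of `1e15`.
#' @export
conditionalFStatistic <- function(design, exposure = c("mother", "father"),
                                  includeChildPgi = TRUE,
                                  singleExposure = FALSE) {
  exposure <- match.arg(exposure)
  parts <- .wf_design_parts(design, includeChildPgi)
  x1 <- if (exposure == "mother") parts$X[, 1L] else parts$X[, 2L]
  x2 <- if (exposure == "mother") parts$X[, 2L, drop = FALSE]
        else parts$X[, 1L, drop = FALSE]
  W <- parts$W
  Z <- parts$Z
  n <- length(x1)
  kz <- ncol(Z)
  if (singleExposure) {
    resid1 <- x1
    kx <- 1L
  } else {
    kx <- 2L
    sw <- .tsls(x1, x2, Z, W, design@cluster)
    delta <- sw$coef[colnames(x2)]
    resid1 <- x1 - as.numeric(x2 %*% delta)
  }
  # classical F of the excluded instruments in the auxiliary regression
  q0 <- qr(W)
  q1 <- qr(cbind(W, Z))
  rss0 <- sum(qr.resid(q0, resid1)^2)
  rss1 <- sum(qr.resid(q1, resid1)^2)
  df1 <- kz - kx + 1L
  df2 <- n - q1$rank
  f <- if (rss1 <= .Machine$double.eps * max(1, rss0)) 1e15
       else ((rss0 - rss1) / df1) / (rss1 / df2)
  # partial r2 of the parent's own instrument given everything else
  own <- if (exposure == "mother") Z[, "pgiMother", drop = FALSE]
         else Z[, "pgiFather", drop = FALSE]
  other <- if (exposure == "mother") Z[, "pgiFather", drop = FALSE]
           else Z[, "pgiMother", drop = FALSE]
  base <- cbind(W, other)
  rss_b <- sum(qr.resid(qr(base), x1)^2)
  rss_f <- sum(qr.resid(qr(cbind(base, own)), x1)^2)
  r2 <- if (rss_b <= 0) 0 else max(0, min(1, (rss_b - rss_f) / rss_b))
  list(conditional_F = min(f, 1e15), partial_r2 = r2, df1 = df1, df2 = df2)
}

#' Fit all three individual-level estimators
#'
#' Runs [fitPhenotypicOls()], [fitWfMvmr()] and [fitStandardMr()] on the same
#' design and binds the tidy rows.
#'
#' @param design a [TrioDesign-class].
#' @param outcome label recorded in the `outcome` column.
#' @return data.frame with one row per (outcome, exposure, estimator).
#' @export
fitAllEstimators <- function(design, outcome = "outcome") {
  out <- rbind(fitPhenotypicOls(design), fitWfMvmr(design),
               fitStandardMr(design))
  cbind(outcome = outcome, out, stringsAsFactors = FALSE)
}
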