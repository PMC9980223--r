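# Internal helpers shared across modules.

#' @importFrom stats rnorm rbinom runif coef lm qnorm pnorm pt pf sd var cor
#'   median complete.cases setNames residuals dnorm mad quantile
#' @importFrom methods new validObject is slot
#' @importFrom utils packageVersion read.delim write.table head
NULL

# Derive a per-stage seed from a root seed so that adding draws in one stage
# (e.g. more SNPs) does not perturb the random stream of another stage.
# Kept below 2^31 - 1 so set.seed() accepts it.
.stage_seed <- function(seed, stage) {
  chars <- utf8ToInt(stage)
  h <- sum(chars * seq_along(chars)) %% 99991
  as.integer((abs(as.numeric(seed)) %% 2147480000 * 48271 + h * 7919) %%
               2147483647)
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

.assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                  strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  ok <- if (strict) (x > lower && x < upper) else (x >= lower && x <= upper)
  if (!ok)
    stop(sprintf("'%s' = %g is outside %s%g, %g%s", name, x,
                 if (strict) "(" else "[", lower, upper,
                 if (strict) ")" else "]"), call. = FALSE)
  invisible(x)
}

# z-standardize a vector; a constant vector maps to zeros rather than NaN.
.standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  as.numeric((x - mean(x)) / s)
}

# OLS with CR0 cluster-robust covariance (finite-sample factor G/(G-1)).
# Returns coefficients, their cluster-robust SEs, residuals and fit stats.
.ols_cluster <- function(X, y, cluster) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrX, y)
  e <- as.numeric(y - X %*% beta)
  A <- chol2inv(qr.R(qrX))
  cl <- as.factor(cluster)
  G <- nlevels(cl)
  Xe <- rowsum(X * e, cl)
  meat <- crossprod(Xe)
  V <- A %*% meat %*% A * G / max(G - 1, 1)
  dimnames(V) <- list(colnames(X), colnames(X))
  list(coef = beta, vcov = V, residuals = e, rank = qrX$rank,
       n = length(y), n_clusters = G)
}

.ci <- function(est, se, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(lower = est - z * se, upper = est + z * se)
}
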