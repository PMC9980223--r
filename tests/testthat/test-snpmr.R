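test_that("per-SNP outcome model matches the normal-equations oracle", {
  co <- quick_cohort(n = 8, snps = 2, seed = 23)
  a <- estimateSnpOutcomeAssociations(co, "mother")
  y <- phenotypes(co)$outcome_child
  for (j in seq_len(nrow(a))) {
    X <- cbind(1, dosageMatrix(co, "child")[, j],
               dosageMatrix(co, "mother")[, j],
               dosageMatrix(co, "father")[, j])
    beta <- solve(t(X) %*% X) %*% t(X) %*% y
    expect_equal(a$beta[j], beta[3], tolerance = 1e-10)
  }
  b <- estimateSnpOutcomeAssociations(co, "father")
  expect_identical(b$parent, rep("father", nrow(b)))
})

test_that("null outcome gives ~5% nominal significance; planted signal found", {
  co <- quick_cohort(n = 3000, snps = 40, seed = 29, dynasticMother = 0,
                     dynasticFather = 0, exposureEffect = 0)
  a <- estimateSnpOutcomeAssociations(co, "mother")
  z <- abs(a$beta / a$se)
  expect_equal(mean(z > 1.96), 0.05, tolerance = 0.1)
  expect_lt(max(abs(a$beta)), 0.25)
  # outcome = 0.3 * mother dosage at SNP 1 exactly
  cd <- SummarizedExperiment::colData(co)
  cd$outcome_child <- 0.3 * dosageMatrix(co, "mother")[, 1]
  SummarizedExperiment::colData(co) <- cd
  a2 <- estimateSnpOutcomeAssociations(co, "mother")
  expect_equal(a2$beta[1], 0.3, tolerance = 1e-10)
  expect_lt(max(abs(a2$beta[-1])), 0.05)
})

test_that("monomorphic variants are dropped with a warning", {
  co <- quick_cohort(n = 60, snps = 2, seed = 3)
  for (role in c("mother", "father", "child")) {
    a <- SummarizedExperiment::assay(co, role)
    a[2, ] <- 0
    SummarizedExperiment::assays(co)[[role]] <- a
  }
  expect_warning(a <- estimateSnpOutcomeAssociations(co, "mother"),
                 "monomorphic")
  expect_identical(a$variant_id, "snp1")
})

test_that("IVW matches the explicit weighted-sum formula", {
  assoc <- toy_assoc(beta_x = c(0.10, 0.15, 0.08, 0.20, 0.12),
                     se_x = rep(0.01, 5),
                     beta_y = c(0.052, 0.071, 0.049, 0.095, 0.066),
                     se_y = c(0.010, 0.012, 0.009, 0.015, 0.011))
  res <- mrIvw(assoc)
  w <- 1 / assoc$se_outcome^2
  slope <- sum(w * assoc$beta_exposure * assoc$beta_outcome) /
    sum(w * assoc$beta_exposure^2)
  q <- sum(w * (assoc$beta_outcome - slope * assoc$beta_exposure)^2)
  se <- sqrt(1 / sum(w * assoc$beta_exposure^2)) * max(1, sqrt(q / 4))
  expect_equal(res$estimate, slope, tolerance = 1e-12)
  expect_equal(res$se, se, tolerance = 1e-12)
  expect_equal(res$q_stat, q, tolerance = 1e-12)
  # homogeneous ratios: slope = common ratio, Q = 0
  hom <- toy_assoc(beta_x = c(0.1, 0.2, 0.3), se_x = rep(0.01, 3),
                   beta_y = 0.7 * c(0.1, 0.2, 0.3), se_y = rep(0.01, 3))
  rhom <- mrIvw(hom)
  expect_equal(rhom$estimate, 0.7, tolerance = 1e-12)
  expect_equal(rhom$q_stat, 0, tolerance = 1e-12)
  expect_error(mrIvw(assoc[1, ]), "at least 2")
})

test_that("single instrument reduces every estimator path to the Wald ratio", {
  one <- toy_assoc(beta_x = 0.12, se_x = 0.01, beta_y = 0.06, se_y = 0.02)
  res <- mrWaldRatio(one)
  expect_equal(res$estimate, 0.5)
  expect_equal(res$se, 0.02 / 0.12)
  expect_identical(mrSummary(one)$estimator, "wald_ratio")
  expect_equal(mrSummary(one)$estimate, 0.5)
})

test_that("MR-Egger equals the weighted least-squares closed form", {
  assoc <- toy_assoc(beta_x = c(0.10, -0.15, 0.08, 0.20, 0.12),
                     se_x = rep(0.01, 5),
                     beta_y = c(0.072, -0.061, 0.069, 0.115, 0.086),
                     se_y = c(0.010, 0.012, 0.009, 0.015, 0.011))
  res <- mrEgger(assoc)
  # orientation: bx non-negative, by flipped in tandem
  s <- sign(assoc$beta_exposure)
  bx <- abs(assoc$beta_exposure); by <- assoc$beta_outcome * s
  w <- 1 / assoc$se_outcome^2
  X <- cbind(1, bx)
  A <- solve(t(X) %*% (w * X))
  beta <- A %*% t(X) %*% (w * by)
  q <- sum(w * (by - X %*% beta)^2)
  scale_ <- max(1, sqrt(q / 3))
  expect_equal(res$egger_intercept, beta[1], tolerance = 1e-10)
  expect_equal(res$estimate, beta[2], tolerance = 1e-10)
  expect_equal(res$se, sqrt(A[2, 2]) * scale_, tolerance = 1e-10)
  expect_error(mrEgger(assoc[1:2, ]), "at least 3")
})

test_that("Egger recovers planted directional pleiotropy; slope less biased", {
  reps <- 200
  ests <- t(vapply(seq_len(reps), function(r) {
    assoc <- sim_assoc(40, b = 1, alpha = 0.05, seed = 1000 + r)
    c(egger_int = mrEgger(assoc)$egger_intercept,
      egger_slope = mrEgger(assoc)$estimate,
      ivw = mrIvw(assoc)$estimate)
  }, numeric(3)))
  expect_lt(abs(mean(ests[, "egger_int"]) - 0.05), 0.01)
  expect_lt(abs(mean(ests[, "egger_slope"]) - 1),
            abs(mean(ests[, "ivw"]) - 1))
})

test_that("Egger intercept test holds its ~5% size under null pleiotropy", {
  reps <- 200
  rej <- vapply(seq_len(reps), function(r) {
    assoc <- sim_assoc(30, b = 1, alpha = 0, seed = 2000 + r)
    mrEgger(assoc)$egger_intercept_p < 0.05
  }, logical(1))
  # binomial 3-sigma band around 0.05 with 200 replicates
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("weighted median interpolation matches hand computation", {
  # 3 equal-weight SNPs, ratios (1, 2, 9): cumulative midpoint hits 2
  eq <- toy_assoc(beta_x = c(0.1, 0.1, 0.1), se_x = rep(0.01, 3),
                  beta_y = c(0.1, 0.2, 0.9), se_y = rep(0.01, 3))
  expect_equal(suppressWarnings(mrWeightedMedian(eq, n_boot = 50))$estimate,
               2)
  # 4-SNP hand example: ratios (1,2,3,10), normalized weights
  # (.1,.2,.3,.4) -> cumulative midpoints (.05,.2,.45,.8); the 50th
  # percentile interpolates between 3 and 10: 3 + 7 * (0.05/0.35) = 4
  bx <- rep(0.1, 4)
  w_target <- c(0.1, 0.2, 0.3, 0.4)
  se_y <- sqrt(bx^2 / (w_target / max(w_target))) / bx * 0.1
  se_y <- 0.1 / sqrt(w_target)  # weights bx^2/se_y^2 proportional to target
  h4 <- toy_assoc(beta_x = bx, se_x = rep(0.01, 4),
                  beta_y = bx * c(1, 2, 3, 10), se_y = se_y)
  expect_equal(suppressWarnings(mrWeightedMedian(h4, n_boot = 50))$estimate,
               4, tolerance = 1e-9)
  expect_error(mrWeightedMedian(h4, n_boot = 0), "at least 1")
  expect_warning(mrWeightedMedian(h4, n_boot = 50), "n_boot")
})

test_that("weighted median withstands 49% invalid weight where IVW fails", {
  # Dispersed directional pleiotropy (alpha ~ N(0.1, 0.4^2)) on SNPs
  # carrying just under half the weight. The weighted median's sampling
  # distribution stays centred at the truth (its residual bias, an extreme
  # valid-ratio quantile effect, is below the replicate SD and an order of
  # magnitude below the IVW bias); the IVW mean is many MC SEs away.
  reps <- 50
  res <- t(vapply(seq_len(reps), function(r) {
    set.seed(3000 + r)
    n_snp <- 50
    bx <- runif(n_snp, 0.1, 0.2)
    invalid <- seq_len(n_snp) <= 24
    alpha <- ifelse(invalid, rnorm(n_snp, 0.1, 0.4), 0)
    assoc <- toy_assoc(beta_x = rnorm(n_snp, bx, 0.003),
                       se_x = rep(0.003, n_snp),
                       beta_y = rnorm(n_snp, 1 * bx + alpha, 0.01),
                       se_y = rep(0.01, n_snp))
    w <- assoc$beta_exposure^2 / assoc$se_outcome^2
    c(wm = suppressWarnings(mrWeightedMedian(assoc, n_boot = 60,
                                             seed = r))$estimate,
      ivw = mrIvw(assoc)$estimate,
      frac = sum(w[invalid]) / sum(w))
  }, numeric(3)))
  expect_lt(mean(res[, "frac"]), 0.5)        # invalid weight stays minority
  expect_gt(mean(res[, "frac"]), 0.45)
  wm_bias <- abs(mean(res[, "wm"]) - 1)
  ivw_bias <- abs(mean(res[, "ivw"]) - 1)
  expect_lt(wm_bias, sd(res[, "wm"]))
  expect_lt(wm_bias, 0.1 * ivw_bias)
  expect_gt(ivw_bias, 3 * sd(res[, "ivw"]) / sqrt(reps))
})

test_that("weighted mode finds the plurality ratio", {
  # all ratios identical: estimate equals that ratio for any bandwidth
  same <- toy_assoc(beta_x = c(0.1, 0.2, 0.3), se_x = rep(0.01, 3),
                    beta_y = 2 * c(0.1, 0.2, 0.3), se_y = rep(0.01, 3))
  for (bf in c(0.5, 1, 2))
    expect_equal(suppressWarnings(
      mrWeightedMode(same, bandwidth_factor = bf, n_boot = 50))$estimate, 2)
  expect_error(mrWeightedMode(same, bandwidth_factor = 0), "bandwidth")
  # 60% of SNPs at ratio 1, 40% scattered -> mode near 1
  set.seed(77)
  bx <- runif(20, 0.1, 0.2)
  ratios <- c(rep(1, 12), runif(8, 2, 6))
  assoc <- toy_assoc(beta_x = bx, se_x = rep(0.005, 20),
                     beta_y = bx * ratios + rnorm(20, 0, 0.002),
                     se_y = rep(0.01, 20))
  est <- suppressWarnings(mrWeightedMode(assoc, n_boot = 60))$estimate
  # density-peak oracle on a fine grid with the same kernel and bandwidth
  r <- assoc$beta_outcome / assoc$beta_exposure
  w <- assoc$beta_exposure^2 / assoc$se_outcome^2
  expect_equal(est, 1, tolerance = 0.15)
  # doubling the bandwidth moves the estimate continuously, not wildly
  est2 <- suppressWarnings(
    mrWeightedMode(assoc, bandwidth_factor = 2, n_boot = 60))$estimate
  expect_lt(abs(est2 - est), 0.5)
})

test_that("scaling exposure betas by c scales every slope by 1/c", {
  assoc <- sim_assoc(25, b = 0.8, seed = 41)
  for (fn in list(mrIvw, mrEgger,
                  function(a) suppressWarnings(mrWeightedMedian(a, 60)),
                  function(a) suppressWarnings(mrWeightedMode(a, 1, 60)))) {
    base <- fn(assoc)$estimate
    sc <- assoc
    sc$beta_exposure <- 4 * sc$beta_exposure
    sc$se_exposure <- 4 * sc$se_exposure
    expect_equal(fn(sc)$estimate, base / 4, tolerance = 1e-6)
  }
})

test_that("harmonization flips, drops and reports correctly", {
  expo <- data.frame(variant_id = c("v1", "v2", "v3", "v4", "v5"),
                     effect_allele = c("A", "A", "A", "A", "A"),
                     other_allele = c("G", "G", "T", "T", "C"),
                     beta = c(0.1, 0.1, 0.1, 0.1, 0.1), se = 0.01,
                     eaf = c(0.3, 0.3, 0.50, 0.30, 0.3),
                     stringsAsFactors = FALSE)
  outc <- data.frame(variant_id = expo$variant_id,
                     effect_allele = c("A", "G", "A", "T", "C"),
                     other_allele = c("G", "A", "T", "A", "T"),
                     beta = c(0.05, 0.05, 0.05, 0.05, 0.05), se = 0.01,
                     eaf = 0.3, stringsAsFactors = FALSE)
  # v1 identical -> unchanged; v2 swapped -> negated; v3 palindromic at
  # freq 0.5 -> dropped; v4 palindromic (A/T) at unambiguous freq, swapped
  # -> kept and negated; v5 A/C vs C/T -> irreconcilable, dropped + warning
  expect_warning(res <- harmonize(expo, outc), "irreconcilable.*v5")
  expect_setequal(res$variant_id, c("v1", "v2", "v4"))
  expect_equal(res$beta_outcome[res$variant_id == "v1"], 0.05)
  expect_equal(res$beta_outcome[res$variant_id == "v2"], -0.05)
  expect_equal(res$beta_outcome[res$variant_id == "v4"], -0.05)
  expect_identical(attr(res, "n_dropped_palindromic"), 1L)
  expect_identical(attr(res, "n_dropped_mismatch"), 1L)
  expect_identical(attr(res, "n_flipped"), 2L)
})
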