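test_that("parental genotypes follow Binomial(2, freq) moments", {
  cfg <- simConfig(nCouples = 40000, alleleFreqs = 0.5, seed = 1)
  g <- simulateParentalGenotypes(cfg)
  expect_equal(dim(g$mother), c(40000, 1))
  expect_equal(mean(g$mother), 1.0, tolerance = 0.02)
  expect_equal(var(as.numeric(g$mother)), 0.5, tolerance = 0.05)
  # degenerate frequency: almost everything is 0
  tiny <- simulateParentalGenotypes(
    simConfig(nCouples = 1000, alleleFreqs = 0.001, seed = 2))
  expect_gt(mean(tiny$father == 0), 0.99)
})

test_that("simulation is bit-reproducible and seed-sensitive", {
  cfg <- simConfig(nCouples = 500, nSnps = 4, assortmentPhi = 0.4, seed = 9)
  c1 <- simulateTrioCohort(cfg)
  c2 <- simulateTrioCohort(cfg)
  expect_identical(dosageMatrix(c1, "child"), dosageMatrix(c2, "child"))
  expect_identical(phenotypes(c1), phenotypes(c2))
  c3 <- simulateTrioCohort(simConfig(nCouples = 500, nSnps = 4,
                                     assortmentPhi = 0.4, seed = 10))
  expect_false(identical(dosageMatrix(c1, "child"),
                         dosageMatrix(c3, "child")))
  # different seeds, same distribution: moments agree within MC error
  expect_equal(mean(dosageMatrix(c1, "mother")),
               mean(dosageMatrix(c3, "mother")), tolerance = 0.1)
})

test_that("spousal genotype correlation rises with phi and is 0 at phi=0", {
  n <- 40000
  cors <- vapply(c(0, 0.3, 0.6, 0.9), function(phi) {
    r <- vapply(1:10, function(rep) {
      g <- simulateParentalGenotypes(
        simConfig(nCouples = n, seed = 100 + rep))
      pair <- assortCouples(g$mother, g$father, phi, seed = 100 + rep)
      cor(g$mother[, 1], g$father[pair, 1])
    }, numeric(1))
    mean(r)
  }, numeric(1))
  expect_lt(abs(cors[1]), 3 / sqrt(n))
  expect_true(all(diff(cors) > 0))
  # phi = 1 matches on genotype rank alone: correlation near its maximum
  g <- simulateParentalGenotypes(simConfig(nCouples = n, seed = 3))
  pair <- assortCouples(g$mother, g$father, 1, seed = 3)
  expect_gt(cor(g$mother[, 1], g$father[pair, 1]), 0.9)
  expect_error(assortCouples(g$mother, g$father, 1.2), "phi")
  expect_error(assortCouples(g$mother[1:10, , drop = FALSE], g$father),
               "equal numbers")
})

test_that("assortative pairing is always a permutation", {
  for (phi in c(0, 0.5, 1)) {
    g <- simulateParentalGenotypes(simConfig(nCouples = 257, seed = 21))
    pair <- assortCouples(g$mother, g$father, phi, seed = 21)
    expect_setequal(pair, seq_len(257))
  }
})

test_that("Mendelian transmission: exact enumeration and legality", {
  # homozygous parents are deterministic
  m2 <- matrix(2L, 50, 1); m0 <- matrix(0L, 50, 1)
  expect_true(all(transmitGenotypes(m2, m2, 1:50, seed = 1) == 2L))
  expect_true(all(transmitGenotypes(m0, m0, 1:50, seed = 1) == 0L))
  expect_true(all(transmitGenotypes(m2, m0, 1:50, seed = 1) == 1L))
  # het x het -> {0: 1/4, 1: 1/2, 2: 1/4} (gamete enumeration)
  n <- 40000
  m1 <- matrix(1L, n, 1)
  kid <- transmitGenotypes(m1, m1, seq_len(n), seed = 4)
  frac <- tabulate(kid + 1L, 3) / n
  expect_equal(frac, c(0.25, 0.5, 0.25), tolerance = 0.03)
  expect_error(transmitGenotypes(m1, m1, rep(1L, n)), "permutation")
  # zero illegal child genotypes across assorted multi-SNP cohorts
  for (phi in c(0, 0.9)) {
    co <- quick_cohort(n = 1500, snps = 6, phi = phi, seed = 31)
    expect_identical(countMendelianViolations(co), 0L)
  }
})

test_that("child PGI regresses on both parental PGIs with slopes near 0.5", {
  # On the raw-score scale the joint transmission coefficients are exactly
  # 0.5 at any assortment level (E[g_c | g_m, g_f] = (g_m + g_f)/2). On the
  # per-role standardized scale this carries over under random mating; a
  # single assorted generation inflates the child PGI variance relative to
  # its (unassorted-ancestry) parents, shrinking the standardized slope.
  for (phi in c(0, 0.6)) {
    co <- quick_cohort(n = 20000, snps = 50, phi = phi, seed = 17)
    pgis <- cohortPgis(co)
    fit <- lm(pgi_raw_child ~ pgi_raw_mother + pgi_raw_father, data = pgis)
    ses <- summary(fit)$coefficients[-1, "Std. Error"]
    expect_lt(abs(coef(fit)[["pgi_raw_mother"]] - 0.5), 3 * ses[1])
    expect_lt(abs(coef(fit)[["pgi_raw_father"]] - 0.5), 3 * ses[2])
  }
  co <- quick_cohort(n = 20000, snps = 50, phi = 0, seed = 17)
  pgis <- cohortPgis(co)
  fit <- lm(pgi_child ~ pgi_mother + pgi_father, data = pgis)
  ses <- summary(fit)$coefficients[-1, "Std. Error"]
  expect_lt(abs(coef(fit)[["pgi_mother"]] - 0.5), 3 * ses[1])
  expect_lt(abs(coef(fit)[["pgi_father"]] - 0.5), 3 * ses[2])
})

test_that("phenotype generation follows the configured effects", {
  # pure noise model: unit outcome variance, no genotype correlation
  co <- quick_cohort(n = 20000, snps = 2, seed = 5, dynasticMother = 0,
                     dynasticFather = 0, exposureEffect = 0)
  ph <- phenotypes(co)
  expect_equal(var(ph$outcome_child), 1, tolerance = 0.05)
  expect_lt(abs(cor(ph$outcome_child, dosageMatrix(co, "child")[, 1])),
            3 / sqrt(20000))
  # direct effect recovered by OLS of outcome on child dosage sum
  co2 <- quick_cohort(n = 20000, snps = 1, seed = 6, dynasticMother = 0,
                      dynasticFather = 0, exposureEffect = 0,
                      directEffect = 0.5)
  fit <- lm(phenotypes(co2)$outcome_child ~ dosageMatrix(co2, "child")[, 1])
  expect_equal(unname(coef(fit)[2]), 0.5, tolerance = 0.05)
  # dynastic covariance under the restricted model:
  # cov(y, x_m) = Var(x_m) + cov(x_f, x_m); at phi=0 spouses independent,
  # so cov(y, x_m) = Var(g) + noise^2 = 1.5
  co3 <- quick_cohort(n = 40000, snps = 1, seed = 7)
  ph3 <- phenotypes(co3)
  expect_equal(cov(ph3$outcome_child, ph3$exposure_mother), 1.5,
               tolerance = 0.06)
})

test_that("empty and invalid configurations are handled", {
  expect_error(simConfig(nCouples = 10, alleleFreqs = 1.2), "inside")
  expect_error(simConfig(nCouples = 10, assortmentPhi = 2), "\\[0, 1\\]")
  expect_error(simConfig(nCouples = 10, noiseSdExposure = 0), "> 0")
  empty <- simulateTrioCohort(simConfig(nCouples = 0, seed = 1))
  expect_identical(nFamilies(empty), 0L)
  expect_identical(countMendelianViolations(empty), 0L)
})

test_that("TrioCohort validity rejects malformed dosages", {
  gm <- matrix(c(0, 1), 1, 2)
  expect_error(TrioCohort(gm, gm, matrix(c(0, 3), 1, 2)), "\\[0, 2\\]")
  expect_error(TrioCohort(gm, gm, matrix(0, 2, 2)), "dimensions")
})
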