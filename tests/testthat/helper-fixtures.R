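# Shared fixtures, all generated in code.

# small cohort under the restricted generative model
quick_cohort <- function(n = 2000, snps = 1, phi = 0, seed = 42, ...) {
  simulateTrioCohort(simConfig(nCouples = n, nSnps = snps,
                               assortmentPhi = phi, seed = seed, ...))
}

# hand-rollable design with known coefficients and optional noise
toy_design <- function(n = 10, seed = 7, noise = 0) {
  set.seed(seed)
  gm <- rnorm(n); gf <- rnorm(n); gc <- rnorm(n)
  xm <- 1.0 * gm + rnorm(n, 0, 0.5)
  xf <- 1.0 * gf + rnorm(n, 0, 0.5)
  y <- 2 * xm + 3 * xf + noise * rnorm(n)
  trioDesign(outcome = y, exposureMother = xm, exposureFather = xf,
             pgiMother = gm, pgiFather = gf, pgiChild = gc)
}

# harmonized summary-data association set
toy_assoc <- function(beta_x, se_x, beta_y, se_y, ids = NULL) {
  n <- length(beta_x)
  if (is.null(ids)) ids <- paste0("snp", seq_len(n))
  data.frame(variant_id = ids, effect_allele = "A", other_allele = "G",
             beta_exposure = beta_x, se_exposure = se_x,
             beta_outcome = beta_y, se_outcome = se_y,
             eaf = 0.3, flipped = FALSE, stringsAsFactors = FALSE)
}

# simulate GWAS-style summary statistics: true slope `b`, optional per-SNP
# pleiotropic intercepts `alpha`, measurement noise per side (exposure-side
# noise kept small so the NOME assumption of MR-Egger holds)
sim_assoc <- function(n_snp, b = 1, alpha = 0, se_x = 0.003, se_y = 0.05,
                      seed = 1) {
  set.seed(seed)
  bx_true <- runif(n_snp, 0.05, 0.2)
  alpha <- rep(alpha, length.out = n_snp)
  toy_assoc(beta_x = rnorm(n_snp, bx_true, se_x), se_x = rep(se_x, n_snp),
            beta_y = rnorm(n_snp, b * bx_true + alpha, se_y),
            se_y = rep(se_y, n_snp))
}

# 20-variant panel with constructed LD blocks + matching reference dosages
ld_fixture <- function(seed = 11, n_ref = 400) {
  set.seed(seed)
  p <- 20
  panel <- data.frame(
    variant_id = sprintf("v%02d", 1:p),
    chromosome = rep(c(1L, 2L), each = 10),
    position = rep(seq(1e6, 10e6, by = 1e6), 2),
    effect_allele = "A", other_allele = "G",
    weight = round(rnorm(p, 0, 0.05), 4),
    p_value = signif(10^runif(p, -12, -8), 3),
    stringsAsFactors = FALSE)
  # blocks of correlated variants: within a block, dosages are copies of a
  # template with occasional flips, so r2 is high; across blocks ~0
  block <- rep(1:5, each = 4)
  dos <- matrix(0, n_ref, p)
  for (b in unique(block)) {
    template <- rbinom(n_ref, 2, 0.4)
    for (j in which(block == b)) {
      mut <- rbinom(n_ref, 1, 0.08)
      col <- ifelse(mut == 1, rbinom(n_ref, 2, 0.4), template)
      dos[, j] <- col
    }
  }
  colnames(dos) <- panel$variant_id
  list(panel = panel, dosages = dos, ld = ldFromDosages(dos))
}

# brute-force check that a clumped panel is a valid greedy solution
clump_is_valid <- function(kept, full, ld, window_kb, r2) {
  win <- window_kb * 1000
  pairs_in_window <- function(a, b)
    a$chromosome == b$chromosome & abs(a$position - b$position) <= win
  # retained set pairwise below threshold within window
  for (i in seq_len(nrow(kept))) for (j in seq_len(nrow(kept))) {
    if (i == j) next
    if (pairs_in_window(kept[i, ], kept[j, ]) &&
        ld[kept$variant_id[i], kept$variant_id[j]] >= r2) return(FALSE)
  }
  # every removed variant is blocked by a retained better-p in-window variant
  removed <- full[!full$variant_id %in% kept$variant_id, , drop = FALSE]
  for (i in seq_len(nrow(removed))) {
    blockers <- vapply(seq_len(nrow(kept)), function(j) {
      pairs_in_window(removed[i, ], kept[j, ]) &&
        ld[removed$variant_id[i], kept$variant_id[j]] >= r2 &&
        (kept$p_value[j] < removed$p_value[i] ||
           (kept$p_value[j] == removed$p_value[i]))
    }, logical(1))
    if (!any(blockers)) return(FALSE)
  }
  TRUE
}
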