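---
title: "Within-family Mendelian randomization with parent-child trios"
author: "triomr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Within-family Mendelian randomization with parent-child trios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triomr)
```

## The estimation problem

Parents' phenotypes (the canonical example is educational attainment)
correlate strongly with their children's outcomes. The correlation mixes at
least four mechanisms: direct genetic transmission, *dynastic effects*
(genetic nurture — parents' genotypes shaping the rearing environment via the
parents' own phenotypes), assortative mating, and population structure.
`triomr` implements the trio design that separates the dynastic path from the
others: in a genotyped mother-father-child trio, each parent's polygenic
index (PGI) instruments that parent's exposure phenotype, while the *child's*
PGI is conditioned on. Because transmission is Mendelian, the child's
genotype is quasi-random given the parents' genotypes; conditioning on the
child's PGI closes the transmitted-allele path, and instrumenting with both
parents' PGIs simultaneously absorbs the spousal correlation induced by
assortative mating.

The individual-level estimator is a two-exposure, two-instrument two-stage
least squares. First stages, for each parent $p \in \{m, f\}$ of family $k$:

$$x_{k,p} = \gamma_{p0} + \gamma_{p1} g_{k,c} + \gamma_{p2} g_{k,m} +
\gamma_{p3} g_{k,f} + \gamma_{p4} C_k + u_{k,p}$$

and the second stage:

$$y_k = \beta_0 + \beta_1 g_{k,c} + \beta_2 \hat x_{k,m} +
\beta_3 \hat x_{k,f} + \beta_4 C_k + e_k,$$

with $g_{k,c}, g_{k,m}, g_{k,f}$ the child/mother/father PGIs, $C_k$
covariates, and standard errors cluster-robust by family (CR0 with a
$G/(G-1)$ finite-sample factor), computed from second-stage residuals at the
*observed* exposures. `fitWfMvmr()` implements this; `fitPhenotypicOls()` and
`fitStandardMr()` are the comparators; `conditionalFStatistic()` reports
Sanderson-Windmeijer conditional instrument strength.

## The synthetic cohort generator

Real trio cohorts of this kind are access-restricted, so the package ships a
generator (`simulateTrioCohort()`) that reproduces the statistical structure
the estimators assume:

1. **Parental pools.** Dosages at each biallelic locus are
   Binomial(2, allele frequency) — Hardy-Weinberg proportions,
   no LD between loci.
2. **Assortment.** Each individual gets a latent score
   $a = \phi\, z(g) + (1-\phi)\, v$, where $z(g)$ is the standardized mean
   genotype and $v$ is standard normal noise. Pools are paired by rank of
   $a$. The genotypes entering the score are standardized so that $\phi$
   interpolates between random mating ($\phi = 0$) and genotype-rank
   matching ($\phi = 1$) on a common scale; the matching rule itself
   (sort-and-match) is the simplest mechanism whose spousal correlation
   rises monotonically with $\phi$. A Gaussian-copula pairing would be a
   drop-in alternative; rank pairing was chosen because it is deterministic
   given the scores.
3. **Transmission.** Each child receives one allele drawn uniformly from
   each parent's two alleles, so the transmitted count from a parent with
   dosage $g$ is Bernoulli($g/2$) and illegal genotypes are impossible by
   construction (`countMendelianViolations()` checks this exactly).
4. **Phenotypes.** Parental exposure $x = g^\top w_x + \varepsilon$,
   $\varepsilon \sim N(0, \sigma_x^2)$; child outcome
   $y = \beta_m x_m + \beta_f x_f + g_c^\top(\delta + \alpha) + \varepsilon'$,
   with per-SNP pleiotropy $\alpha_j \sim N(\mu_\alpha, \sigma_\alpha^2)$.

The defaults (`simConfig()`) are the restricted model of the assortment
study: one SNP at frequency 0.5, $w_x = 1$, $\beta_m = \beta_f = 1$,
$\delta = 0$, $\alpha \equiv 0$, unit noise SDs. "Child phenotype is a
function of the parents' phenotypes with coefficient 1" is read as a
coefficient of 1 on *each* parent separately; multi-SNP panels, direct
effects, per-SNP exposure weights and pleiotropy are generalizations needed
to exercise the summary-data estimators and the child-PGI conditioning, and
all of them are off by default.

Randomness flows from a single root seed through per-stage derived streams
(genotypes, assortment, transmission, pleiotropy, phenotype noise), so
adding SNPs does not perturb the phenotype noise and identical
configurations give bit-identical cohorts.

### What the generator does and does not emulate

It reproduces Mendelian transmission, one generation of genotype-based
assortment, dynastic/direct/pleiotropic architecture, and family-keyed data
layout. It does **not** emulate LD between variants (clumping is tested
against its own constructed-LD fixture), multi-generational assortment
equilibrium, selection/participation bias, measurement error in phenotypes,
or missing data. Passing tests therefore validate the estimators under the
stated generative model, not robustness to those real-data features.

One consequence of single-generation assortment is worth flagging: the joint
regression of the child PGI on both parental PGIs has coefficients of
exactly 0.5 on the *raw-score* scale at any $\phi$, but per-role
standardization shrinks them to $0.5/\sqrt{1 + r/2}$ (with $r$ the spousal
PGI correlation) because the children's PGI variance is inflated relative to
their unassorted-ancestry parents. A real cohort at assortment equilibrium
does not show this discrepancy. The transmission-coefficient check is
therefore run under random mating, where the two scales coincide.

## Polygenic indices

`clumpVariants()` is the standard greedy p-value clumping: order by
ascending p-value (ties broken by chromosome, position, variant id, so the
output is invariant to input row order), accept a variant unless a retained
same-chromosome variant within the window has $r^2$ at or above the
threshold. The two regimes used in practice — $r^2 < 0.01$ within 10,000 kb
for index construction and a more conservative $r^2 < 0.001$ for two-sample
summary MR, both at $p < 5\times10^{-8}$ — are parameterizations of the same
operation. A missing $r^2$ for an in-window pair is an error rather than an
assumption of independence. For simulated data the LD source is an empirical
$r^2$ matrix from reference dosages (`ldFromDosages()`); external reference
panels are out of scope. `buildPgi()` forms the weighted allele-dosage sum
and standardizes within the supplied sample, per role, matching the
convention of reporting effects per SD of the index.

## Summary-data estimators

`estimateSnpOutcomeAssociations()` fits, SNP by SNP, the child outcome on
the child, mother and father dosages at that SNP (plus covariates) with
family-clustered errors, returning the requested parent's coefficient — the
trio-adjusted outcome association. After `harmonize()` aligns effect
alleles (sign flips for swapped or strand-flipped alleles; strand-ambiguous
palindromic variants with allele frequency in 0.42–0.58 dropped — a common
convention, chosen here because the sources are silent), four
self-contained estimators are available, in their canonical published
forms:

* **IVW** (`mrIvw()`): weighted zero-intercept regression of outcome on
  exposure betas, weights $1/\mathrm{se}_y^2$; multiplicative
  random-effects SE with the residual scale floored at 1 (the
  fixed-/random-effects choice is not stated by the sources; the floored
  multiplicative form never reports less uncertainty than fixed effects).
  Cochran's Q is reported.
* **MR-Egger** (`mrEgger()`): same regression with a free intercept,
  exposure betas oriented non-negative; the intercept estimates directional
  pleiotropy with a t-test on $n-2$ degrees of freedom.
* **Weighted median** (`mrWeightedMedian()`): interpolated weighted 50th
  percentile of the Wald ratios, ratio weights $b_x^2/\mathrm{se}_y^2$;
  SE by seeded parametric bootstrap (default 1,000 draws).
* **Weighted mode** (`mrWeightedMode()`): mode of the weight-scaled
  Gaussian kernel density of the ratios; bandwidth =
  `bandwidth_factor` $\times\ 0.9 \cdot 1.4826\,\mathrm{wMAD}\, n^{-1/5}$;
  identical ratios short-circuit to that ratio; zero bandwidth is an error.

A single instrument reduces every path to the Wald ratio
$b_y/b_x$ (`mrWaldRatio()`), with delta-method SE.

Numerical notes: the weighted-median interpolation uses cumulative weight
midpoints $(S_j - w_j/2)/\sum w$; the mode search uses a 512-point grid over
the ratio range padded by three bandwidths; bootstrap draws resample both
exposure and outcome betas from their normal sampling distributions under a
derived seed, so results are reproducible and independent of draw order
elsewhere.

Two estimator-design caveats surfaced by the calibration suite are inherent
to the methods, not implementation artifacts. MR-Egger assumes negligible
exposure-side measurement error (NOME): exposure betas measured with
non-trivial error dilute the slope and push the intercept off zero, so the
type-I-error calibration uses precise exposure betas. The weighted median at
*exactly* its 50%-invalid-weight breakdown boundary sits at an extreme
quantile of the valid-ratio distribution; its residual bias scales with the
ratio noise exactly as its replicate SD does, so the package's robustness
test plants dispersed directional pleiotropy on SNPs carrying just under
half the weight and checks that the median's sampling distribution stays
centred at the truth (bias below its replicate SD and an order of magnitude
below the IVW bias).

## The comparator estimators and the assortment bias study

`runAssortmentGrid()` reruns the whole pipeline over a grid of $\phi$ values
(default $0, 0.1, \ldots, 0.9$ — the step is a package choice) and
aggregates per-replicate estimates into mean, bias against the configured
truth, and Monte-Carlo SE ($\mathrm{SD}/\sqrt{\mathrm{reps}}$), with
estimator failures recorded and excluded rather than fatal.

The contrast the grid reproduces needs care about what the comparators are.
Under the generator's outcome model, the *mutually adjusted* OLS of $y$ on
$(x_m, x_f)$ and the two-instrument 2SLS without the child PGI are exactly
unbiased at any $\phi$ when the direct effect is zero — their regressors and
instruments are exogenous to the outcome noise. The assortment bias that the
trio design removes arises in the *single-parent* analyses: omitting the
spouse's exposure (OLS) inflates the coefficient by
$\mathrm{cov}(x_m, x_f)/\mathrm{var}(x_m)$, and instrumenting one parent's
exposure with their own PGI alone (conventional MR) inflates the Wald ratio
by the spousal genotype correlation, since the instrument then proxies the
omitted parent's exposure too. Including both parents in a multivariable
estimation adjusts away exactly this correlation. Accordingly
`fitStandardMr()` is the conventional per-parent univariable 2SLS (own PGI
instrumenting own exposure, no child PGI, no other parent), and the bias
study's "ols" arm is `fitPhenotypicOls(design, perParent = TRUE)`; the
default mutually adjusted OLS remains the real-data phenotypic estimator.
With a dynastic effect of 1 and $\phi = 0.9$, the grid at $n = 4{,}000$ and
200 replicates shows the single-parent OLS around $1.33$, the conventional
MR around $1.99$ ($\approx 1 + r_g$), and the within-family estimator within
Monte-Carlo error of 1 — the directional content of the assortment
simulation, which the acceptance suite asserts.

## Problem sizes and numerical choices

Test-suite simulations run at desk scale, chosen as the smallest sizes at
which the Monte-Carlo bands are informative: 40,000 trios for the
transmission-coefficient check (1,000 SNPs), 200 replicates of $n = 4{,}000$
for the bias contrast, 30-50 SNPs and 50-200 replicates for estimator
calibration. The acceptance script uses 40,000 trios throughout, including
200 replicates of the $\phi = 0.9$ single-SNP study. Degenerate inputs are
handled explicitly: empty cohorts simulate without error; monomorphic
variants are dropped (with a warning) from per-SNP fits and carry zero LD
information; constant scores standardize to zero rather than NaN; a
noiseless first stage reports a capped conditional F of $10^{15}$ with
partial $r^2$ of 1; clumping p-value ties break lexicographically.

## Known limitations

* Standard errors are CR0-cluster-robust; with one child per family this is
  HC0-like, and no small-cluster refinement (CR2, wild bootstrap) is
  provided.
* No weak-instrument-robust inference (Anderson-Rubin), no more than two
  exposures, no sibling or three-generation designs.
* The summary-MR module assumes harmonized, approximately independent
  instruments; correlated-instrument corrections are the user's
  responsibility via the conservative clumping regime.
* Multiple imputation is out of scope: all estimators are complete-case and
  the design constructor rejects incomplete rows.
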