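---
title: "Partitioning trait variance between genome-wide DNA methylation and genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning trait variance between genome-wide DNA methylation and genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnamvar)
```

## The question

Adult height is strongly heritable, and methylome-wide association scans
have found little signal for it, so blood DNA methylation (DNAm) has often
been treated as irrelevant to the trait. Whole-genome methods ask a
different question: not whether any single CpG probe passes a significance
threshold, but what fraction of phenotypic variance the *entire* methylome
tracks — marginally, and conditional on common genetic variation fitted
alongside it. `dnamvar` implements that analysis end to end: a Bayesian
mixture model over all probes and SNPs jointly, a REML counterpart on
relationship matrices as a sensitivity check, out-of-sample profile
scoring, and a PheWAS stage, together with a synthetic-cohort generator so
the whole pipeline can be exercised against known truth.

## The model

Let $y$ be the trait, residualized on age, age squared and sex, and let
$W$ ($n \times p_m$) and $Z$ ($n \times p_g$) be column-standardized
probe and SNP matrices (probes are residualized on technical covariates —
batch, slide, cell proportions, smoking score — before standardization).
The joint model is

$$ y = W\beta_m + Z\beta_g + e, \qquad e \sim N(0, \sigma^2_e I). $$

Each marker effect is drawn from a spike at zero or one of three normal
components whose variances are fixed fractions of the phenotypic variance:
$10^{-4}$, $10^{-3}$ and $10^{-2}$ — classes of markers that individually
capture 0.01%, 0.1% and 1% of trait variance ("small", "medium", "large").
Mixture proportions per marker set carry a symmetric Dirichlet prior
(concentration 1, spike included), and $\sigma^2_e$ a scaled inverse
chi-square prior (df 4, scale $0.5\,\mathrm{Var}(y)$).

`fit_bayesr()` samples this posterior by single-site Gibbs: each sweep
visits every marker in a fresh random order, computes the marginal
likelihood of the residual under each mixture component, samples the
component indicator and then the effect from its conjugate normal;
mixture proportions and the residual variance are refreshed from their
conjugate posteriors. Effect-variance classes are parameterized as fixed
fractions of phenotypic variance rather than relative to a sampled set
variance, which keeps class membership directly interpretable as "this
marker captures about x% of trait variance".

Per retained draw the realized linear predictors $g_s = Z_s\beta_s$ are
formed and each set's variance share recorded as
$\mathrm{cov}(g_s, g_{tot}) / (\mathrm{Var}(g_{tot}) + \sigma^2_e)$,
with the residual share $\sigma^2_e$ over the same denominator. The
covariance allocation splits any between-set covariance (real data has it
through mQTLs) so the shares sum to one within every draw; for
uncorrelated sets it reduces to $\mathrm{Var}(g_s)$ over the total.
Computing shares from realized predictors rather than $\sum\beta^2$ makes
them robust to residual correlation among markers. Credible intervals are
equal-tailed percentiles of the retained draws. A marker's posterior
inclusion probability (PIP) is the fraction of retained draws in which it
sits outside the spike; the discovery rule used throughout is PIP > 95%.

Default chain settings are 10,000 sweeps, 5,000 burn-in, thinning 5, two
chains. The studies in the test-suite use shorter, validated settings
(stated below) so they complete quickly on one core.

## REML sensitivity analysis

`fit_reml()` fits the infinitesimal-model counterpart: with $K_m = WW'/p_m$
(the omics relationship matrix, ORM) and $K_g$ the allele-frequency
standardized GRM,

$$ y \sim N(Xb,\; \sigma^2_m K_m + \sigma^2_g K_g + \sigma^2_e I) $$

maximized by average-information REML with EM fallback whenever an AI step
proposes a negative component, components clamped at a small positive
floor and flagged as boundary rather than silently truncated. Standard
errors come from the inverse AI matrix, mapped to the fraction scale by
the delta method; confidence intervals are $\pm 1.96\,\mathrm{SE}$.
Internal correctness is anchored by two oracles in the test-suite: a
restricted-likelihood grid search after eigen-rotation (agreement to the
0.01 grid), and the exact invariance of REML under eigen-rotation of the
data. A relationship matrix numerically proportional to the identity is
rejected up front — its component is not separable from the residual.

`fit_bivariate_sex()` treats the trait in the two sexes as two traits on
disjoint individuals, with cross-group covariance
$r\,\sigma_1\sigma_2 K_{12}$. The correlation is optimized on the atanh
scale (capped at $|r| \le 0.99$: beyond that the surface is flat in the
transformed parameter and the delta-method SE degenerates), with
multi-start over $r_0 \in \{0, \pm 0.5\}$ because the restricted
likelihood can be multimodal when a group variance is small. The test of
$r = 1$ is a likelihood-ratio test against the boundary, so the p-value
uses the half-$\chi^2_1$ mixture.

## What the generator emulates

`simulate_cohort()` produces cohorts with the statistical structure this
analysis assumes:

* genotypes are binomial(2, MAF) dosages, MAF uniform on (0.05, 0.5);
* methylation is built additively on the logit scale and mapped through
  the logistic function — beta values stay in [0, 1] while remaining
  near-linear in the bulk. Each probe has a uniform baseline
  (logit 0.15–0.85), a latent SD of 0.5, batch effects (SD 0.1), a
  loading on the first cell-proportion component (SD 0.2), and, for a
  configurable fraction of probes, one cis-driver SNP explaining
  `mqtl_r2` of the latent variance;
* marker effects are drawn from the {null, small, medium, large} classes
  with variance ratio 1:10:100, matching the estimator's component
  classes so class-recovery checks are interpretable. Probe effects act
  on **covariate-adjusted** standardized probes: the trait-relevant probe
  signal is by construction the part not driven by batch, cell
  composition or smoking, matching the convention that probes are
  adjusted before analysis. The realized linear predictors are rescaled
  so the probe and SNP contributions carry exactly their target variance
  fractions, and the residual is drawn orthogonal to them with exact
  complementary variance — so the generative fractions are pinned, with
  residual seed-to-seed variation coming only from intended covariance
  (e.g., mQTL coupling);
* height in cm adds an intercept of 162, a male–female gap of 14 cm (the
  gap in large adult cohorts), a small linear age slope (−0.05 cm/year)
  and a cm scale of 6.7 for the unit-variance signal (the within-sex SD
  of adult height);
* the polygenic-score column is a noisy proxy (about 70% of variance) of
  the **total** additive-genetic value — direct SNP effects plus the
  mQTL-mediated genetic component of the probe signal — because a PGS
  trained on a trait GWAS captures genetic influence regardless of
  whether methylation mediates it.

One RNG stream keyed by `seed` drives everything, with a documented draw
order, so cohorts are bit-reproducible.

What the generator does *not* emulate: genomic correlation structure (LD
blocks, probe co-methylation regions), non-Gaussian residuals, missing
data, family structure, age-varying effects, or array-level artifacts
beyond additive batch/slide shifts. Passing tests therefore demonstrate
the estimators' correctness and calibration under the model's own
assumptions, not robustness to every pathology of real cohort data.

## Study conditions used by the test-suite

Problem sizes are chosen so each study is informative yet runs in minutes
on one core:

* *Parameter recovery*: truth (DNAm 0.25, SNP 0.55, residual 0.20),
  n = 2000, 2000 probes, 3000 SNPs, 10 replicates; chains of 1500 sweeps
  (500 burn-in, thin 2). Posterior means land within ±0.05 of truth and
  at least 18 of the 20 set-level 95% credible intervals cover it.
* *Null calibration*: n = 2000, 500 probes, phenotype independent of the
  methylome, two chains of 800 sweeps; the posterior-mean DNAm fraction
  stays at or below 0.05 across 10 seeds. At much smaller n (a few
  hundred) the sampler visibly absorbs noise into the small-effect class
  — a known small-sample property of spike-plus-mixture models worth
  keeping in mind when reading single-cohort fits.
* *Discovery*: five probes planted with equal effects totalling 15% of
  variance (3% each), n = 3000; all five exceed PIP 0.95 in ≥ 9/10 seeds.
* *Cross-sex decomposition*: n = 600, DNAm fraction 0.5 with a dense
  class mix, shared (r = 1) and independent (r = 0) architectures each
  recovered within 2 SE in ≥ 8/10 seeds.
* *Method concordance*: the Bayesian and REML joint fits agree within
  0.06 on both set fractions on a dense-architecture cohort (n = 1200).
* *Attenuation direction*: with strong probe–genotype coupling
  (60–80% of probes driven at $r^2 = 0.5$), the joint DNAm fraction sits
  below the marginal one on average, and conditioning the phenotype on
  the polygenic score attenuates — but does not zero — the marginal DNAm
  fraction, since the planted independent probe effects survive.

The acceptance script (`scripts/acceptance.R`) runs the whole pipeline —
marginal, joint and PGS-adjusted Bayesian fits, joint REML, the cross-sex
decomposition, train/test profile scoring and the PheWAS stage — on a
1500-individual cohort (1000 train, 500 test; 1000 probes, 1500 SNPs)
with strong probe–genotype coupling (`mqtl_frac = 0.6`, `mqtl_r2 = 0.5`).
That coupling level is a deliberate generative choice: it reproduces the
qualitative behaviour of cohort data in which a genome-wide polygenic
score removes an appreciable part of the methylation-associated signal,
so the marginal → joint and marginal → PGS-adjusted comparisons both show
attenuation rather than the mechanical rise a fully independent methylome
would produce (removing genetic variance shrinks the denominator of every
fraction).

## Numerical and design choices

* Probes are residualized on covariates first, then standardized; the
  sampler rejects matrices whose columns deviate from unit variance by
  more than $10^{-3}$ rather than silently restandardizing.
* The trait is standardized internally; reported fractions are invariant
  to this and posterior-mean effects are returned on the input scale.
* Marker update order is a fresh random permutation per sweep; all
  randomness flows from R's RNG, so `set.seed()` (or the `seed` fields of
  `mcmc_spec()` / `sim_config()`) makes any run reproducible.
* `fix_resid_var` and `fix_pi` hold the residual variance and mixture
  proportions fixed; the closed-form single-marker posterior then becomes
  an exact oracle for the sampler, which the test-suite uses as the
  gating correctness check.
* The greedy unrelatedness filter removes, while any pair exceeds the
  threshold, the individual in the most offending pairs; on ties the
  lower-indexed individual is kept. At desk-scale marker counts the null
  off-diagonal of a relationship matrix has SD $1/\sqrt{p}$, so the
  pipeline's default cutoff (0.3) sits above that noise; with hundreds of
  thousands of markers the conventional 0.05 is appropriate.
* Profile scores are rescaled to cm by z-scoring in the target sample and
  re-anchoring to the training phenotype mean/SD ("train" anchors;
  "target" anchors are available by flag). Only the affine class matters
  for correlations and $R^2$.
* The decile contrast uses stable quantile ranks (ties broken by index)
  and a Welch t-test.
* Zero-variance marker columns are dropped with a warning, never imputed;
  core fits reject missing data outright.

## Limitations

The mixture model's smallest effect class (0.01% of variance) is nearly
indistinguishable from the spike at desk-scale n, so "inclusion" counts
in that class are diffuse and the architecture table is best read
alongside the per-class variance shares. Variance-fraction estimates for
the methylome inherit any unmodelled confounding that survives the
covariate residualization. The bivariate cross-sex correlation is weakly
identified when either group's variance fraction is small; its SE should
be taken seriously. And all calibration statements above are statements
about data generated under the model's assumptions — real-cohort behaviour
additionally depends on LD, co-methylation and confounder structure the
generator does not attempt to reproduce.
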