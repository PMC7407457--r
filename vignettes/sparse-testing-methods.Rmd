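---
title: "Models and methods behind sparsemet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sparsemet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sparsemet)
```

`sparsemet` studies how to allocate a fixed plot budget across
environments in a sparse multi-environment trial, and how much of the
unobserved genotype-by-environment factorial can be recovered by
genomic prediction. This vignette documents the statistical models, the
synthetic-data generator, the numerical choices, and the limits of what
the package's own simulations can demonstrate.

## The two-stage analysis

**Stage 1 — phenotypic adjustment.** Plot records within one
environment follow

$$y_{jkl} = \mu + L_j + r_k + d_{l(k)} + e_{jkl},$$

with the genotype effect $L_j$ fixed, the replicate effect
$r_k \sim N(0, \sigma^2_r)$, the incomplete-block-within-replicate
effect $d_{l(k)} \sim N(0, \sigma^2_{l(r)})$ and plot error
$e_{jkl} \sim N(0, \sigma^2_e)$. `estimate_stage1_varcomps()` obtains
the three variance components by REML (via `lme4`); `compute_blues()`
then solves the generalized-least-squares equations at those estimates,
in cell-means coding, so the reported BLUE is $\hat\mu + \hat L_j$ on
the trait scale. Environments are adjusted strictly one at a time: the
stage-2 models, not stage 1, are responsible for sharing information
across environments. Two conventions are deliberate:

* *Cell-means coding* is numerically identical to an intercept plus
  sum-to-zero genotype contrasts and frees the result from any
  reference-level choice.
* Structurally inestimable terms (one replicate; one block per
  replicate) are fixed at zero with a message rather than being dropped
  silently; boundary (zero) REML estimates are accepted.

**Stage 2 — genomic prediction.** Per-environment BLUEs $y_{ij}$ enter
one of three nested random-effects models: M1 with environment and iid
line main effects, M2 adding the genomic value
$g \sim N(0, \mathbf{G}\sigma^2_g)$, and M3 adding the interaction
$gE \sim N(0, (\mathbf{Z}_g\mathbf{G}\mathbf{Z}_g')\circ
(\mathbf{Z}_E\mathbf{Z}_E')\,\sigma^2_{gE})$, the Hadamard product of
the genomic and environment cell kernels. Keeping both $L$ and $g$ in
M2/M3 guards against imperfect marker information: $L$ absorbs genetic
signal the markers miss. A consequence worth stating explicitly:
genotypes never observed anywhere receive no contribution from the iid
$L$ kernel — information reaches them only through $\mathbf{G}$ (and
its interaction kernel), which is exactly why marker data make sparse
designs with fully untested genotypes usable at all.

## The genomic relationship matrix

`qc_filter()` drops markers with more than 50% missing calls or a minor
allele frequency below 3% (both strict inequalities, so a marker
sitting exactly on a threshold is kept; monomorphic and constant
markers are always dropped). `impute_and_standardize()` replaces
missing dosages with the marker mean and standardizes columns with the
*population* (divisor-$n$) standard deviation; `compute_grm()` forms
$\mathbf{G} = \mathbf{XX}'/p$ (VanRaden method 1). Divisor-$n$ scaling
makes $\mathrm{mean}(\mathrm{diag}(\mathbf{G})) = 1$ and
$\mathrm{trace}(\mathbf{G}) = n$ exactly, which the tests assert to
$10^{-9}$; the divisor is configurable for users who prefer the sample
convention. Mean imputation and the divisor choice are package
decisions — reasonable defaults where practice varies — and are
documented rather than hidden.

## Allocation designs

`make_design()` samples the overlapping set first (uniformly without
replacement), then the per-environment non-overlapping sets from the
remainder, pairwise disjoint. The construction guarantees, for every
seed: calibration and prediction cells partition the factorial; the
calibration budget is exactly $n_\mathrm{envs}(NO + O)$; and the
canonical counts — e.g. an 843-genotype, 3-environment trial at 281/0
yields 843 calibration cells and 562 prediction genotypes per
environment, and at 241/40 leaves 723 genotypes observed once and 80
unobserved — hold identically. `enumerate_grid()` walks a sample size
$s$ from $s/0$ down to $1/(s-1)$ in overlap steps of 10 (configurable);
the all-overlap $0/s$ design is constructible directly but not part of
the default grid, mirroring the usual tabulation that stops at $NO=1$.
Repetition $r$ of a cross-validation uses seed $\texttt{base\_seed}+r$,
a simple reproducible convention for "independent random partitions".

## The Gibbs sampler

All three models are Gaussian kernel regressions, fitted by a blocked
Gibbs sampler written for this package:

* Each effect is represented in the eigenbasis of its kernel restricted
  to the calibration cells, $K[\mathrm{tr},\mathrm{tr}] = VDV'$. Because
  $V$ is orthonormal, the full conditional of the coefficient vector is
  *diagonal*: one kernel update costs two matrix-vector products, and
  the eigendecomposition is done once per design.
* Variance components get scaled-inverse-$\chi^2$ updates with prior
  degrees of freedom 5; prior scales are set so the prior modes split
  `prior_R2 = 0.5` of the phenotypic variance equally among the
  non-residual kernels, the remainder going to the residual. These are
  the conventional weakly-informative defaults of Bayesian
  kernel-regression software; both knobs are exposed in
  `gibbs_config()`.
* The intercept has a flat prior. Chain defaults are 12,000 iterations,
  2,000 burn-in, thinning 5.
* Prediction of a masked cell uses the joint-kernel conditional mean
  $K[\mathrm{te},\mathrm{tr}]\,V D^{-1} b$, averaged over kept draws, so
  the reported value is the posterior mean of $\mu + \sum_k u_k$.

Numerical choices: kernels get eigenvalues clipped at zero (maximum
clip magnitude reported in the diagnostics) and components below
$10^{-8}$ of the largest eigenvalue are dropped; the relationship
matrix receives a $10^{-8}$ diagonal jitter before Cholesky in the
generator, and a failure after jitter is raised as an error rather than
silently repaired. Monte Carlo standard errors of predictions use
**batch means** (up to 25 batches over the kept draws), which stays
honest under autocorrelation where the naive $s/\sqrt{n}$ formula is
optimistic. Effective sample sizes per variance component use the
initial-positive-sequence estimator; a fit warns when any ESS falls
below 10. With the variance updates disabled (`fix_varcomps`), the
sampler's posterior-mean predictions coincide with closed-form
Henderson-equation BLUP, which the tests verify against an
independently assembled dense solve.

## The synthetic-data generator

`simulate_markers()` draws, per marker, an allele frequency uniform on
`maf_range` and independent $\mathrm{Binomial}(2, f_m)$ dosages — a
linkage-free panel. `simulate_phenotypes()` then draws the cell-level
model exactly as stage 2 assumes it, with the interaction generated per
environment as an independent $N(0, \mathbf{G}\sigma^2_{gE})$ vector —
equivalent to the Hadamard-kernel covariance when each
genotype-environment pair has one cell. `simulate_plot_trial()` expands
cells into replicates and randomly partitioned near-equal incomplete
blocks, re-randomized per replicate; no field-layout geometry is
modelled because only the stage-1 model structure matters downstream.
Plot-level default variances (replicate 0.05, block 0.05, plot 0.2) are
package choices at magnitudes typical for well-run yield trials —
small relative to the cell-level signal — since trial reports rarely
print them.

Default shape: 300 genotypes, 2,000 markers, 3 environments — a
desk-scale mirror of a large maize hybrid trial. The default variance
components (`var_E = 0.2`, `var_L = 0.03`, `var_g = 0.17`,
`var_gE = 0.5`, `var_e = 0.55`) put the expected between-environment
correlation of cell values,
$(\sigma^2_L+\sigma^2_g)/(\sigma^2_L+\sigma^2_g+\sigma^2_{gE}+\sigma^2_e)
= 0.16$, inside the low-to-moderate band (about 0.07–0.37) reported
between stress and optimal sites in large maize hybrid programs, with
GE and residual terms dominating. This ratio matters scientifically:
it is the strength of the cross-environment "transfer" route for a
genotype tested elsewhere, and it competes with the genomic
"borrowing" route that serves untested genotypes. Designs with more
overlap win only when borrowing is competitive with transfer.

**What the generator does not emulate — and what that limits.** Real
breeding panels carry linkage disequilibrium and family structure, so
their relationship matrices have strong off-diagonal signal. A
linkage-free panel with $p \gg n$ yields $\mathbf{G}$ close to the
identity (off-diagonals of order $1/\sqrt{p}$), which has two
consequences:

1. *Weak identifiability of the variance split.* On an all-NO design
   each genotype is observed once, so the iid line and residual
   variances are confounded exactly, and the genomic components are
   identified only through those small off-diagonals. Posterior means
   then shrink materially toward the prior; a maximum-likelihood fit on
   the same data misallocates in the same way, so this is an
   information limit of the simulated design, not a sampler artifact.
   Recovery of the *sum* of confounded components and of the
   interaction variance is much better behaved.
2. *A finely balanced overlap trend.* Because genomic borrowing is
   weak, the accuracy-vs-overlap trend on a single simulated dataset
   depends on the realized between-environment correlation and can
   invert run to run; averaged over repetitions at the default
   settings the genome-enabled models do not lose accuracy as overlap
   grows, and the GE model is consistently the most accurate and
   leaves the least residual variance. Passing tests therefore
   demonstrate internal consistency and the direction of effects, not
   the effect sizes one would obtain with a structured real panel.

## Evaluation conventions

`pearson_by_env()` scores prediction cells within one environment;
undefined correlations (fewer than three scorable cells, or zero
variance on either side) propagate as `NA` with a warning — coercing
them to zero would bias grid summaries. `summarize_cv()` averages
first across environments within a repetition, then across
repetitions, and reports the standard deviation over repetitions only;
this matches the common "average across environments over random
partitions" presentation, and the alternative pooled-cell correlation
is intentionally not offered. Each model fit inside `run_cv()` runs on
its own derived RNG stream, so a failed (and skipped) fit cannot shift
the draws of later fits.

## Problem sizes used by the test suite and acceptance script

The shipped checks are sized for a single desk CPU: the
Henderson-equivalence check uses 20 genotypes in 2 environments with
12,000 iterations; variance recovery uses five 300-genotype
simulations with 6,000-iteration chains; the model-comparison
cross-validation uses a 3-design grid at 100 plots per environment,
three models, three repetitions and 1,500-iteration chains. These are
the package's own choices of demonstration scale; all of them are
configuration, and larger studies simply pass larger values to
`sim_config()`, `gibbs_config()` and `run_cv()`.

## Known limitations

* No linkage disequilibrium, pedigree, or family structure in the
  marker generator; see above for the consequences.
* Stage 1 fits no spatial (row-column) adjustment — the adjustment
  model is replicate plus incomplete block only.
* Only VanRaden method-1 relationships; no dominance or epistatic
  kernels, no factor-analytic environment covariance, no environmental
  covariates.
* Equal per-environment sample sizes; cost-weighted budgets are out of
  scope.
* Variance components are re-estimated within every repetition of a
  cross-validation, which is the defensible default but makes grids of
  many designs computationally heavier than a fixed-variance sweep.
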