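---
title: "Simulating the response to genomic selection in multi-environment trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the response to genomic selection in multi-environment trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package answers

Predictive accuracy -- the cross-validated correlation between observed and
predicted genomic breeding values (GBVs) -- does not tell a breeder how many
entries to keep. The operational question is different: *if I select the top
`n` of my `N` candidates on their GBLUPs, what is the probability that the
`m` truly best candidates are among them?* `selresp` estimates exactly this
probability by simulating from the joint distribution of true breeding
values `g` and their predictions `ghat` implied by the fitted mixed model.

Under the GBLUP model both vectors are jointly multivariate normal with
mean zero and covariance

$$\Omega = \begin{bmatrix} D & M \\ M & M \end{bmatrix}, \qquad
D = K\sigma^2_g, \quad M = \mathrm{var}(\hat g) = D - C,$$

where `K` is the VanRaden genomic relationship matrix and
`C = var(ghat - g)` is the prediction error variance (PEV) matrix, read off
the genetic block of the inverse coefficient matrix of Henderson's mixed
model equations. Given a factor `Gamma` with `Gamma Gamma' = Omega`, draws
are `w = Gamma z` with standard-normal `z`; the first `N` elements of `w`
are a realization of `g`, the last `N` of `ghat`. For each of `S` draws the
top-`n` set by `ghat` is compared with the top-`m` set by `g`; the
probability estimate is the fraction of draws in which the latter is
contained in the former. Because the success event for a draw is "the
worst `ghat`-rank among the `m` truly best is at most `n`", a single pass
records, per draw, that worst rank, and the whole probability curve over
`n` follows from its empirical distribution function. Pearson correlations
of values and of ranks are accumulated per draw and averaged (a pooled
variant over all draws is also reported, since averaging per replicate and
pooling answer slightly different questions; both are exposed).

## Why a single-year analysis overstates response

A trial network observes each candidate cohort of the first testcross
stage (GCA1) in a single year. A single-year fit cannot separate the GBV
main effect from its GBV-by-year interaction: the genomic variance it
estimates is the *apparent* variance
$\sigma^2_{\tilde g} = \sigma^2_g + \sigma^2_{gy}$, and a simulation based
on it overstates the response to selection, because only the main effect
carries over to future years. The package's remedy, following the
current-year workflow it implements:

1. estimate the long-term ratio
   $\rho = \sigma^2_g / (\sigma^2_g + \sigma^2_{gy})$ from multi-year
   data -- either several years of first-stage trials (`MY` assembly) or
   all stages of all selection cycles combined (`CYC` assembly);
2. fit the current year alone to get $\hat\sigma^2_{\tilde g}$;
3. split it as $\sigma^2_g = \rho\,\hat\sigma^2_{\tilde g}$ and
   $\sigma^2_{gy} = (1-\rho)\,\hat\sigma^2_{\tilde g}$ (the split is exact
   by construction);
4. re-solve the current-year model *once*, with two kinship-structured
   random terms sharing the entry incidence matrix and all variances held
   fixed at the prespecified values. The PEV matrix of this rerun feeds
   the simulation.

Because the two terms share their incidence matrix and their covariances
are proportional (`rho K` and `(1-rho) K` times the same scalar), the
rerun's GBV BLUPs equal exactly `rho` times the apparent BLUPs; the test
suite asserts this identity at `1e-8`. The value of the rerun is not in
the point predictions but in the increased shrinkage and the PEV matrix
`C` that enters `Omega`.

For the second trial stage (GCA2) the package instead restricts a cycle to
the entries common to its first two stages and fits a two-year single-stage
model in which all design nuisance factors are nested within years with
year-specific variances, so that $\sigma^2_g$ and $\sigma^2_{gy}$ are
separated directly.

## The mixed-model engine

`reml_fit()` implements average-information (AI) REML on Henderson's mixed
model equations with

* arbitrary crossed/nested iid random factors;
* `gbv(entry)` terms with covariance $K\sigma^2_g$;
* `gbv_by(entry, year)` terms, block-diagonal over years with blocks
  $K_j \sigma^2_{gy}$, where $K_j$ is the kinship submatrix of the entries
  observed in year `j`;
* `at(factor, year)` terms with a separate variance per year;
* residuals that are homogeneous, heterogeneous by group (location or
  year-location), or fully fixed at known diagonal weights (the
  Smith-weight case of the two-stage analysis).

Numerical choices, all of which matter in practice:

* **Kinship factorization.** A VanRaden matrix built from centred markers
  is always singular (rows sum to zero), so `G^{-1}` does not exist.
  Genomic terms are reparameterized through a factor `L` with `LL' = K`
  (Cholesky if possible, otherwise an eigendecomposition with eigenvalues
  below `1e-8` of the largest clipped to zero). The marginal model is
  unchanged; BLUPs and the PEV block are mapped back through `L`.
* **Optimization.** AI steps with step halving and an EM fallback (EM
  never decreases the restricted likelihood); the first iteration is an
  EM step for stability, and a trust-region amplification accelerates the
  otherwise-geometric crawl along near-flat variance ridges (for example
  entry-by-location within year trading off against GBV-by-year on small
  two-year data). Convergence requires the log-likelihood change below
  `1e-6` together with a largest relative parameter change below `1e-3`
  (or a sustained sub-`1e-6` plateau); the scaled score is recorded in the
  iteration trace but does not gate stopping, because at a zero boundary
  it tends to a non-zero constant and could never pass.
* **Boundaries.** REML estimates are constrained non-negative. A
  component heading below `1e-6` times the response variance with a
  negative score is pinned at the bound, removed from the AI system
  (re-entering if its score turns positive), reported as `0`, flagged
  `boundary`, and given no standard error. Asymptotic correlations
  involving such a component are reported as 0 with a flag.
* **Aliased fixed effects** are dropped deterministically (the earliest
  full-rank column subset is kept) and listed in the fit object.
* **Two-stage weighting.** Stage 1 fits each year at plot level with
  *fixed* entry effects -- the adjusted means are GLS estimates (EBLUEs),
  avoiding double shrinkage -- and location-specific residual variances.
  Stage 2 fixes its residual at the Smith weights; the default takes the
  diagonal of the inverse of the EBLUE covariance matrix, the
  `diag_inverse` variant (inverse of the diagonal) is available since the
  literature uses both.
* **`Omega` factorization** tries Cholesky first and falls back to an
  eigendecomposition; `Omega` is singular by construction whenever
  `C = 0`. Eigenvalues in `[-1e-8 * lambda_max, 0)` are clipped to zero;
  anything more negative indicates an invalid PEV matrix and is an error.
* **Ties** in the simulated rankings occur with probability zero; the
  deterministic index-order tie-break only pins down reproducibility.

## What the synthetic generator emulates

The generator (`sim_config()`, `sim_met()`, `sim_breeding_program()`)
reproduces the statistical structure the models assume: testcross entries
evaluated with 2 testers at 3 locations, 2 trials per location (entries
split into trial series), 2 replicates subdivided into incomplete blocks
of about 15 plots, nuisance effects (location, tester, entry-by-tester,
entry-by-location, trial, replicate, block) drawn independently per year,
kinship-structured GBVs (`u_g = Q_c v` with iid marker effects, so
`var(u_g) = K sigma2_g` exactly under the VanRaden scaling),
kinship-structured GBV-by-year deviations per year, location-specific
residual standard deviations, optional sparse testing (a random entry
subset per location) and truncation selection between cycle stages (on
true GBV by default, so that truth stays controlled in tests).

Default variances are chosen once at magnitudes typical of hybrid rye
yield trials (dt/ha): mean 100, year 20, location 10, tester 1, GBV 2,
GBV-by-year 1.4, entry-by-tester 0.3, entry-by-location 0.5, trial 2,
replicate 1, block 1, residuals 8/10/12 by location. The implied
generating ratio `rho = 2/3.4 = 0.588` sits in the middle of the range
reported for real programs.

Two deliberate simplifications, and what they mean for test evidence:

* **Unrelated entries.** Marker genotypes are drawn independently per
  entry, so kinship is near-identity and cohorts from different cycles
  are essentially unrelated. Real programs have family structure. One
  consequence is embraced rather than hidden: with *disjoint* yearly
  cohorts and no relatedness, `rho` is not identifiable from a
  multi-year assembly -- exactly why parameter-recovery conditions use a
  common-entry panel (the same `N` entries in all years). Passing tests
  therefore show the estimators work when the data carry the information,
  not that four years of unrelated cohorts would identify `rho` in the
  wild.
* **Random incomplete blocks.** Entries are assigned to equal-sized
  blocks at random rather than by an alpha-array; since block effects are
  iid random in both the generator and the models, design optimality
  affects efficiency, not correctness.

## Problem sizes used by the checks

The packaged checks run the recovery study at `N = 300` entries over 4
years with 20 replicates (about 3,600 plots per year), the
replicate-data identity `var(ghat) = D - C` at `N = 30` with 10,000
simulated datasets, the closed-form orthant check at `S = 1e6` draws, and
the end-to-end acceptance run at `N = 150` with `S = 50,000`. These sizes
were chosen so the full evidence base recomputes in well under an hour on
one core; all of them scale up linearly in `S` and roughly cubically in
the mixed-model dimension.

## Known limitations

* Variance estimation is the Achilles' heel: with few years,
  `sigma2_gy` (and the year variance itself) is estimated with large
  error or at the zero boundary, and `rho` inherits that uncertainty.
  The delta-method SE reported for `rho` is asymptotic.
* The engine targets desk-scale problems (mixed-model dimension up to a
  few thousand); it uses dense factorizations once kinship terms enter
  and makes no attempt at sparse-inverse machinery beyond that.
* Spatial residual models, factor-analytic genotype-by-environment
  structures, dominance and epistasis are out of scope.
* A Bayesian treatment of the variance components (priors instead of a
  fixed long-term `rho`) is a natural extension and is not implemented.

## A worked example

```{r, eval = FALSE}
library(selresp)

cfg <- sim_config(n_entries = 150, n_years = 5, seed = 42)
sm  <- sim_met(cfg)                       # markers, truth, plot table

res <- run_gca1_assessment(sm$plots, sm$truth$K, mode = "MY",
                           S = 50000, seed = 42)
res$stage2                                # rho and its SE
res$refit$adjustment                      # exact variance split
plot(res$sim)                             # probability curves, one per m
```
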