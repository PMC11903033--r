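---
title: "Functional linear mixed models for trial-aligned signals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional linear mixed models for trial-aligned signals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funflmm)
```

## The problem

Trial-based recordings such as fiber photometry produce one signal curve per
trial, sampled on a common within-trial time grid, nested inside sessions and
subjects. The routine analysis collapses each curve to a scalar summary (an
"AUC" over a window) and tests that summary, which discards the temporal
information and can average away effects whose sign or timing varies within
the window. `funflmm` instead models the signal value at *every* trial
time-point with a linear mixed model, treats the resulting coefficient
sequences as functions of trial time, and reports each covariate's effect as
a smooth curve with pointwise and simultaneous (joint) 95% confidence bands.

## Model

For subject $i$, trial $j$ and trial time-point $s \in \{1, \dots, S\}$,

$$
E\left[Y_{ij}(s) \mid X_{ij}, Z_{ij}, \gamma_i(s)\right]
 = X_{ij}^\top \beta(s) + Z_{ij}^\top \gamma_i(s),
$$

where $\beta(s)$ is the $p$-vector of functional fixed effects shared across
subjects, and $\gamma_i(s)$ the functional random effects (subject- or
session-specific deviation curves), $\gamma_i(s) \sim N(0, G(s))$,
independent of the trial-level error. Nested designs are expressed through
the familiar mixed-model formula grammar, e.g.
`photometry ~ IRI + (lick_latency | id/session)`, which expands the `id/session`
grouping into a subject block and a subject-by-session block.

Estimation is massively univariate ("fast univariate inference"):

1. **Pointwise fits.** At each $s$, a Gaussian LMM is fit to $Y(s)$ by REML
   (via lme4). This yields $\hat\beta(s)$, variance components
   $\hat G(s), \hat\sigma^2(s)$, BLUPs and Wald covariances. Fits are
   independent across $s$; the implementation shares one model structure and
   warm-starts the optimizer along the grid purely for speed, always keeping
   the better of the warm-started and default-started solutions because warm
   starts near a variance boundary can stall the optimizer.
2. **Smoothing.** Each raw coefficient sequence $\hat\beta_k(\cdot)$ is
   smoothed with a penalized cubic B-spline: $\tilde\beta_k = H_k
   \hat\beta_k$ with $H_k = B(B^\top B + \lambda_k P)^{-1}B^\top$.
3. **Covariance assembly.** The cross-time covariance
   $\mathrm{Cov}(\hat\beta(s_1), \hat\beta(s_2))$ is assembled analytically
   from the GLS coefficient maps and a method-of-moments estimate of the
   cross-time covariance of the random effects, then propagated through the
   smoother: $\mathrm{Cov}(\tilde\beta_k) = H_k \,\mathrm{Cov}(\hat\beta_k)\,
   H_k^\top$.
4. **Bands.** The pointwise band is $\tilde\beta_k(s) \pm 1.96\,
   \mathrm{se}_k(s)$. The joint band replaces 1.96 with the 95% quantile
   $q_k$ of $\max_s |\xi(s)|$, $\xi \sim N(0, C_k)$ with $C_k$ the estimated
   correlation of $\tilde\beta_k(\cdot)$, drawn by Monte Carlo (10,000 draws,
   fixed seed). $q_k$ is floored at $z_{0.975}$ so the joint band never falls
   inside the pointwise band.

## Smoothing: basis, penalty and $\lambda$ selection

* **Basis.** Cubic B-splines with equally spaced interior knots on the index
  grid, $K = \min(\lceil S/2 \rceil, 35)$ (floored at 4). The saturated case
  $K = S$ is reachable through `flmm_control(basis_size = )`.
* **Penalty.** A second-order difference penalty on the basis coefficients,
  formed from second *divided* differences at the Greville abscissae. With
  clamped knots the Greville sites are unequally spaced near the boundary, and
  the divided-difference form is what makes the penalty null space exactly
  the constant and linear functions, so $H_k \mathbf{1} = \mathbf{1}$ and
  $H_k s = s$ at every $\lambda$.
* **Selection.** One $\lambda_k$ per coefficient, by GCV over a fixed
  100-point log-spaced grid on $[10^{-8}, 10^8]$, with a two-stage parsimony
  rule. If the fully penalized fit (the best straight line) scores within one
  GCV standard error of the minimum — the GCV score's sampling coefficient of
  variation is about $\sqrt{2/n}$ — GCV cannot distinguish the input from its
  linear trend, and the largest grid $\lambda$ is used; pure-noise inputs are
  therefore smoothed to a line. Otherwise the largest $\lambda$ within 1% of
  the minimal score is taken, which leaves genuinely curved inputs essentially
  at the GCV minimizer and keeps smoothing bias small (bias, unlike variance,
  is not reflected in the bands). A `selector = "fixed"` mode bypasses GCV.
* **Non-converged time-points** are excluded from the GCV fit and imputed by
  the smoother prediction; their bands use the same propagated covariance.

## Cross-time covariance and its bias correction

Marginal residuals $e(s) = Y(s) - X\hat\beta(s)$ satisfy, within a subject
and for $s_1 \ne s_2$,

$$
E\left[e(s_1)e(s_2)^\top\right] \approx \sum_b Z_b G_b(s_1,s_2) Z_b^\top
 + r(s_1,s_2) I,
$$

and the blocks $G_b(s_1,s_2)$ together with the scalar trial-level residual
cross-covariance $r(s_1,s_2)$ are estimated by least squares on the
vectorized cross-products. Two details matter in practice:

* **The residual cross-covariance is estimated, not zeroed.** Trial-level
  noise in real recordings is temporally correlated; omitting $r(s_1,s_2)$
  understates $\mathrm{Var}(\tilde\beta)$ after smoothing (in our replicated
  simulations the omission cost roughly 10% of the joint coverage). The
  diagonal $r(s,s)$ is the REML $\hat\sigma^2(s)$, which keeps the assembled
  $\mathrm{Var}(\hat\beta(s))$ identical to the pointwise Wald covariance.
* **Projection bias is removed.** Because $e(s) = (I - XM(s))Y(s)$, the naive
  moment equations are deflated by the fixed-effect estimation terms — an
  $O(1/n_{\text{subjects}})$ effect (about 15% at $n = 7$). The correction
  terms are linear in the unknown covariances, so they are added back by two
  plug-in iterations using per-time-point correction operators; the
  corrected estimates matched the replicate-to-replicate covariance of
  $\hat\beta$ to within a few percent at every lag in our calibration runs.

* **The estimated surfaces are smoothed.** The true cross-covariance
  surfaces are smooth in $(s_1, s_2)$, while their moment estimates carry
  substantial pairwise sampling noise that would propagate into the band
  widths; because band width enters the max statistic in the denominator,
  that noise fattens the tail of $\max_s |z(s)|$ well beyond its Gaussian
  reference (in null simulations it roughly doubled the joint type-I error).
  Each estimated surface is therefore smoothed over the time-pair plane with
  a moderate sandwich smoother (effective df about $S/3$ per axis — enough to
  track the near-diagonal ridge left by temporally correlated trial noise),
  keeping the REML diagonals as estimated. Coefficient functions themselves
  are smoothed only once, as described above.

The assembled per-coefficient $S \times S$ covariance is symmetrized and
eigenvalue-clipped at zero, and the correlation used for the joint critical
value is rescaled to unit diagonal afterwards.

## The synthetic generative model

`simulate_dataset()` draws data from

$$
Y_{ij}(s) = \beta_0(s) + \gamma_{0,i}(s) + x_{ij}\left[\beta_1(s) +
\gamma_{1,i}(s)\right] + \epsilon_{ij}(s),
$$

with $\gamma_{0,i} \sim N(0, K_{\gamma_0})$, $\gamma_{1,i} \sim N(0,
K_{\gamma_1})$ per subject, and $\epsilon_{ij} \sim N(0, c \cdot s_i \cdot
K_\epsilon)$ independently across trials and subjects. Defaults
(`default_truth()`), chosen once to emulate a delay-lengthening photometry
experiment sampled at 15 Hz:

* $\beta_0$: a fast-rising, slow-decaying transient peaking near 1.5 —
  a cue-response shape.
* $\beta_1$: zero over the first quarter of the trial, a smooth dip to
  $-0.5$ over a mid-trial window (a late relative reduction); the window
  where $\beta_1 \neq 0$ defines the cue period used for scoring.
* $K_{\gamma_0}$: squared-exponential, variance $0.25$ (between-animal
  baseline curves, sd 0.5), length scale 0.5 s.
* $K_{\gamma_1}$: squared-exponential, variance $0.0225$ (slope sd 0.15,
  30% of the effect peak). The regime is deliberately noise-dominated:
  the emulated study inflates its residual covariance fivefold, so trial
  noise, not between-animal slope heterogeneity, carries most of
  $\mathrm{Var}(\hat\beta_1)$; large slope heterogeneity at $n \le 7$
  subjects would put half the variance on a handful of degrees of freedom,
  where Wald-type bands are known to undercover.
* $K_\epsilon$: Ornstein–Uhlenbeck, variance $0.25$, length 0.3 s, scaled by
  `eps_scale = 5`, with a mild lognormal per-subject scale jitter
  (sd 0.15) for between-animal noise heterogeneity. Errors from different
  subjects are independent; a `share_error_kernel_groups` flag restores a
  recycled 7-scale pool for fidelity runs.
* Defaults `n_subjects = 7` and `trials_per_condition = 25` give trial-level
  signal-to-noise that is visibly low on single trials and clear in session
  averages; the integrated random-effect to noise variance ratio is about
  0.21.

What the generator does *not* emulate: raw-photometry preprocessing
(bleaching, ΔF/F computation), irregular or missing within-trial samples,
time-varying covariates, and between-subject error correlation. Passing
simulation tests therefore says nothing about preprocessing artifacts in
real data; it does exercise nested designs, functional random effects and
temporally correlated trial noise.

`simulate_iri_design()` generates the nested session/trial random-reward
design (exponential inter-reward intervals with mean 14 s, gamma lick
latencies, subject- and session-level functional intercepts and lick-latency
slopes) so the nested-formula templates can be exercised end to end,
including type-I-error checks with a null covariate.

## Comparators and the benchmark

`perm_test()` implements the within-subject permutation test with the
consecutive-threshold criterion: subject-level condition flips, pointwise
two-sided p-values at resolution $1/(B+1)$, and significant runs of at least
0.5 s ("full") or 0.25 s ("half") of consecutive significance, converted to
samples at the grid rate (8 and 4 samples at 15 Hz). Pointwise intervals for
its coverage rows come from a subject-level cluster bootstrap (percentile,
B = 500). `paired_ttest_auc()` and `lmm_auc()` analyze the cue-period mean
signal per trial, the former after averaging to subject-by-condition means
(df = $n-1$), the latter as a scalar mixed model with Wald (normal)
inference.

`run_benchmark()` scores, per replicate: joint coverage (the joint band
contains the entire true curve), pointwise coverage averaged over cue-period
time-points, and cue-period power (joint band excluding zero somewhere in
the cue period for the functional model; a surviving run intersecting the
cue period for the permutation test; p < 0.05 for the scalar methods).
Power for the functional model deliberately uses the joint band to keep the
comparison familywise-honest. Replicates are seed-streamed, so runs are
reproducible and restartable.

## Numerical choices and degenerate inputs

* Estimation is REML throughout; AIC/BIC are sums of the per-time-point REML
  criteria over converged time-points and are comparable only across models
  fit to the same data and converged set.
* Variance components at the boundary (zero) are accepted, not jittered;
  singular fits count as converged.
* A nested grouping with one inner level per outer level duplicates the outer
  block and is dropped with a warning.
* A rank-deficient fixed design is an error naming the aliased columns.
* Categorical covariates are treatment-coded with the lexicographically first
  level as reference; continuous covariates (more than two distinct values)
  are mean-centered by default so the functional intercept is the mean curve
  at average covariate values; binary indicators are left as coded.
* The time grid is metadata: estimation uses the integer index, and grids
  must be evenly spaced.
* Repeating a fit on identical input is bit-reproducible (the joint critical
  value uses a fixed internal seed and restores the RNG state). Reordering
  trial rows changes floating-point summation order and can move estimates
  at the optimizer's convergence tolerance; a discrete $\lambda$ pick can
  then flip by one grid step.

## Known limitations

* Inference is Wald-type with plug-in variance components. With very few
  subjects and a variance budget dominated by a between-subject component,
  bands undercover — this is the familiar small-$n$ z-versus-t gap, and no
  degrees-of-freedom correction is applied. The default generator avoids that
  regime deliberately; in our replicated runs residual joint undercoverage of
  a few percent remains at $n = 4$, driven by replicates in which the
  REML slope variance lands on the zero boundary.
* The data-driven $\lambda$ makes $H_k$ random, which the propagated
  covariance treats as fixed; smoothing bias is likewise not reflected in
  the bands. Both effects are small under the default truth but grow with
  rougher coefficient functions.
* Only Gaussian conditional distributions are implemented; other families
  raise an error pointing at the (unimplemented) bootstrap band path.
* BLUP curves are smoothed for display only; no uncertainty accompanies
  them.

## Problem sizes used by the tests

The packaged tests run replicated simulations at desk scale, chosen as a
balance of Monte-Carlo error and runtime: 200 replicates for the coverage and
recovery checks at the default study size ($n = 7$, $S = 40$), 50 replicates
per sample size for the power-ordering comparison over $n \in \{4, 7, 10,
14\}$, and 500 null replicates at a reduced size ($n = 6$, $S = 20$, 10
trials per condition) for the type-I checks. `scripts/acceptance.R`
re-runs the coverage benchmark at 200 replicates per sample size across the
full grid.
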