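---
title: "Random-walk likelihoods, least-squares trends and peak tracking for sparse fossil series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-walk likelihoods, least-squares trends and peak tracking for sparse fossil series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grwtrend)
```

## The model and its assumptions

A fossil trait series is a short, irregular sequence of population
samples: at times $t_1 < \dots < t_N$ we observe sample means
$\bar y_i$ of $n_i$ individuals drawn from populations with phenotypic
variance $V_p$, so each observation carries sampling noise of variance
$v_i = V_p / n_i$, independent across samples.

The general random walk (GRW) model for the latent mean is
$$ y_{t+1} = y_t + \mu_{step} + \sqrt{\sigma^2_{step}}\,\varepsilon_t,
   \qquad \varepsilon_t \sim \mathcal N(0, 1) \text{ i.i.d.} $$
Directional evolution is measured by $\mu_{step}$; evolutionary
volatility by $\sigma^2_{step}$.  Each ancestor–descendant transition,
with observed change $\Delta Y$ over $T$ steps, is normal with mean
$T\mu_{step}$ and variance $T\sigma^2_{step} + v_A + v_D$; the summed
transition log-likelihood is what `fit_grw()` maximizes.  Key
assumptions: increments are i.i.d. normal, sampling times are known
exactly, and sampling errors are independent of the evolutionary
process.

Two competing descriptions of the same trend are implemented
alongside:

* **GLS/WLS** (`gls_fit()`, `wls_fit()`): the line $a + b t$ fitted by
  generalized least squares with covariance $\Omega = C + V$, where
  $C_{ij} = \min(t_i, t_j)\,\sigma^2_{step}$ is the integrated-noise
  covariance of the walk and $V = \mathrm{diag}(v_i)$.  With a known
  $\sigma^2_{step}$ the slope is BLUE; at $\sigma^2_{step} = 0$ the fit
  is exactly weighted least squares with weights $1/v_i$.
* **Adaptive peak tracking** (`fit_tracking()`): the trait regressed by
  WLS on a smoothed environmental proxy rather than on time, for
  records where a known driver moves the adaptive peak.

Prediction lines are scored by the weighted mean squared error
$\mathrm{WMSE} = r^\top \Omega^{-1} r / \mathrm{trace}(\Omega^{-1})$
(diagonal case: $\sum w_i r_i^2 / \sum w_i$), whose normalization makes
it coincide with ordinary MSE under identity weighting.  In simulations
the residual $r$ is taken against the latent truth; for real data the
observations stand in for the truth.

## The negative-variance collapse

The likelihood is perfectly well defined for *negative*
$\sigma^2_{step}$ as long as every total variance
$T\sigma^2_{step} + v_A + v_D$ stays positive, and with large $v_i$ the
unconstrained maximizer frequently lands below zero.  `fit_grw()`
therefore searches down to the admissibility boundary
$\max_i\{-(v_{A,i} + v_{D,i})/T_i\}$ (plus a $10^{-9}$ margin), reports
the raw estimate, and — when it is strictly negative — flags the fit
and stores a constrained refit at $\sigma^2_{step} = 0$.  At zero step
variance the profile in $\mu_{step}$ is an exact quadratic, so the
refit uses the closed form
$$ \hat\mu_{step} = \frac{\sum_i T_i \Delta Y_i / v_i}
                         {\sum_i T_i^2 / v_i},
   \qquad v_i = v_{A,i} + v_{D,i}, $$
which is the stationary point of the summed quadratic in $\mu_{step}$
(tests cross-check it against a 1-D numeric search).  The clamped
log-likelihood can never exceed the raw one, and the clamped GRW is a
deterministic walk plus noise — operationally indistinguishable in its
weighting from WLS.

## The simulator's stated world

`sim_config()` defaults encode the benchmark world: a 1000-step walk
with $\mu_{step} = 0.1$, $\sigma^2_{step} = 0.1$ (total change about
100), pinned at 0 at step 1; $N = 10$ samples; regular sampling at the
block midpoints $50, 150, \dots, 950$ or irregular sampling with one
uniform integer per 100-step block; $V_p = 1$ with $n = 30$ (standard
error $0.1826$) for the low-error protocol, $V_p = 400$ with $n = 30$
fixed or $n \sim U\{3, \dots, 60\}$ for the realistic-error protocols.
`benchmark_configs()` returns exactly these three worlds.

Choices the generator makes where the stated world is silent:

* The latent clock starts at $t = 1$ (value 0), so sample times are
  path indices on that clock.
* Sampling error is drawn once as $\mathcal N(0, V_p/n_i)$ rather than
  averaging $n_i$ individual errors — the same distribution, cheaper.
* Irregular times and per-sample $n$ are redrawn independently each
  replicate, so Monte-Carlo spreads include time randomness.

What the generator does **not** emulate: age-model (time measurement)
error, unequal $V_p$ across samples, non-normal increments, and any
dependence between sampling error and the walk.  A green Monte-Carlo
test therefore establishes correctness of the estimators *under the
model's own assumptions*, not robustness to their violation — age
uncertainty in particular is known to matter and is deliberately out
of scope.

## Weighting conventions in the study runner

Which $\sigma^2_{step}$ builds $\Omega$ is the one genuinely open
design choice, and `run_replicate()` exposes it:

* Default (`omega = "true_sigma"`): the GLS slope and its WMSE use the
  configured true $\sigma^2_{step}$ — the BLUE framing — while the GRW
  intercept and its WMSE always use the *estimated* step variance,
  clamped at zero when negative.  This treats GLS as the oracle-weight
  reference and GRW as a self-contained procedure, and it reproduces
  the benchmark WMSE ordering.
* Sensitivity mode (`omega = "estimated_sigma"`): both sides use the
  clamped estimate.

In real-data mode (`run_case()`) there is no true value; both fits use
the clamped estimate, which in every shipped example is zero, so the
linear fit is reported as WLS.

## Numerical choices

* **Optimizer**: Nelder–Mead on the negative log-likelihood, relative
  tolerance $10^{-10}$, restarted once from its converged point;
  moment-matching start ($\mu_0$ from the endpoint slope, $\sigma^2_0$
  from increment variance, floored at $10^{-6}$).  Inadmissible points
  are assigned a large finite penalty.  A grid oracle in the tests
  confirms agreement within one $10^{-4}$ cell on seeded series.
* **Error-free limit**: when all $v_i = 0$ the likelihood diverges as
  $\sigma^2 \to 0$ with vanishing residuals, so `fit_grw()` switches to
  the closed-form maximizer instead of the simplex.
* **Linear algebra**: all solves and quadratic forms go through a
  Cholesky factorization (fallback: explicit symmetric solve), with a
  condition-number warning above $10^{12}$; $\mathrm{trace}(\Omega^{-1})$
  comes from the factorization, never an explicit inverse formed for
  the fit itself.  An all-zero $\Omega$ (the noiseless limit, where all
  weightings are equivalent) falls back to identity weighting.
* **Real-data clock**: covariance construction needs positive times, so
  `run_case()` shifts non-positive ages by $1 - \min(t)$ and records
  the shift in the report.
* **Smoothing**: the centered moving average adjusts even windows up to
  the next odd size (window 100 averages 101 points) and shrinks the
  window symmetrically at the edges; edge behavior is a package choice,
  not prescribed by the model.
* **Log transform**: natural log, with standard errors transformed as
  $e_{log} = e \cdot \bar y_{log} / \bar y$, exactly preserving each
  sample's coefficient of variation; the $V_p$ bookkeeping is updated
  so $se^2 n = V_p$ keeps holding.  Means must exceed 1 so the log-mean
  is positive.
* **Seeding**: replicate $i$ of a study uses a counter-derived sub-seed
  of the master seed (kept below $2^{31}$), so any replicate is
  reproducible in isolation and extending a study leaves earlier
  replicates unchanged.

## Limitations

* The benchmark Monte-Carlo quantities are stochastic: at 1000
  replicates the negative-variance counts vary by tens and WMSE means
  by a few percent between seeds.  The negative-variance count in the
  irregular protocol tends to sit a few percent above the benchmark's
  printed count across seeds; the package reports what its own stated
  world produces rather than calibrating toward a reference draw.
* No unbiased-random-walk (zero-drift) rate estimation, no stasis
  model, and no information-criterion model categorization are
  provided; the comparison surface is deliberately the
  slope/WMSE one.
* Iterative re-estimation of the GLS covariance from data is not
  implemented; GLS uses a supplied (true or estimated) step variance.
* Tracking assumes an approximately linear trait–proxy relation and
  known proxy ages; hierarchical (e.g. colony-mean) sampling structures
  are summarized by their reported per-sample standard errors.
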