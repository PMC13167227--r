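# grwtrend

Inference of directional evolution from sparse, noisy fossil time
series — and a framework for asking whether the popular general random
walk (GRW) model is actually the right tool for that job.

## The problem

A fossil record of a mean trait is a handful of population samples
`(t_i, ȳ_i)`: a sample mean of `n_i` individuals at time `t_i`, with
sampling variance `Vp/n_i` (phenotypic variance over sample size).  The
GRW model treats the latent mean as a random walk with normal increments
of mean `μ_step` and variance `σ²_step` per time step; each
ancestor–descendant transition of observed change `ΔY` over `T` steps
contributes the log-likelihood

    ℓ(μ, σ²) = −½ln(2π) − ½ln(Tσ² + v_A + v_D) − (ΔY − Tμ)² / (2(Tσ² + v_A + v_D))

with `v_A`, `v_D` the endpoint sampling variances.  Summing over the
N − 1 transitions and maximizing gives `μ̂_step` — a measure of
directional evolution.  With realistic sampling errors, however, the
unconstrained `σ̂²_step` is very often **negative** and must be set to
zero, collapsing the GRW into a deterministic walk plus noise.

The alternative: fit the linear trend `ȳ = a + b·t` by generalized
least squares with the random-walk covariance
`Ω = C + V`, `C[i,j] = min(t_i, t_j)·σ²_step`, `V = diag(Vp/n_i)`.  The
GLS slope is the best linear unbiased estimator; when `σ²_step = 0` it
reduces to weighted least squares (weights `n_i/Vp`).  Methods are
compared by the weighted mean squared prediction error
`WMSE = rᵀΩ⁻¹r / trace(Ω⁻¹)`.  A third option, adaptive peak tracking,
regresses the trait on a smoothed environmental proxy instead of time.

`grwtrend` implements all three, plus a fully seeded simulator and
Monte-Carlo study runner that quantify how often the negative-variance
collapse happens and which estimator predicts better.

## Worked example

Analyze the shipped synthetic case table (a deterministic directional
walk, `μ_step = 0.1`, `σ²_step = 0`, observed with phenotypic variance
400 and 3–60 individuals per sample):

```r
library(grwtrend)
ser <- read_trait_series(system.file("extdata",
         "synthetic_case_series.tsv", package = "grwtrend"))
run_case(ser,
         proxy = system.file("extdata", "synthetic_proxy.tsv",
                             package = "grwtrend"),
         smooth_window = 21)
#> Case report
#>   sigma2_raw = -0.11138 (negative; clamped to 0)
#>   WLS:  b = 0.100497, a = 0.0063761, WMSE = 12.2577
#>   GRW:  b = 0.102373, a = -0.973248, WMSE = 12.4669
#>   TRACKING: b = 34.3179, a = 40.9273, WMSE = 341.323
```

Read: the unconstrained step-variance estimate came out negative
(−0.111) and was clamped to zero, so the GRW degenerates and its
weighting coincides with WLS.  Both slope estimates recover the true
0.1; WLS has the (slightly) smaller WMSE, as theory predicts for a
collapsed GRW.  The tracking fit is poor because this series does not
follow the proxy — the report makes that failure visible rather than
hiding it.

A small Monte-Carlo study (200 replicates of the high-error regular
protocol):

```r
st <- run_study(benchmark_configs()["vp400_regular"],
                replicates = 200, master_seed = 1)
st$summary[, c("n_negative_sigma2", "mean_mu", "mean_b_gls",
               "mean_wmse_grw", "mean_wmse_gls")]
#>   n_negative_sigma2  mean_mu mean_b_gls mean_wmse_grw mean_wmse_gls
#> 1                73 0.1005447   0.100739      8.691461      7.249197
```

73/200 replicates collapsed to a negative step variance; both slope
estimators are unbiased, but the GLS prediction line has the smaller
weighted error.

## Command line

```sh
Rscript -e 'grwtrend::grw_cli()' simulate --seed 1 --Vp 400 --out series.tsv
Rscript -e 'grwtrend::grw_cli()' fit      --series series.tsv
Rscript -e 'grwtrend::grw_cli()' study    --preset all --reps 1000 --seed 1 --out study
Rscript -e 'grwtrend::grw_cli()' case     --series series.tsv --proxy proxy.tsv --window 101
```

(`system.file("cli", "grwtrend.R", package = "grwtrend")` is a copyable
launcher script.)

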