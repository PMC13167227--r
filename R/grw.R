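#' Ancestor-descendant transitions of a trait series
#'
#' Converts N ordered samples into the N - 1 evolutionary transitions on
#' which the random-walk likelihood operates.  Transition i carries the
#' observed trait change `dY` between consecutive samples, the elapsed
#' time `T` (in steps), and the sampling-error variances `vA = Vp_i/n_i`
#' and `vD = Vp_{i+1}/n_{i+1}` of the ancestor and descendant means.
#'
#' @param series a [trait_series()].
#' @return data frame of class `grw_transitions` with columns `dY`, `T`,
#'   `vA`, `vD`.
#' @export
series_to_transitions <- function(series) {
  stopifnot(inherits(series, "trait_series"))
  N <- nrow(series)
  if (N < 2L) stop("need at least 2 samples to form a transition")
  Tt <- diff(series$time)
  if (any(Tt <= 0)) stop("sample times must be strictly increasing")
  v <- series$Vp / series$n
  out <- data.frame(dY = diff(series$mean), T = Tt,
                    vA = v[-N], vD = v[-1L])
  class(out) <- c("grw_transitions", "data.frame")
  out
}

#' Per-transition random-walk log-likelihood
#'
#' The log-likelihood of one observed trait change `dY` over `T` time
#' steps under a general random walk with mean step `mu_step` and step
#' variance `sigma2_step`, with sampling-error variances `vA` and `vD` at
#' the two endpoints.  The total variance of the transition is
#' `V = T * sigma2_step + vA + vD`, and
#'
#'   l = -1/2 log(2 pi) - 1/2 log(V) - (dY - T * mu_step)^2 / (2 V).
#'
#' `sigma2_step` may be negative (unconstrained likelihood surfaces are
#' explored down to the admissibility boundary where V hits 0), but every
#' total variance must be strictly positive.
#'
#' @param mu_step mean step (trait units per step).
#' @param sigma2_step step variance (may be negative while V stays > 0).
#' @param transitions a `grw_transitions` frame (or anything with
#'   columns `dY`, `T`, `vA`, `vD`).
#' @return numeric vector of per-transition log-likelihood values.
#' @export
transition_loglik <- function(mu_step, sigma2_step, transitions) {
  V <- transitions$T * sigma2_step + transitions$vA + transitions$vD
  bad <- which(V <= 0)
  if (length(bad)) {
    stop(sprintf("non-positive total variance at transition %d (V = %g)",
                 bad[1], V[bad[1]]))
  }
  -0.5 * log(2 * pi) - 0.5 * log(V) -
    (transitions$dY - transitions$T * mu_step)^2 / (2 * V)
}

#' Summed random-walk log-likelihood of a series
#'
#' @param mu_step,sigma2_step step parameters.
#' @param series a [trait_series()] (or a precomputed
#'   `grw_transitions` frame).
#' @return the sum of [transition_loglik()] over all N - 1 transitions.
#' @export
total_loglik <- function(mu_step, sigma2_step, series) {
  tr <- if (inherits(series, "grw_transitions")) series
        else series_to_transitions(series)
  sum(transition_loglik(mu_step, sigma2_step, tr))
}

## Admissibility boundary: smallest sigma2 with all total variances > 0.
sigma2_lower_bound <- function(tr) {
  max(-(tr$vA + tr$vD) / tr$T)
}

## Closed-form ML mean step at sigma2 = 0: with V_i = vA_i + vD_i the
## quadratic in mu is maximized at sum(T dY / V) / sum(T^2 / V).
mu_hat_sigma2_zero <- function(tr) {
  V <- tr$vA + tr$vD
  sum(tr$T * tr$dY / V) / sum(tr$T^2 / V)
}

#' Fit the general random walk by maximum likelihood
#'
#' Maximizes the summed transition log-likelihood over
#' `(mu_step, sigma2_step)` with the step variance unconstrained down to
#' the admissibility boundary (the largest negative value at which every
#' transition's total variance stays positive).  Uses a Nelder-Mead
#' simplex on the negative log-likelihood, restarted once from the
#' converged point, started from moment-matching values.
#'
#' When the unconstrained step-variance estimate is negative -- the
#' "negative-variance collapse" typical of large sampling errors -- the
#' fit is flagged and a constrained refit at `sigma2_step = 0` is stored,
#' whose mean step has the closed form weighted-least-squares solution;
#' the random walk then degenerates to a deterministic directional walk
#' plus sampling error.
#'
#' For a single transition the estimate is `mu_hat = dY / T` exactly.
#'
#' @param series a [trait_series()].
#' @return object of class `grw_fit`: list with `mu_raw`, `sigma2_raw`
#'   (unconstrained estimates), `mu_clamped`, `sigma2_clamped` (equal to
#'   the raw values unless clamping triggered), `negative_variance`
#'   flag, `loglik_raw`, `loglik_clamped`, `converged`, `boundary`
#'   (whether the raw estimate sits at the admissibility boundary) and
#'   `n_transitions`.
#' @export
#' @examples
#' fit <- fit_grw(simulate_series(sim_config(seed = 42)))
#' fit$mu_raw
fit_grw <- function(series) {
  tr <- series_to_transitions(series)

  ## Error-free observations (all Vp/n = 0): the likelihood has the
  ## closed-form maximizer mu = sum(dY)/sum(T),
  ## sigma2 = mean over transitions of (dY - T mu)^2 / T, and the
  ## simplex cannot be exact because the likelihood diverges as
  ## sigma2 -> 0 when the residuals vanish.
  if (all(tr$vA + tr$vD == 0)) {
    mu_raw <- sum(tr$dY) / sum(tr$T)
    s2_raw <- sum((tr$dY - tr$T * mu_raw)^2 / tr$T) / nrow(tr)
    ll <- if (s2_raw > 0) total_loglik(mu_raw, s2_raw, tr) else Inf
    return(structure(list(
      mu_raw = mu_raw, sigma2_raw = s2_raw,
      mu_clamped = mu_raw, sigma2_clamped = s2_raw,
      negative_variance = FALSE,
      loglik_raw = ll, loglik_clamped = ll,
      converged = TRUE, boundary = s2_raw == 0,
      n_transitions = nrow(tr)
    ), class = "grw_fit"))
  }

  bound <- sigma2_lower_bound(tr) + 1e-9
  nll <- function(p) {
    if (p[2] <= bound) return(.Machine$double.xmax / 2)
    -total_loglik(p[1], p[2], tr)
  }
  mu0 <- sum(tr$dY) / sum(tr$T)
  s20 <- max(stats::var(tr$dY / sqrt(tr$T)) / mean(tr$T), 1e-6)
  if (!is.finite(s20)) s20 <- 1e-6   # single transition: var() is NA
  ctl <- list(reltol = 1e-10, maxit = 5000L)
  opt <- stats::optim(c(mu0, s20), nll, method = "Nelder-Mead",
                      control = ctl)
  opt <- stats::optim(opt$par, nll, method = "Nelder-Mead", control = ctl)
  mu_raw <- opt$par[1]
  s2_raw <- opt$par[2]
  converged <- opt$convergence == 0L
  boundary <- (s2_raw - bound) < 1e-6 * max(abs(bound), 1)

  ## single transition: the exact maximizer in mu is dY / T at any
  ## admissible sigma2; keep the simplex answer for sigma2, fix mu.
  if (nrow(tr) == 1L) mu_raw <- tr$dY / tr$T

  negative <- s2_raw < 0
  if (negative) {
    mu_cl <- mu_hat_sigma2_zero(tr)
    s2_cl <- 0
  } else {
    mu_cl <- mu_raw
    s2_cl <- s2_raw
  }
  structure(list(
    mu_raw = mu_raw, sigma2_raw = s2_raw,
    mu_clamped = mu_cl, sigma2_clamped = s2_cl,
    negative_variance = negative,
    loglik_raw = total_loglik(mu_raw, s2_raw, tr),
    loglik_clamped = total_loglik(mu_cl, s2_cl, tr),
    converged = converged, boundary = boundary,
    n_transitions = nrow(tr)
  ), class = "grw_fit")
}

#' @export
print.grw_fit <- function(x, ...) {
  cat(sprintf("GRW fit over %d transitions\n", x$n_transitions))
  cat(sprintf("  raw:     mu_step = %.6g, sigma2_step = %.6g (logL = %.4f)\n",
              x$mu_raw, x$sigma2_raw, x$loglik_raw))
  if (x$negative_variance) {
    cat(sprintf("  clamped: mu_step = %.6g, sigma2_step = 0 (logL = %.4f)\n",
                x$mu_clamped, x$loglik_clamped))
    cat("  negative step-variance estimate clamped to zero\n")
  }
  if (!x$converged) cat("  WARNING: optimizer did not report convergence\n")
  invisible(x)
}

#' Log-likelihood surface on a parameter grid
#'
#' Evaluates the summed log-likelihood on a rectangular
#' `(mu_step, sigma2_step)` grid, for contour plots and as an
#' independent check on the optimizer.  Negative step variances are
#' admitted; grid cells where any transition's total variance is
#' non-positive are returned as `NA` rather than raising an error.
#'
#' @param series a [trait_series()].
#' @param mu_range length-2 range for the mean step axis.
#' @param sigma2_range length-2 range for the step-variance axis.
#' @param n_mu,n_sigma2 number of grid points per axis.
#' @return list of class `loglik_grid` with `mu` and `sigma2` axis
#'   vectors, the `loglik` matrix (rows index mu), and `argmax`, the
#'   `(mu, sigma2)` pair of the best grid cell.
#' @export
loglik_grid <- function(series, mu_range, sigma2_range,
                        n_mu = 101L, n_sigma2 = 101L) {
  tr <- series_to_transitions(series)
  mu <- seq(mu_range[1], mu_range[2], length.out = n_mu)
  s2 <- seq(sigma2_range[1], sigma2_range[2], length.out = n_sigma2)
  bound <- sigma2_lower_bound(tr)
  ll <- matrix(NA_real_, n_mu, n_sigma2)
  for (j in seq_along(s2)) {
    if (s2[j] <= bound) next
    V <- tr$T * s2[j] + tr$vA + tr$vD
    base <- sum(-0.5 * log(2 * pi) - 0.5 * log(V))
    for (i in seq_along(mu)) {
      ll[i, j] <- base - sum((tr$dY - tr$T * mu[i])^2 / (2 * V))
    }
  }
  best <- which(ll == max(ll, na.rm = TRUE), arr.ind = TRUE)[1, ]
  structure(list(mu = mu, sigma2 = s2, loglik = ll,
                 argmax = c(mu = mu[best[1]], sigma2 = s2[best[2]])),
            class = "loglik_grid")
}

#' Trend model constructor
#'
#' A fitted straight line `a + b * t` tagged by the method that produced
#' it; `weighting` records the covariance or weight structure used.
#'
#' @param a intercept (trait units).
#' @param b slope (trait units per time step).
#' @param method one of `"GRW"`, `"GLS"`, `"WLS"`, `"TRACKING"`.
#' @param weighting the weighting object used for fitting (kept for
#'   provenance; may be `NULL`).
#' @return object of class `trend_model`.
#' @export
trend_model <- function(a, b, method = c("GRW", "GLS", "WLS", "TRACKING"),
                        weighting = NULL) {
  method <- match.arg(method)
  structure(list(a = a, b = b, method = method, weighting = weighting),
            class = "trend_model")
}

#' @export
print.trend_model <- function(x, ...) {
  cat(sprintf("%s trend: a = %.6g, b = %.6g\n", x$method, x$a, x$b))
  invisible(x)
}

#' Predict from a trend model
#'
#' @param object a [trend_model()].
#' @param times times at which to evaluate the line.
#' @param ... unused.
#' @return numeric vector `a + b * times`.
#' @export
predict.trend_model <- function(object, times, ...) {
  object$a + object$b * times
}

#' Random-walk prediction line from a fitted model
#'
#' Builds the GRW prediction line: slope equal to the estimated mean
#' step (the clamped estimate when the step variance collapsed to zero,
#' times the scaling constant `c`, fixed at 1), and intercept fitted by
#' generalized least squares at that fixed slope:
#' `a = (1' Omega^-1 (y - b t)) / (1' Omega^-1 1)`.
#'
#' @param series a [trait_series()].
#' @param fit a [fit_grw()] result.
#' @param cov a [build_covariance()] model supplying the weighting
#'   `Omega`; defaults to the covariance built from the fit's clamped
#'   step variance.
#' @return a `"GRW"`-tagged [trend_model()].
#' @export
grw_trend <- function(series, fit, cov = NULL) {
  stopifnot(inherits(fit, "grw_fit"))
  if (is.null(cov)) {
    cov <- build_covariance(series$time, fit$sigma2_clamped,
                            series$Vp, series$n)
  }
  b <- fit$mu_clamped
  ch <- chol_factor(cov$Omega)
  one <- rep(1, nrow(series))
  num <- quad_solve(ch, one, series$mean - b * series$time)
  den <- quad_solve(ch, one, one)
  trend_model(a = num / den, b = b, method = "GRW", weighting = cov)
}
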