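#' Random-walk covariance model for a sampled series
#'
#' The latent mean trait of a random walk has covariance
#' `Cov(y(t), y(s)) = min(t, s) * sigma2_step` -- the variance law of
#' integrated discrete white noise -- so N samples at times t_1 < ... <
#' t_N have covariance matrix `C[i, j] = min(t_i, t_j) * sigma2`.
#' Observed means add independent sampling noise, giving
#' `Omega = C + V` with `V = diag(Vp_i / n_i)`.
#'
#' Estimation may visit negative step variances, but a covariance model
#' can only be built from `sigma2 >= 0`; at `sigma2 = 0` the matrix `C`
#' vanishes and the model collapses to the diagonal (weighted
#' least squares) case.
#'
#' @param times strictly increasing positive sample times on the
#'   process clock.
#' @param sigma2 step variance used to build `C` (>= 0).
#' @param Vp phenotypic variance per sample (scalar or vector).
#' @param n individuals per sample (scalar or vector).
#' @return object of class `cov_model`: list with matrices `C`, `V`,
#'   `Omega`, the `sigma2_used`, and `mode` (`"full"` or `"diagonal"`).
#' @export
#' @examples
#' cm <- build_covariance(c(50, 150, 950), 0.1, Vp = 1, n = 30)
#' cm$C[1, 3]   # min(50, 950) * 0.1 = 5
build_covariance <- function(times, sigma2, Vp, n) {
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(times <= 0)) stop("times must be positive on the process clock")
  if (sigma2 < 0) stop("covariance construction requires sigma2 >= 0")
  N <- length(times)
  Vp <- rep_len(Vp, N)
  n <- rep_len(n, N)
  C <- outer(times, times, pmin) * sigma2
  V <- diag(Vp / n, nrow = N)
  structure(list(C = C, V = V, Omega = C + V, sigma2_used = sigma2,
                 times = times,
                 mode = if (sigma2 == 0) "diagonal" else "full"),
            class = "cov_model")
}

## Cholesky factorization with a symmetric-indefinite fallback.  All
## downstream quadratic forms, solves and the trace of the inverse go
## through the factorization; no explicit inverse unless chol() fails.
chol_factor <- function(Omega) {
  if (max(abs(Omega)) == 0) {
    # noiseless limit (sigma2 = 0 and Vp = 0): all observations exact,
    # every weighting is equivalent; use the identity
    return(list(R = diag(nrow(Omega)), Oinv = NULL))
  }
  kap <- kappa(Omega, exact = FALSE)
  if (is.finite(kap) && kap > 1e12) {
    warning(sprintf("weighting matrix badly conditioned (kappa ~ %.2g)", kap))
  }
  R <- tryCatch(chol(Omega), error = function(e) NULL)
  if (is.null(R)) {
    Oinv <- tryCatch(solve(Omega), error = function(e) {
      stop("weighting matrix is singular")
    })
    return(list(R = NULL, Oinv = Oinv))
  }
  list(R = R, Oinv = NULL)
}

## x' Omega^-1 y through the factorization.
quad_solve <- function(ch, x, y) {
  if (!is.null(ch$R)) {
    zx <- backsolve(ch$R, x, transpose = TRUE)
    zy <- backsolve(ch$R, y, transpose = TRUE)
    sum(zx * zy)
  } else {
    drop(crossprod(x, ch$Oinv %*% y))
  }
}

trace_inverse <- function(ch) {
  if (!is.null(ch$R)) sum(diag(chol2inv(ch$R))) else sum(diag(ch$Oinv))
}

#' Generalized least squares trend fit
#'
#' Fits the two-parameter line `y = a + b t` by GLS with weighting
#' `Omega` from a covariance model: `(a, b)' = (X' Omega^-1 X)^-1
#' X' Omega^-1 y` with design `X = [1, t]`, solved through a Cholesky
#' factorization rather than an explicit inverse.  With `Omega` built
#' from the true step variance the slope is the best linear unbiased
#' estimator (BLUE) of the evolutionary trend.
#'
#' @param series a [trait_series()].
#' @param cov a [build_covariance()] model for the series' times.
#' @return a `"GLS"`-tagged [trend_model()] (tag `"WLS"` when the
#'   covariance is diagonal).
#' @export
gls_fit <- function(series, cov) {
  stopifnot(inherits(series, "trait_series"), inherits(cov, "cov_model"))
  t <- series$time
  if (length(unique(t)) < 2L) stop("need at least 2 distinct times")
  X <- cbind(1, t)
  ch <- chol_factor(cov$Omega)
  if (!is.null(ch$R)) {
    Z <- backsolve(ch$R, X, transpose = TRUE)
    w <- backsolve(ch$R, series$mean, transpose = TRUE)
    beta <- solve(crossprod(Z), crossprod(Z, w))
  } else {
    A <- crossprod(X, ch$Oinv %*% X)
    beta <- solve(A, crossprod(X, ch$Oinv %*% series$mean))
  }
  trend_model(a = beta[1], b = beta[2],
              method = if (cov$mode == "diagonal") "WLS" else "GLS",
              weighting = cov)
}

#' Weighted least squares trend fit
#'
#' The diagonal special case of [gls_fit()]: weights `w_i` (by default
#' the reciprocal sampling variances `n_i / Vp_i`, the `W = V^-1` of the
#' zero-step-variance model) and normal equations
#' `(a, b)' = (X' W X)^-1 X' W y`.
#'
#' @param series a [trait_series()].
#' @param weights positive weights, one per sample; default `1 / se^2`.
#' @return a `"WLS"`-tagged [trend_model()].
#' @export
wls_fit <- function(series, weights = NULL) {
  stopifnot(inherits(series, "trait_series"))
  if (is.null(weights)) weights <- series$n / series$Vp
  if (length(weights) != nrow(series)) stop("one weight per sample required")
  if (any(weights <= 0) || any(!is.finite(weights))) {
    stop("weights must be positive and finite")
  }
  t <- series$time
  if (length(unique(t)) < 2L) stop("need at least 2 distinct times")
  X <- cbind(1, t)
  XtW <- t(X * weights)
  beta <- solve(XtW %*% X, XtW %*% series$mean)
  trend_model(a = beta[1], b = beta[2], method = "WLS",
              weighting = weights)
}

#' Weighted mean squared prediction error
#'
#' Scores predictions against a reference vector by the quadratic form
#' `r' Omega^-1 r / trace(Omega^-1)` (full covariance weighting) or
#' `sum(w r^2) / sum(w)` (diagonal weights), with `r` the residual
#' vector.  The trace normalization makes the score coincide with the
#' ordinary mean squared error when `Omega` is the identity.  In
#' simulations the reference is the latent true mean vector; for real
#' data the observations stand in for the truth.
#'
#' @param reference reference vector (true or observed means).
#' @param predictions model predictions at the same samples.
#' @param weighting a [build_covariance()] model, or a positive weight
#'   vector for the diagonal case.
#' @return object of class `wmse_report`: list with `value`, `method`
#'   (filled by callers), and `normalization` (the trace or weight sum).
#' @export
wmse <- function(reference, predictions, weighting) {
  if (length(reference) != length(predictions)) {
    stop("reference and predictions must have equal length")
  }
  r <- reference - predictions
  if (inherits(weighting, "cov_model")) {
    ch <- chol_factor(weighting$Omega)
    val <- quad_solve(ch, r, r)
    norm <- trace_inverse(ch)
  } else {
    w <- weighting
    if (length(w) != length(r)) stop("one weight per sample required")
    if (any(w <= 0)) stop("weights must be positive")
    val <- sum(w * r^2)
    norm <- sum(w)
  }
  structure(list(value = val / norm, normalization = norm,
                 weighting = weighting),
            class = "wmse_report")
}

#' @export
print.wmse_report <- function(x, ...) {
  cat(sprintf("WMSE = %.6g (normalization %.6g)\n", x$value,
              x$normalization))
  invisible(x)
}
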