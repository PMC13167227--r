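#' Construct an environmental proxy series
#'
#' A two-column container for an environmental driver (for example an
#' oxygen-isotope or Mg/Ca paleotemperature record) on the same clock as
#' the trait series it will be aligned with.
#'
#' @param times increasing timestamps.
#' @param values proxy measurements.
#' @return data frame of class `proxy_series` with columns `time`,
#'   `value`.
#' @export
proxy_series <- function(times, values) {
  if (length(times) != length(values)) stop("times and values must match")
  if (any(diff(times) <= 0)) stop("proxy times must be strictly increasing")
  if (any(!is.finite(values))) stop("proxy values must be finite")
  out <- data.frame(time = as.numeric(times), value = as.numeric(values))
  class(out) <- c("proxy_series", "data.frame")
  out
}

#' Read a proxy series from delimited text
#'
#' Expects two columns (time, value), with or without a header.
#'
#' @param path file path.
#' @return a [proxy_series()].
#' @export
read_proxy_series <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  has_header <- !grepl("^[-0-9.eE+ \t,]+$", first)
  df <- utils::read.table(path, header = has_header, sep = sep,
                          stringsAsFactors = FALSE)
  proxy_series(df[[1]], df[[2]])
}

#' Centered moving-average smoothing of a proxy series
#'
#' Smooths the proxy with a centered moving average of the given window
#' (adjusted up to the next odd integer so the window is symmetric; the
#' window-100 smoothing of an isotope record therefore averages 101
#' points).  Near the edges the window shrinks symmetrically, so the
#' first and last points are returned unchanged.
#'
#' @param proxy a [proxy_series()].
#' @param window window size in samples (>= 1).
#' @return a smoothed [proxy_series()] on the same timestamps.
#' @export
moving_average_smooth <- function(proxy, window) {
  stopifnot(inherits(proxy, "proxy_series"))
  window <- as.integer(window)
  if (window < 1L) stop("window must be at least 1")
  if (window %% 2L == 0L) window <- window + 1L
  n <- nrow(proxy)
  if (n < window) stop("proxy series shorter than the smoothing window")
  half <- (window - 1L) %/% 2L
  v <- proxy$value
  sm <- vapply(seq_len(n), function(i) {
    k <- min(half, i - 1L, n - i)
    mean(v[(i - k):(i + k)])
  }, numeric(1))
  proxy_series(proxy$time, sm)
}

#' Log-transform a trait series with error propagation
#'
#' Replaces each mean by its natural logarithm and transforms the
#' standard errors as `e_log = e * y_log / y`, which preserves the
#' coefficient of variation of every sample (`e_log / y_log = e / y`).
#' The per-sample `Vp` bookkeeping is updated so that
#' `se^2 * n = Vp` continues to hold.
#'
#' @param series a [trait_series()]; all means (and their logs) must be
#'   positive for the transform to be defined.
#' @return a transformed [trait_series()].
#' @export
log_transform_series <- function(series) {
  stopifnot(inherits(series, "trait_series"))
  if (any(series$mean <= 0)) stop("log transform requires positive means")
  y_log <- log(series$mean)
  if (any(y_log <= 0)) {
    stop("log transform requires log-means > 0 (means > 1)")
  }
  se_log <- series$se * y_log / series$mean
  y_true_log <- if (all(is.na(series$mean_true))) NULL
                else log(series$mean_true)
  trait_series(series$time, y_log, Vp = se_log^2 * series$n,
               n = series$n, y_true = y_true_log)
}

## Nearest-timestamp alignment of proxy values to sample times.
## Tolerance defaults to half the median proxy spacing; unmatched
## samples are an error, never dropped silently.
align_proxy <- function(proxy, times, tolerance = NULL) {
  if (is.null(tolerance)) {
    tolerance <- stats::median(diff(proxy$time)) / 2
  }
  vapply(times, function(t) {
    i <- which.min(abs(proxy$time - t))
    if (abs(proxy$time[i] - t) > tolerance) {
      stop(sprintf("no proxy value within %g of sample time %g",
                   tolerance, t))
    }
    proxy$value[i]
  }, numeric(1))
}

#' Fit an adaptive-peak-tracking model
#'
#' Regresses the mean trait on a (smoothed) environmental proxy by
#' weighted least squares, modeling the population as tracking a moving
#' adaptive peak driven by the proxy rather than drifting in time.  The
#' proxy is aligned to the sample times by nearest-timestamp matching,
#' the line is fitted with weights `1 / se^2`, and predictions in time
#' coordinates are obtained by evaluating the line at each sample
#' time's proxy value.
#'
#' @param series a [trait_series()].
#' @param proxy a [proxy_series()], typically pre-smoothed with
#'   [moving_average_smooth()]; alternatively a numeric vector of proxy
#'   values already aligned to the sample times.
#' @param tolerance alignment tolerance in time units; default half the
#'   median proxy spacing.
#' @return list of class `tracking_fit`: the `"TRACKING"`-tagged
#'   [trend_model()] in proxy coordinates (`a + b * proxy`), the aligned
#'   `proxy_at_samples`, per-sample `predictions` in time coordinates,
#'   and the `wmse_report` of those predictions against the observed
#'   means under the WLS weighting.
#' @export
fit_tracking <- function(series, proxy, tolerance = NULL) {
  stopifnot(inherits(series, "trait_series"))
  p <- if (inherits(proxy, "proxy_series")) {
    align_proxy(proxy, series$time, tolerance)
  } else {
    if (length(proxy) != nrow(series)) {
      stop("aligned proxy vector must have one value per sample")
    }
    as.numeric(proxy)
  }
  if (max(p) - min(p) < .Machine$double.eps^0.5 * max(1, abs(p[1]))) {
    stop("proxy is constant across samples: tracking slope indeterminate")
  }
  w <- series$n / series$Vp
  X <- cbind(1, p)
  XtW <- t(X * w)
  beta <- solve(XtW %*% X, XtW %*% series$mean)
  model <- trend_model(a = beta[1], b = beta[2], method = "TRACKING",
                       weighting = w)
  preds <- beta[1] + beta[2] * p
  structure(list(model = model, proxy_at_samples = p,
                 predictions = preds,
                 wmse = wmse(series$mean, preds, w)),
            class = "tracking_fit")
}

#' @export
print.tracking_fit <- function(x, ...) {
  cat(sprintf("Tracking model: trait = %.6g + %.6g * proxy (WMSE %.6g)\n",
              x$model$a, x$model$b, x$wmse$value))
  invisible(x)
}
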