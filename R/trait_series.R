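#' Construct a trait series
#'
#' A `trait_series` is the package's central container: an ordered set of
#' population samples from a fossil (or simulated) record, each sample
#' being a mean trait value observed at a known time with a known sampling
#' error.  The sampling variance of each observed mean is `Vp / n`, the
#' within-population phenotypic variance divided by the number of measured
#' individuals, so the recorded standard error is `sqrt(Vp / n)`.
#'
#' @param times strictly increasing sample times (process time steps for
#'   simulated data; real-data ages may be non-positive and are shifted
#'   onto a positive process clock by [run_case()] before any
#'   random-walk covariance is built).
#' @param y_obs observed sample means (trait units).
#' @param Vp phenotypic variance per sample; scalar or vector.
#' @param n number of individuals per sample; scalar or vector.
#' @param y_true latent true means, if known (simulated data); `NULL`
#'   otherwise.
#'
#' @return A data frame of class `trait_series` with columns `time`,
#'   `mean`, `mean_true` (may be `NA`), `Vp`, `n` and `se`, where
#'   `se = sqrt(Vp / n)`.
#' @export
#' @examples
#' ts <- trait_series(times = c(50, 150), y_obs = c(0, 10), Vp = 1, n = 30)
#' ts$se
trait_series <- function(times, y_obs, Vp, n, y_true = NULL) {
  N <- length(times)
  if (N < 2L) stop("a trait series needs at least 2 samples")
  if (length(y_obs) != N) stop("times and y_obs must have equal length")
  if (any(!is.finite(times))) stop("sample times must be finite")
  if (any(diff(times) <= 0)) stop("sample times must be strictly increasing")
  Vp <- rep_len(as.numeric(Vp), N)
  n <- rep_len(as.numeric(n), N)
  if (any(Vp < 0)) stop("Vp must be nonnegative")
  if (any(n < 1)) stop("n must be at least 1 for every sample")
  if (!is.null(y_true) && length(y_true) != N) {
    stop("y_true must match the number of samples")
  }
  out <- data.frame(
    time = as.numeric(times),
    mean = as.numeric(y_obs),
    mean_true = if (is.null(y_true)) rep(NA_real_, N) else as.numeric(y_true),
    Vp = Vp,
    n = n,
    se = sqrt(Vp / n)
  )
  class(out) <- c("trait_series", "data.frame")
  out
}

#' @export
print.trait_series <- function(x, ...) {
  cat(sprintf("Trait series: %d samples, time %g..%g\n",
              nrow(x), min(x$time), max(x$time)))
  NextMethod()
}

#' Write a trait series table
#'
#' Writes the tab-delimited table dialect shared by all package tools:
#' header columns `time`, `mean`, `mean_true` (omitted when unknown),
#' `Vp`, `n`, `se`.
#'
#' @param series a [trait_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trait_series <- function(series, path) {
  stopifnot(inherits(series, "trait_series"))
  df <- as.data.frame(series)
  if (all(is.na(df$mean_true))) df$mean_true <- NULL
  for (col in names(df)) {           # full precision: exact round-trips
    df[[col]] <- sprintf("%.17g", df[[col]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trait series table
#'
#' Reads the delimited dialect written by [write_trait_series()].  Columns
#' `time`, `mean` are required; `se` or the pair (`Vp`, `n`) must be
#' present so sampling variances can be reconstructed; `mean_true` is
#' optional.  Any whitespace or comma delimiter is accepted.
#'
#' @param path input file path.
#' @return a [trait_series()].
#' @export
read_trait_series <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("time", "mean") %in% names(df))) {
    stop("trait series table needs 'time' and 'mean' columns")
  }
  if (!all(c("Vp", "n") %in% names(df))) {
    if (!"se" %in% names(df)) {
      stop("trait series table needs either (Vp, n) or se columns")
    }
    df$n <- if ("n" %in% names(df)) df$n else rep(1, nrow(df))
    df$Vp <- df$se^2 * df$n
  }
  trait_series(df$time, df$mean, Vp = df$Vp, n = df$n,
               y_true = if ("mean_true" %in% names(df)) df$mean_true)
}
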