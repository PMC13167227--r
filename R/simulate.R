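#' Simulation configuration for the general random walk generator
#'
#' Bundles and validates the parameters of the discrete-time generative
#' model: a latent mean trait following
#' `y(t+1) = y(t) + mu_step + sqrt(sigma2_step) * eps(t)` over `horizon`
#' steps, sparsely sampled `n_samples` times, each observed mean
#' contaminated with sampling error of variance `Vp / n`.
#'
#' Defaults are the benchmark simulation conditions: a 1000-step walk
#' with mean step 0.1 and step variance 0.1, ten samples, phenotypic
#' variance 1 and 30 individuals per sample.
#'
#' @param mu_step mean evolutionary step (trait units per time step).
#' @param sigma2_step step variance (trait units^2 per time step, >= 0).
#' @param Vp phenotypic variance (trait units^2, >= 0).
#' @param horizon number of time steps of the latent walk.
#' @param n_samples number N of extracted samples (>= 2).
#' @param sampling `"regular"` (block midpoints) or `"irregular"` (one
#'   uniform draw per block).
#' @param n_individuals either a single integer (fixed number of
#'   individuals per sample) or an integer range `c(lo, hi)` from which n
#'   is drawn uniformly per sample (inclusive).
#' @param seed optional integer seed applied by [simulate_series()].
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(mu_step = 0.1, sigma2_step = 0.1, Vp = 1,
                       horizon = 1000L, n_samples = 10L,
                       sampling = c("regular", "irregular"),
                       n_individuals = 30L, seed = NULL) {
  sampling <- match.arg(sampling)
  horizon <- as.integer(horizon)
  n_samples <- as.integer(n_samples)
  if (sigma2_step < 0) stop("sigma2_step must be nonnegative")
  if (Vp < 0) stop("Vp must be nonnegative")
  if (n_samples < 2L) stop("need at least 2 samples")
  if (horizon < n_samples) stop("horizon must be at least n_samples")
  if (!length(n_individuals) %in% c(1L, 2L)) {
    stop("n_individuals must be a single integer or a range c(lo, hi)")
  }
  if (any(n_individuals < 1)) stop("n_individuals must be >= 1")
  if (length(n_individuals) == 2L && n_individuals[1] > n_individuals[2]) {
    stop("n_individuals range must be increasing")
  }
  structure(list(mu_step = mu_step, sigma2_step = sigma2_step, Vp = Vp,
                 horizon = horizon, n_samples = n_samples,
                 sampling = sampling,
                 n_individuals = as.integer(n_individuals),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sim_config")
}

#' Simulate the latent random-walk trajectory
#'
#' Generates the full latent path of the mean trait over
#' `config$horizon` time steps.  The path starts at 0 at time step 1 and
#' accumulates i.i.d. Normal(`mu_step`, `sigma2_step`) increments, so its
#' variance at step t (for zero mean step) is `(t - 1) * sigma2_step` --
#' integrated discrete white noise.
#'
#' Uses the current RNG state; seed with [set.seed()] or via
#' [simulate_series()] for reproducibility.
#'
#' @param config a [sim_config()].
#' @return numeric vector of length `config$horizon`; element t is the
#'   latent mean at time step t, with element 1 equal to 0.
#' @export
simulate_trajectory <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  incr <- stats::rnorm(config$horizon - 1L, mean = config$mu_step,
                       sd = sqrt(config$sigma2_step))
  cumsum(c(0, incr))
}

#' Draw the sparse sampling times
#'
#' Partitions the horizon into `n_samples` equal blocks.  Regular
#' sampling returns the block midpoints (offset `ceiling(block / 2)`
#' within each block: 50, 150, ..., 950 for a 1000-step horizon and 10
#' samples).  Irregular sampling draws one uniform integer per block, so
#' sample i lies in `(100 * (i - 1), 100 * i]` for the default layout.
#'
#' @param config a [sim_config()]; `horizon` must be divisible by
#'   `n_samples`.
#' @return strictly increasing integer vector of length `n_samples`.
#' @export
make_sampling_times <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  N <- config$n_samples
  if (config$horizon %% N != 0L) {
    stop("horizon must divide into n_samples equal blocks")
  }
  block <- config$horizon %/% N
  if (config$sampling == "regular") {
    times <- (seq_len(N) - 1L) * block + as.integer(ceiling(block / 2))
  } else {
    times <- (seq_len(N) - 1L) * block +
      vapply(seq_len(N), function(i) sample.int(block, 1L), integer(1))
  }
  if (any(diff(times) <= 0)) stop("sampling times are not increasing")
  times
}

#' Observe a latent path at the sampling times
#'
#' Extracts the latent means at `times` and adds sampling error: each
#' observed mean is the true mean plus one Normal(0, Vp / n_i) draw --
#' distributionally identical to the mean of n_i individual errors of
#' variance Vp.  With a fixed `n_individuals` every sample has the same
#' n; with a range, n_i is drawn uniformly on the inclusive range.
#'
#' @param path latent trajectory from [simulate_trajectory()].
#' @param times sampling times from [make_sampling_times()].
#' @param config a [sim_config()].
#' @return a [trait_series()] with `mean_true` filled in.
#' @export
observe_series <- function(path, times, config) {
  stopifnot(inherits(config, "sim_config"))
  if (any(times < 1L) || any(times > length(path))) {
    stop("sampling times outside the simulated path")
  }
  N <- length(times)
  ni <- config$n_individuals
  n <- if (length(ni) == 2L) {
    ni[1] + vapply(seq_len(N),
                   function(i) sample.int(ni[2] - ni[1] + 1L, 1L),
                   integer(1)) - 1L
  } else {
    rep(ni, N)
  }
  y_true <- path[times]
  y_obs <- y_true + stats::rnorm(N, mean = 0, sd = sqrt(config$Vp / n))
  trait_series(times, y_obs, Vp = config$Vp, n = n, y_true = y_true)
}

#' Simulate one complete observed trait series
#'
#' Convenience wrapper: seeds the RNG when `config$seed` is set, then
#' runs [simulate_trajectory()], [make_sampling_times()] and
#' [observe_series()] in order.
#'
#' @param config a [sim_config()].
#' @return a [trait_series()].
#' @export
#' @examples
#' ts <- simulate_series(sim_config(seed = 1))
#' head(ts)
simulate_series <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  path <- simulate_trajectory(config)
  times <- make_sampling_times(config)
  observe_series(path, times, config)
}
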