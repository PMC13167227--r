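# Shared fixtures and independent oracles for the test suite.

# A small deterministic series with known structure.
make_toy_series <- function() {
  trait_series(times = c(50, 150, 250, 350),
               y_obs = c(0.2, 10.4, 19.8, 30.1),
               Vp = 1, n = 30)
}

# Seeded simulated series under a given protocol.
make_sim_series <- function(seed, Vp = 1, sampling = "regular",
                            n_individuals = 30L, n_samples = 10L,
                            horizon = 1000L) {
  simulate_series(sim_config(Vp = Vp, sampling = sampling,
                             n_individuals = n_individuals,
                             n_samples = n_samples, horizon = horizon,
                             seed = seed))
}

# Independent re-implementation of the summed transition log-likelihood:
# plain scalar loop, no shared code with the package internals.
oracle_total_loglik <- function(mu, s2, series) {
  total <- 0
  for (i in seq_len(nrow(series) - 1L)) {
    dY <- series$mean[i + 1] - series$mean[i]
    Tt <- series$time[i + 1] - series$time[i]
    v <- series$Vp[i] / series$n[i] + series$Vp[i + 1] / series$n[i + 1]
    V <- Tt * s2 + v
    if (V <= 0) return(-Inf)   # inadmissible parameter point
    total <- total - 0.5 * log(2 * pi) - 0.5 * log(V) -
      (dY - Tt * mu)^2 / (2 * V)
  }
  total
}

# Exhaustive grid maximization of the likelihood as an optimizer oracle.
oracle_grid_max <- function(series, mu_lim, s2_lim, step) {
  mus <- seq(mu_lim[1], mu_lim[2], by = step)
  s2s <- seq(s2_lim[1], s2_lim[2], by = step)
  best <- c(NA, NA, -Inf)
  for (s2 in s2s) {
    ll <- vapply(mus, function(m) oracle_total_loglik(m, s2, series),
                 numeric(1))
    j <- which.max(ll)
    if (ll[j] > best[3]) best <- c(mus[j], s2, ll[j])
  }
  best
}
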