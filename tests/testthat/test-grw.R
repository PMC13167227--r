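test_that("series_to_transitions builds dY, T and error variances", {
  ser <- trait_series(c(50, 150), c(0, 10), Vp = 1, n = 30)
  tr <- series_to_transitions(ser)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$dY, 10)
  expect_equal(tr$T, 100)
  expect_equal(tr$vA, 1 / 30)
  expect_equal(tr$vD, 1 / 30)

  reg <- make_sim_series(21)
  trr <- series_to_transitions(reg)
  expect_equal(nrow(trr), 9)
  expect_equal(trr$T, rep(100, 9))

  ser3 <- trait_series(c(1, 2, 4), c(0, 1, 3), Vp = 1, n = 10)
  expect_equal(series_to_transitions(ser3)$T, c(1, 2))
})

test_that("transition log-likelihood matches the closed form", {
  tr <- data.frame(dY = 0.7, T = 1, vA = 0.5, vD = 0.5)
  # unit total variance, zero residual: l = -log(2*pi)/2
  expect_equal(transition_loglik(0.7, 0, tr), -0.5 * log(2 * pi))
  expect_equal(round(transition_loglik(0.7, 0, tr), 5), -0.91894)
  # doubling total variance at zero residual costs log(2)/2
  tr2 <- data.frame(dY = 0.7, T = 1, vA = 1, vD = 1)
  expect_equal(transition_loglik(0.7, 0, tr2),
               -0.5 * log(2 * pi) - 0.5 * log(2))
  # mu = dY/T maximizes the residual term at any admissible sigma2
  for (s2 in c(0, 0.3, -0.4)) {
    l_at_mle <- transition_loglik(0.7, s2, tr)
    expect_true(all(transition_loglik(c(0, 0.5, 1.2), s2, tr) <= l_at_mle))
  }
  # inadmissible total variance is an error naming the transition
  expect_error(transition_loglik(0, -2, tr), "transition 1")
})

test_that("total log-likelihood sums transitions and matches the oracle", {
  ser <- make_toy_series()
  one <- trait_series(c(50, 150), c(0.2, 10.4), Vp = 1, n = 30)
  expect_equal(total_loglik(0.1, 0.05, one),
               transition_loglik(0.1, 0.05, series_to_transitions(one)))
  # translation invariance: only differences enter
  shifted <- trait_series(ser$time, ser$mean + 57.3, Vp = 1, n = 30)
  expect_equal(total_loglik(0.08, 0.02, shifted),
               total_loglik(0.08, 0.02, ser))
  # oracle equivalence on seeded series
  for (seed in c(1, 2, 3)) {
    s <- make_sim_series(seed, Vp = 400)
    for (p in list(c(0.1, 0.1), c(0, 0.5), c(-0.2, 0.01))) {
      expect_equal(total_loglik(p[1], p[2], s),
                   oracle_total_loglik(p[1], p[2], s))
    }
  }
})

test_that("single-transition fit gives mu = dY/T exactly", {
  ser <- trait_series(c(50, 150), c(0, 10), Vp = 1, n = 30)
  fit <- fit_grw(ser)
  expect_equal(fit$mu_raw, 0.1)
  expect_equal(fit$n_transitions, 1)
})

test_that("fit_grw agrees with an exhaustive grid-search oracle", {
  # 20 seeded 4-sample series; optimizer must land within one 1e-4 cell
  # of the best grid point (likelihood-wise, within the cell's spread).
  for (seed in 1:20) {
    ser <- make_sim_series(seed, Vp = 1, n_samples = 4L, horizon = 1000L)
    fit <- fit_grw(ser)
    g <- oracle_grid_max(ser,
                         mu_lim = fit$mu_raw + c(-0.005, 0.005),
                         s2_lim = fit$sigma2_raw + c(-0.005, 0.005),
                         step = 1e-4)
    expect_lt(abs(fit$mu_raw - g[1]), 1e-4 + 1e-9)
    expect_lt(abs(fit$sigma2_raw - g[2]), 1e-4 + 1e-9)
    expect_gte(fit$loglik_raw, g[3] - 1e-6)
  }
})

test_that("negative variance estimates are flagged and clamped", {
  # large sampling error, short series: engineered negative estimate
  found <- FALSE
  for (seed in 1:10) {
    ser <- make_sim_series(seed, Vp = 400)
    fit <- fit_grw(ser)
    if (fit$negative_variance) {
      found <- TRUE
      expect_lt(fit$sigma2_raw, 0)
      expect_identical(fit$sigma2_clamped, 0)
      expect_lte(fit$loglik_clamped, fit$loglik_raw + 1e-10)
      # clamped mu equals the closed form, cross-checked by 1-D search
      tr <- series_to_transitions(ser)
      opt <- optimize(function(m) total_loglik(m, 0, tr),
                      interval = fit$mu_clamped + c(-1, 1),
                      maximum = TRUE, tol = 1e-12)
      expect_equal(fit$mu_clamped, opt$maximum, tolerance = 1e-6)
    } else {
      expect_identical(fit$mu_clamped, fit$mu_raw)
      expect_identical(fit$sigma2_clamped, fit$sigma2_raw)
    }
  }
  expect_true(found)
})

test_that("loglik_grid is consistent with the optimizer and Eq structure", {
  ser <- make_sim_series(31, Vp = 400)
  fit <- fit_grw(ser)
  g <- loglik_grid(ser, mu_range = c(0, 0.2),
                   sigma2_range = c(-0.2, 0.3),
                   n_mu = 81L, n_sigma2 = 101L)
  cell <- c(diff(g$mu[1:2]), diff(g$sigma2[1:2]))
  expect_lt(abs(g$argmax["mu"] - fit$mu_raw), cell[1])
  expect_lt(abs(g$argmax["sigma2"] - fit$sigma2_raw), cell[2])
  # negative step variances are admitted on the grid
  expect_true(any(g$sigma2 < 0 & !is.na(g$loglik[1, ])))
  # restricting to sigma2 >= 0 cannot raise the maximum
  nonneg <- g$loglik[, g$sigma2 >= 0]
  expect_lte(max(nonneg, na.rm = TRUE), max(g$loglik, na.rm = TRUE))
  # profile in mu at fixed sigma2 is an exact parabola
  ll <- g$loglik[, 60]
  fit2 <- lm(ll ~ g$mu + I(g$mu^2))
  expect_lt(max(abs(residuals(fit2))), 1e-10)
})

test_that("grid cells below the admissibility boundary are NA not fatal", {
  ser <- trait_series(c(10, 20, 30), c(0, 1, 2), Vp = 1, n = 10)
  # boundary: -(0.1 + 0.1)/10 = -0.02; grid reaching below must have NAs
  g <- loglik_grid(ser, c(0, 0.2), c(-0.05, 0.05), n_mu = 5, n_sigma2 = 11)
  expect_true(any(is.na(g$loglik)))
  expect_true(any(!is.na(g$loglik)))
})

test_that("grw_trend fits the intercept by generalized least squares", {
  ser <- make_toy_series()
  fit <- fit_grw(ser)
  # identity weighting, slope 0: intercept is the plain mean
  id <- build_covariance(ser$time, 0, Vp = 1, n = 1)
  fit0 <- fit
  fit0$mu_clamped <- 0
  tm0 <- grw_trend(ser, fit0, id)
  expect_equal(tm0$a, mean(ser$mean))
  # identity weighting, fixed slope: OLS intercept
  b <- fit$mu_clamped
  tm <- grw_trend(ser, fit, id)
  expect_equal(tm$a, mean(ser$mean - b * ser$time))
  expect_equal(tm$b, b)
  # closed form vs 1-D numeric minimization under a full covariance
  cov <- build_covariance(ser$time, fit$sigma2_clamped, ser$Vp, ser$n)
  tm2 <- grw_trend(ser, fit, cov)
  Oi <- solve(cov$Omega)
  obj <- function(a) {
    r <- ser$mean - a - b * ser$time
    drop(t(r) %*% Oi %*% r)
  }
  opt <- optimize(obj, tm2$a + c(-5, 5), tol = 1e-12)
  expect_equal(tm2$a, opt$minimum, tolerance = 1e-7)
  expect_equal(predict(tm2, c(0, 100)), tm2$a + tm2$b * c(0, 100))
})
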