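test_that("logistic mean has the inflection, asymptote and overflow safety", {
  expect_equal(logistic_mean(25, 45, 0.12, 25), 22.5) # a/2 at x0
  expect_equal(logistic_mean(1e6, 45, 0.12, 25), 45)
  # exact at b*(t - x0) = +/- 800, no NaN/Inf
  expect_equal(logistic_mean(25 + 800 / 0.12, 45, 0.12, 25), 45)
  expect_equal(logistic_mean(25 - 800 / 0.12, 45, 0.12, 25), 0)
  t <- seq(-50, 300, by = 1)
  expect_true(all(diff(logistic_mean(t, 45, 0.12, 25)) > 0)) # monotone
  expect_true(all(is.finite(logistic_mean(t * 1e4, 45, 0.12, 25))))
})

test_that("quadratic mean has the intercept and vertex of its coefficients", {
  expect_equal(quadratic_mean(0, 3.5, 2, -0.01), 3.5)
  # vertex at -b/(2c)
  vertex <- -2 / (2 * -0.01)
  expect_equal(vertex, 100)
  g <- quadratic_mean(c(99, 100, 101), 0, 2, -0.01)
  expect_true(g[2] > g[1] && g[2] > g[3])
  expect_equal(quadratic_mean(c(-5, 0, 7), 1, 0, 0), c(1, 1, 1))
})

test_that("the gamma objective matches direct density summation", {
  d1 <- tibble::tibble(time_min = 0, cort_ng_ml = 1)
  # shape 1, mu 1: exponential density at its mean, -log(exp(-1)) = 1
  expect_equal(gamma_negloglik(d1, "null", list(mu = 1), 1), 1)

  d <- logistic_gamma_data(20, 45, 0.12, 25, shape = 5, seed = 101)
  nll <- gamma_negloglik(d, "logistic", list(a = 45, b = 0.12, x0 = 25), 5)
  mu <- logistic_mean(d$time_min, 45, 0.12, 25)
  expect_equal(nll, -oracle_gamma_loglik(d$cort_ng_ml, mu, 5),
               tolerance = 1e-10)

  # saturated bound: mu_i = y_i minimizes over mean configurations
  sat <- -oracle_gamma_loglik(d$cort_ng_ml, d$cort_ng_ml, 5)
  for (f in c(0.8, 0.95, 1.05, 1.3)) {
    mu_p <- d$cort_ng_ml * f
    expect_gte(-oracle_gamma_loglik(d$cort_ng_ml, mu_p, 5), sat)
  }

  # infeasible mean regions give an infinite objective
  expect_identical(
    gamma_negloglik(d, "quadratic", list(a = -10, b = 0, c = 0), 5), Inf)
  expect_identical(gamma_negloglik(d, "null", list(mu = 1), -2), Inf)
})

test_that("the null fit recovers the sample mean", {
  d <- tibble::tibble(time_min = c(5, 10, 20), cort_ng_ml = c(1, 2, 3))
  fit <- fit_curve(d, "null")
  expect_equal(fit$params$mu, 2, tolerance = 1e-6)
  expect_equal(fit$k, 2L)
  expect_equal(fit$resid_df, 2L)
})

test_that("near-noiseless logistic data recovers the true curve within 1%", {
  d <- logistic_gamma_data(200, 45, 0.12, 25, shape = 1e4, seed = 202)
  fit <- fit_curve(d, "logistic")
  expect_true(fit$converged)
  expect_lt(abs(fit$params$a - 45) / 45, 0.01)
  expect_lt(abs(fit$params$b - 0.12) / 0.12, 0.01)
  expect_lt(abs(fit$params$x0 - 25) / 25, 0.01)
})

test_that("fit bookkeeping matches the shared-shape parameter counting", {
  ds <- simulate_cort_data()
  fit <- fit_curve(ds, "logistic")
  expect_equal(fit$k, 4L)
  expect_equal(fit$resid_df, nrow(ds) - 3L)
  quad <- fit_curve(ds, "quadratic")
  expect_equal(quad$k, 4L)
  expect_equal(quad$resid_df, 60L)
})

test_that("reported optima equal the objective recomputed independently", {
  ds <- simulate_cort_data(sim_config(seed = 303))
  for (m in c("null", "logistic", "quadratic")) {
    fit <- fit_curve(ds, m)
    expect_equal(fit$log_lik,
                 -gamma_negloglik(ds, m, fit$params, fit$shape),
                 tolerance = 1e-10)
    expect_equal(fit$log_lik,
                 oracle_gamma_loglik(ds$cort_ng_ml, fit$fitted, fit$shape),
                 tolerance = 1e-6)
  }
})

test_that("the fitted logistic is never worse than the fitted constant", {
  for (s in 1:10) {
    ds <- simulate_cort_data(sim_config(seed = 500L + s))
    ll_log <- fit_curve(ds, "logistic")$log_lik
    ll_null <- fit_curve(ds, "null")$log_lik
    expect_gte(ll_log, ll_null - 1e-6)
  }
})

test_that("fitting rejects degenerate inputs", {
  d <- tibble::tibble(time_min = rep(30, 10), cort_ng_ml = rgamma(10, 4, 1))
  expect_error(fit_curve(d, "logistic"), "identical")
  expect_error(fit_curve(d[0, ], "null"), "empty")
  d2 <- tibble::tibble(time_min = 1:5, cort_ng_ml = c(1, 2, -3, 4, 5))
  expect_error(fit_curve(d2, "quadratic"), "positive")
  expect_error(fit_curve(d[1:3, ], "logistic"), "at least 5")
})

test_that("delta-method bands behave at the degenerate and far limits", {
  d <- logistic_gamma_data(80, 45, 0.12, 25, shape = 6, seed = 404)
  fit <- fit_curve(d, "logistic")
  band <- predict_with_ci(fit, c(5, 25, 50, 2000))
  expect_true(all(band$lo95 <= band$mean & band$mean <= band$hi95))
  expect_true(all(band$lo95 >= 0))
  expect_true(all(is.finite(band$hi95)))
  expect_true(all(diff(band$mean) > 0))

  # zero covariance collapses the band onto the mean
  fit0 <- fit
  fit0$cov[] <- 0
  band0 <- predict_with_ci(fit0, c(10, 30))
  expect_equal(band0$lo95, band0$mean)
  expect_equal(band0$hi95, band0$mean)

  # singular information: band unavailable, mean still returned
  fitNA <- fit
  fitNA$cov[] <- NA_real_
  bandNA <- predict_with_ci(fitNA, c(5, 25))
  expect_true(all(is.na(bandNA$lo95)))
  expect_equal(bandNA$mean, band$mean[1:2])
})

test_that("delta-method band widths agree with a parametric bootstrap", {
  d <- logistic_gamma_data(60, 45, 0.12, 25, shape = 6, seed = 808)
  fit <- fit_curve(d, "logistic")
  times <- c(20, 40, 80, 150)
  delta <- predict_with_ci(fit, times)
  boot <- predict_with_ci(fit, times, method = "bootstrap",
                          n_boot = 250, seed = 99)
  w_delta <- delta$hi95 - delta$lo95
  w_boot <- boot$hi95 - boot$lo95
  expect_true(all(abs(w_delta - w_boot) / w_boot < 0.30))
})

test_that("tidy and glance summarize curve fits", {
  ds <- simulate_cort_data()
  fit <- fit_curve(ds, "logistic")
  td <- tidy(fit)
  expect_equal(td$term, c("a", "b", "x0", "shape"))
  expect_true(all(td$std.error > 0))
  gl <- glance(fit)
  expect_equal(gl$aicc, aicc(fit$log_lik, 4, 63))
  expect_s3_class(autoplot(fit), "ggplot")
})
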