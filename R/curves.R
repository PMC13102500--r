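#' Logistic CORT mean function
#'
#' Sigmoidal mean of plasma corticosterone over time since capture:
#' `a / (1 + exp(-b * (t - x0)))`. `a` is the asymptotic maximum (ng/ml),
#' `x0` the inflection time (minutes) at which the mean equals `a/2` and the
#' rate of increase is greatest, and `b` the slope (per minute) controlling
#' how fast levels rise around `x0`. Evaluation is overflow-safe for
#' arbitrarily large `|b * (t - x0)|`.
#'
#' @param time Time since capture, minutes (vectorized).
#' @param a Asymptotic maximum CORT, ng/ml (> 0).
#' @param b Rate parameter, per minute.
#' @param x0 Inflection time, minutes.
#' @return Mean CORT in ng/ml.
#' @export
#' @examples
#' logistic_mean(25, a = 45, b = 0.12, x0 = 25) # a/2 at the inflection
logistic_mean <- function(time, a, b, x0) {
  a * plogis(b * (time - x0))
}

#' Quadratic CORT mean function
#'
#' `a + b * t + c * t^2`: intercept `a` is the baseline CORT at time zero,
#' `b` the linear time effect and `c` the curvature (negative `c` gives a
#' peak at `t = -b / (2c)` followed by a decline).
#'
#' @param time Time since capture, minutes (vectorized).
#' @param a Intercept, ng/ml.
#' @param b Linear coefficient, ng/ml per minute.
#' @param c Curvature, ng/ml per minute^2.
#' @return Mean CORT in ng/ml (may be non-positive; such fits are rejected
#'   by the gamma likelihood).
#' @export
quadratic_mean <- function(time, a, b, c) {
  a + b * time + c * time^2
}

# Mean at observed times for a given model / natural-scale parameter list.
curve_mu <- function(model, params, time) {
  switch(model,
    null = rep(params$mu, length(time)),
    logistic = logistic_mean(time, params$a, params$b, params$x0),
    quadratic = quadratic_mean(time, params$a, params$b, params$c),
    abort(paste0("unknown model: ", model))
  )
}

# Gamma log-density in the (shape k, mean mu) parameterization,
# scale = mu / k. Written out explicitly; the test suite checks it against
# direct dgamma() summation.
gamma_loglik_terms <- function(y, mu, shape) {
  shape * log(shape / mu) + (shape - 1) * log(y) - shape * y / mu -
    lgamma(shape)
}

#' Negative gamma log-likelihood of a CORT mean model
#'
#' The objective minimized by [fit_curve()]: minus the sum of gamma
#' log-densities with shape `shape` and per-observation mean given by the
#' chosen mean function. Parameter values for which any predicted mean is
#' non-positive (or `shape <= 0`) return `Inf`, marking the region
#' infeasible for a gamma model.
#'
#' @param data A data frame with `time_min` and `cort_ng_ml`.
#' @param model `"null"`, `"logistic"` or `"quadratic"`.
#' @param mean_params Named list of mean parameters: `mu` for the null
#'   model, `a, b, x0` for logistic, `a, b, c` for quadratic.
#' @param shape Gamma shape (> 0).
#' @return The negative log-likelihood (non-negative objective; `Inf` when
#'   infeasible).
#' @export
#' @examples
#' d <- tibble::tibble(time_min = 0, cort_ng_ml = 1)
#' gamma_negloglik(d, "null", list(mu = 1), shape = 1) # exp(-1) density -> 1
gamma_negloglik <- function(data, model, mean_params, shape) {
  y <- data$cort_ng_ml
  mu <- curve_mu(model, mean_params, data$time_min)
  if (shape <= 0 || any(!is.finite(mu)) || any(mu <= 0)) return(Inf)
  -sum(gamma_loglik_terms(y, mu, shape))
}

# --- parameter transforms -------------------------------------------------
# Optimization runs on an unconstrained scale: log for strictly positive
# parameters (a, mu, shape), identity for the rest. The quadratic mean keeps
# its natural coefficients and relies on the Inf barrier for positivity.

curve_par_info <- function(model) {
  switch(model,
    null = list(names = c("mu", "shape"), log = c(TRUE, TRUE)),
    logistic = list(names = c("a", "b", "x0", "shape"),
                    log = c(TRUE, FALSE, FALSE, TRUE)),
    quadratic = list(names = c("a", "b", "c", "shape"),
                     log = c(FALSE, FALSE, FALSE, TRUE)),
    abort(paste0("unknown model: ", model))
  )
}

theta_to_params <- function(model, theta) {
  info <- curve_par_info(model)
  nat <- ifelse(info$log, exp(theta), theta)
  p <- as.list(nat)
  names(p) <- info$names
  p
}

params_to_theta <- function(model, params) {
  info <- curve_par_info(model)
  nat <- unlist(params[info$names], use.names = FALSE)
  nat[info$log] <- log(nat[info$log])
  nat
}

curve_nll_theta <- function(theta, model, data) {
  if (any(!is.finite(theta))) return(Inf)
  p <- theta_to_params(model, theta)
  gamma_negloglik(data, model, p[-length(p)], p$shape)
}

# Moment-style shape start from the spread of y around a candidate mean:
# var(y / mu) ~ 1 / shape.
start_shape <- function(y, mu) {
  u <- y / pmax(mu, 1e-8)
  v <- var(u)
  if (!is.finite(v) || v <= 0) v <- 0.25
  min(max(1 / v, 0.05), 1e7)
}

curve_starts <- function(model, data) {
  t <- data$time_min
  y <- data$cort_ng_ml
  if (model == "null") {
    mu0 <- mean(y)
    return(list(list(mu = mu0, shape = start_shape(y, mu0))))
  }
  if (model == "logistic") {
    rng <- diff(range(t))
    starts <- list()
    for (a0 in c(max(y), 1.5 * max(y))) {
      for (x00 in unique(c(median(t), mean(t)))) {
        for (b0 in unique(c(4 / rng, 0.1))) {
          mu0 <- logistic_mean(t, a0, b0, x00)
          starts <- c(starts, list(list(a = a0, b = b0, x0 = x00,
                                        shape = start_shape(y, mu0))))
        }
      }
    }
    return(starts)
  }
  # quadratic: least-squares start shifted into feasibility, plus a flat one
  co <- tryCatch(coef(stats::lm(y ~ t + I(t^2))), error = function(e) NULL)
  starts <- list()
  if (!is.null(co) && all(is.finite(co))) {
    p <- list(a = co[[1]], b = co[[2]], c = co[[3]])
    mu0 <- quadratic_mean(t, p$a, p$b, p$c)
    if (min(mu0) <= 0) {
      p$a <- p$a + (0.05 * mean(y) - min(mu0))
      mu0 <- quadratic_mean(t, p$a, p$b, p$c)
    }
    p$shape <- start_shape(y, mu0)
    starts <- c(starts, list(p))
  }
  starts <- c(starts, list(list(a = mean(y), b = 0, c = 0,
                                shape = start_shape(y, mean(y)))))
  starts
}

# Simplex stage on every start, gradient polish on the best two. Returns the
# best optim() result plus bookkeeping.
optimize_multistart <- function(nll, starts_theta) {
  runs <- purrr::map(starts_theta, function(th0) {
    v0 <- nll(th0)
    if (!is.finite(v0)) return(NULL)
    tryCatch(
      optim(th0, nll, method = "Nelder-Mead",
            control = list(maxit = 1000, reltol = 1e-8)),
      error = function(e) NULL
    )
  })
  keep <- !vapply(runs, is.null, logical(1))
  runs <- runs[keep]
  if (length(runs) == 0) {
    abort("curve fitting failed: no feasible start converged")
  }
  ord <- order(vapply(runs, function(r) r$value, numeric(1)))
  polish <- function(r) {
    p <- tryCatch(
      optim(r$par, nll, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-9)),
      error = function(e) NULL
    )
    if (!is.null(p) && is.finite(p$value) && p$value <= r$value) p else r
  }
  best <- purrr::map(ord[seq_len(min(2, length(ord)))],
                     function(i) polish(runs[[i]]))
  vals <- vapply(best, function(r) r$value, numeric(1))
  res <- best[[which.min(vals)]]
  list(result = res, n_starts = length(starts_theta))
}

#' Fit a gamma-likelihood CORT time-course model
#'
#' Jointly maximizes the gamma log-likelihood over the mean parameters and
#' the gamma shape for one of three mean models of CORT versus time since
#' capture: constant (`"null"`), logistic growth (`"logistic"`) or
#' quadratic (`"quadratic"`). Positivity-constrained parameters (`a` of the
#' logistic, the constant mean, the shape) are optimized on the log scale;
#' the quadratic mean keeps its natural coefficients with an infinite
#' objective outside the positive-mean region. Optimization runs a
#' Nelder-Mead stage from several data-driven starts followed by a BFGS
#' polish; the best value over all starts wins. The parameter covariance is
#' the inverse observed information (numerical Hessian) at the optimum, on
#' the transformed scale.
#'
#' Parameter counts follow the shared-shape bookkeeping: `k` counts the
#' mean parameters plus one for the gamma shape (2 for the null model, 4
#' for logistic and quadratic), and `resid_df = n -` (number of mean
#' parameters).
#'
#' @param data A data frame with `time_min` and `cort_ng_ml` (all > 0).
#' @param model `"null"`, `"logistic"` or `"quadratic"`.
#' @return A `cort_fit` object: a list with elements `model`, `params`
#'   (natural scale), `shape`, `log_lik`, `n`, `k`, `resid_df`, `cov`
#'   (transformed scale), `converged`, `n_starts_used`, `fitted` and the
#'   fitting data. Supports [tidy()], [glance()], [logLik()],
#'   [predict_with_ci()] and [autoplot()].
#' @export
#' @examples
#' ds <- simulate_cort_data()
#' fit <- fit_curve(ds, "logistic")
#' glance(fit)
fit_curve <- function(data, model = c("logistic", "quadratic", "null")) {
  model <- rlang::arg_match(model)
  if (!all(c("time_min", "cort_ng_ml") %in% names(data))) {
    abort("data must contain time_min and cort_ng_ml")
  }
  y <- data$cort_ng_ml
  t <- data$time_min
  if (length(y) == 0) abort("cannot fit an empty dataset")
  if (any(!is.finite(y)) || any(y <= 0)) {
    abort("cort_ng_ml must be strictly positive (gamma support)")
  }
  n <- length(y)
  k <- if (model == "null") 2L else 4L
  if (n < k + 1) abort(paste0("need at least ", k + 1, " observations"))
  if (model != "null" && length(unique(t)) < 2) {
    abort("times must not all be identical for a time-course model")
  }

  dat <- tibble::tibble(time_min = t, cort_ng_ml = y)
  nll <- function(theta) curve_nll_theta(theta, model, dat)
  starts <- purrr::map(curve_starts(model, dat),
                       function(p) params_to_theta(model, p))
  opt <- optimize_multistart(nll, starts)
  res <- opt$result

  theta <- res$par
  info <- curve_par_info(model)
  names(theta) <- ifelse(info$log, paste0("log_", info$names), info$names)
  p <- theta_to_params(model, theta)
  mu_hat <- curve_mu(model, p[-length(p)], t)

  H <- tryCatch(optimHess(res$par, nll), error = function(e) NULL)
  V <- NULL
  if (!is.null(H) && all(is.finite(H))) {
    V <- tryCatch(solve(H), error = function(e) NULL)
  }
  if (is.null(V)) {
    V <- matrix(NA_real_, length(theta), length(theta))
  }
  dimnames(V) <- list(names(theta), names(theta))

  structure(list(
    model = model,
    params = p[-length(p)],
    shape = p$shape,
    log_lik = -res$value,
    n = n,
    k = k,
    resid_df = n - (k - 1L),
    cov = V,
    theta = theta,
    converged = res$convergence == 0,
    n_starts_used = opt$n_starts,
    fitted = mu_hat,
    data = dat
  ), class = "cort_fit")
}

#' @export
logLik.cort_fit <- function(object, ...) {
  structure(object$log_lik, df = object$k, nobs = object$n,
            class = "logLik")
}

#' @export
print.cort_fit <- function(x, ...) {
  cat("Gamma-likelihood CORT model: ", x$model, "\n", sep = "")
  cat("  n = ", x$n, ", k = ", x$k, ", resid. df = ", x$resid_df, "\n",
      sep = "")
  cat("  parameters: ",
      paste(names(x$params),
            signif(unlist(x$params), 5), sep = " = ", collapse = ", "),
      "\n  shape = ", signif(x$shape, 5),
      ", logLik = ", signif(x$log_lik, 7),
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  invisible(x)
}

# Mean at arbitrary times as a function of the transformed parameter vector
# (for delta-method gradients).
mean_from_theta <- function(model, theta, times) {
  p <- theta_to_params(model, theta)
  curve_mu(model, p[-length(p)], times)
}

#' Predicted CORT with 95% confidence bands
#'
#' Predicted mean CORT over a time grid with a 95% confidence band. The
#' default band is the delta method: the gradient of the mean with respect
#' to the estimated (transformed) parameters, the observed-information
#' covariance from the fit, and normal quantiles; the lower limit is floored
#' at 0. A parametric bootstrap alternative refits the model to datasets
#' simulated from the fitted gamma model at the observed design times and
#' takes pointwise quantiles of the refitted means.
#'
#' @param fit A converged `cort_fit`.
#' @param times Numeric vector of times (minutes) at which to predict.
#' @param level Confidence level (default 0.95).
#' @param method `"delta"` (default) or `"bootstrap"`.
#' @param n_boot Number of bootstrap refits when `method = "bootstrap"`.
#' @param seed Optional seed for the bootstrap.
#' @return A tibble with columns `time`, `mean`, `lo95`, `hi95`. If the
#'   covariance is unavailable (singular information) the band columns are
#'   `NA` and the mean is still returned.
#' @export
predict_with_ci <- function(fit, times, level = 0.95,
                            method = c("delta", "bootstrap"),
                            n_boot = 1000, seed = NULL) {
  method <- rlang::arg_match(method)
  if (!inherits(fit, "cort_fit")) abort("fit must be a cort_fit")
  if (!fit$converged) abort("fit did not converge; no predictions")
  mu <- mean_from_theta(fit$model, fit$theta, times)

  if (method == "delta") {
    V <- fit$cov
    if (any(!is.finite(V))) {
      lo <- hi <- rep(NA_real_, length(times))
    } else {
      z <- qnorm(1 - (1 - level) / 2)
      h <- pmax(abs(fit$theta), 1) * 1e-6
      grads <- vapply(seq_along(fit$theta), function(j) {
        up <- dn <- fit$theta
        up[j] <- up[j] + h[j]
        dn[j] <- dn[j] - h[j]
        (mean_from_theta(fit$model, up, times) -
            mean_from_theta(fit$model, dn, times)) / (2 * h[j])
      }, numeric(length(times)))
      grads <- matrix(grads, nrow = length(times))
      se <- sqrt(pmax(rowSums((grads %*% V) * grads), 0))
      lo <- pmax(mu - z * se, 0)
      hi <- mu + z * se
    }
  } else {
    sim_one <- function() {
      yb <- rgamma(fit$n, shape = fit$shape,
                   scale = fitted_means(fit) / fit$shape)
      db <- tibble::tibble(time_min = fit$data$time_min, cort_ng_ml = yb)
      nll <- function(theta) curve_nll_theta(theta, fit$model, db)
      r <- tryCatch(
        optim(unname(fit$theta), nll, method = "Nelder-Mead",
              control = list(maxit = 500, reltol = 1e-8)),
        error = function(e) NULL
      )
      if (is.null(r)) return(rep(NA_real_, length(times)))
      mean_from_theta(fit$model, r$par, times)
    }
    draw <- function() {
      m <- vapply(seq_len(n_boot), function(i) sim_one(),
                  numeric(length(times)))
      matrix(m, nrow = length(times))
    }
    M <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    qs <- apply(M, 1, quantile,
                probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                na.rm = TRUE)
    lo <- pmax(qs[1, ], 0)
    hi <- qs[2, ]
  }
  tibble::tibble(time = times, mean = mu, lo95 = lo, hi95 = hi)
}

fitted_means <- function(fit) fit$fitted

#' @export
tidy.cort_fit <- function(x, ...) {
  info <- curve_par_info(x$model)
  est <- c(unlist(x$params, use.names = FALSE), x$shape)
  se_theta <- sqrt(diag(x$cov))
  # delta back-transform for log-scale parameters: se(exp(th)) = exp(th)*se
  se <- ifelse(info$log, est * se_theta, se_theta)
  tibble::tibble(term = info$names, estimate = est, std.error = se)
}

#' @export
glance.cort_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, n = x$n, k = x$k, resid_df = x$resid_df,
    log_lik = x$log_lik, aicc = aicc(x$log_lik, x$k, x$n),
    converged = x$converged, n_starts_used = x$n_starts_used
  )
}

#' Plot a fitted CORT time-course model
#'
#' Observed CORT against time since capture with the fitted mean curve and
#' its 95% delta-method confidence ribbon.
#'
#' @param object A `cort_fit`.
#' @param n_grid Number of grid points for the curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cort_fit <- function(object, n_grid = 200, ...) {
  rng <- range(object$data$time_min)
  grid <- seq(rng[1], rng[2], length.out = n_grid)
  band <- predict_with_ci(object, grid)
  ggplot2::ggplot(band, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo95, ymax = .data$hi95),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), colour = "steelblue") +
    ggplot2::geom_point(
      data = object$data,
      ggplot2::aes(x = .data$time_min, y = .data$cort_ng_ml),
      alpha = 0.6
    ) +
    ggplot2::labs(x = "Time since capture (min)",
                  y = "Plasma CORT (ng/ml)",
                  title = paste0("Gamma ", object$model, " model")) +
    ggplot2::theme_minimal()
}
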