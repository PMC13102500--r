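#' Small-sample-corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k + 1) / (n - k - 1)`. The correction term
#' vanishes as `n` grows, recovering the ordinary AIC.
#'
#' @param log_lik Maximized log-likelihood.
#' @param k Number of estimated parameters (including the gamma shape).
#' @param n Number of observations; must exceed `k + 1`.
#' @return The AICc value.
#' @export
#' @examples
#' aicc(-5, 2, 10)
aicc <- function(log_lik, k, n) {
  if (any(n <= k + 1)) abort("AICc requires n > k + 1")
  -2 * log_lik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from AICc values
#'
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` with `delta` taken
#' relative to the smallest AICc in the set; invariant to adding a constant
#' to every AICc, and summing to 1.
#'
#' @param aicc_values Numeric vector of (unrounded) AICc values.
#' @return Weights summing to 1.
#' @export
#' @examples
#' akaike_weights(c(456.7, 459.5, 568.0))
akaike_weights <- function(aicc_values) {
  if (length(aicc_values) == 0 || any(!is.finite(aicc_values))) {
    abort("aicc_values must be non-empty and finite")
  }
  d <- aicc_values - min(aicc_values)
  w <- exp(-d / 2)
  w / sum(w)
}

# Shape-free gamma deviance: 2 * sum(-log(y/mu) + (y - mu)/mu).
gamma_deviance <- function(y, mu) {
  2 * sum(-log(y / mu) + (y - mu) / mu)
}

model_response <- function(fit) {
  if (inherits(fit, "cort_fit")) return(fit$data$cort_ng_ml)
  if (inherits(fit, "cort_gamma_glm")) return(fit$data$cort_ng_ml)
  abort("fit must be a cort_fit or cort_gamma_glm")
}

#' Deviance pseudo-R2 of a gamma model
#'
#' Explanatory power relative to the constant-mean null:
#' `1 - D(fit) / D(null)` where `D` is the shape-free gamma deviance
#' `2 * sum(-log(y/mu) + (y - mu)/mu)`. A likelihood-ratio variant,
#' `1 - exp((2/n) * (logLik_null - logLik_fit))`, is available via
#' [pseudo_r2_lr()] for comparison.
#'
#' @param fit A `cort_fit` or `cort_gamma_glm`.
#' @param null_fit The intercept-only fit of the same data.
#' @return Pseudo-R2 in \[0, 1\] for nested-versus-null comparisons.
#' @export
pseudo_r2 <- function(fit, null_fit) {
  y <- model_response(fit)
  y0 <- model_response(null_fit)
  if (length(y) != length(y0) ||
      !isTRUE(all.equal(sort(y), sort(y0)))) {
    abort("fit and null_fit must come from the same dataset")
  }
  d0 <- gamma_deviance(y0, fitted_of(null_fit))
  if (d0 <= 0) abort("null deviance is zero (all observations identical)")
  1 - gamma_deviance(y, fitted_of(fit)) / d0
}

fitted_of <- function(fit) {
  if (inherits(fit, "cort_fit")) fit$fitted else fit$fitted
}

#' @rdname pseudo_r2
#' @export
pseudo_r2_lr <- function(fit, null_fit) {
  ll1 <- as.numeric(logLik(fit))
  ll0 <- as.numeric(logLik(null_fit))
  n <- length(model_response(fit))
  1 - exp((2 / n) * (ll0 - ll1))
}

#' Compare CORT time-course models by AICc
#'
#' Fits the constant (null), logistic and quadratic gamma mean models to
#' the same dataset and assembles a comparison table: residual df, AICc,
#' delta-AICc, parameter count `k` (mean parameters plus shared gamma
#' shape: 2 for the null, 4 for logistic and quadratic), Akaike weight
#' (computed from unrounded AICc), and deviance pseudo-R2 relative to the
#' null (blank for the null reference row, with the likelihood-ratio
#' variant alongside). Rows are sorted by AICc.
#'
#' @param data A data frame with `time_min` and `cort_ng_ml`.
#' @return A `cort_model_comparison` tibble with columns `name`,
#'   `resid_df`, `aicc`, `delta_aicc`, `k`, `weight`, `pseudo_r2`,
#'   `pseudo_r2_lr`, `converged`; the three `cort_fit` objects are attached
#'   as the `"fits"` attribute.
#' @export
#' @examples
#' ds <- simulate_cort_data()
#' compare_time_models(ds)
compare_time_models <- function(data) {
  fits <- list(
    null = fit_curve(data, "null"),
    logistic = fit_curve(data, "logistic"),
    quadratic = fit_curve(data, "quadratic")
  )
  rows <- purrr::imap(fits, function(f, nm) {
    tibble::tibble(
      name = nm,
      resid_df = f$resid_df,
      aicc = aicc(f$log_lik, f$k, f$n),
      k = f$k,
      pseudo_r2 = if (nm == "null") NA_real_ else pseudo_r2(f, fits$null),
      pseudo_r2_lr = if (nm == "null") NA_real_ else {
        pseudo_r2_lr(f, fits$null)
      },
      converged = f$converged
    )
  })
  tab <- dplyr::bind_rows(rows)
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  tab$weight <- akaike_weights(tab$aicc)
  tab <- tab |>
    dplyr::arrange(.data$aicc) |>
    dplyr::select("name", "resid_df", "aicc", "delta_aicc", "k", "weight",
                  "pseudo_r2", "pseudo_r2_lr", "converged")
  attr(tab, "fits") <- fits
  class(tab) <- c("cort_model_comparison", class(tab))
  tab
}

#' Select the supported model by the parsimony rule
#'
#' Among models within `threshold` AICc units of the best (default 2, the
#' conventional cutoff for substantial support), the simplest — smallest
#' parameter count `k`, ties broken by name order — is selected; the
#' best-AICc model always belongs to that set.
#'
#' @param rows A comparison table with `name`, `delta_aicc` and `k`
#'   columns (e.g. from [compare_time_models()] or [fit_sex_family()]).
#' @param threshold AICc-difference cutoff (default 2).
#' @return The selected model's name.
#' @export
select_best <- function(rows, threshold = 2) {
  if (nrow(rows) == 0) abort("empty comparison table")
  cand <- rows[rows$delta_aicc < threshold, , drop = FALSE]
  if (nrow(cand) == 0) {
    cand <- rows[rows$delta_aicc == 0, , drop = FALSE]
  }
  cand <- cand[order(cand$k, cand$name), , drop = FALSE]
  cand$name[[1]]
}

#' The sex-varying logistic model family
#'
#' The eight-member family used to test for sex differences in the CORT
#' time course: a null logistic model in which both sexes share all
#' parameters, plus the seven models in which each non-empty subset of
#' `{a, b, x0}` varies by sex. The gamma shape is always shared, so the
#' parameter count is `k = 3 + |varying| + 1`.
#'
#' @return A tibble with columns `name`, `varying` (list of character
#'   vectors) and `k`, giving k values 4, 5, 5, 5, 6, 6, 6, 7.
#' @export
#' @examples
#' build_sex_model_family()
build_sex_model_family <- function() {
  pars <- c("a", "b", "x0")
  subsets <- list(character(0))
  for (m in 1:3) {
    cm <- combn(pars, m, simplify = FALSE)
    subsets <- c(subsets, cm)
  }
  tibble::tibble(
    name = vapply(subsets, function(s) {
      if (length(s) == 0) "null" else paste(s, collapse = "+")
    }, character(1)),
    varying = subsets,
    k = vapply(subsets, function(s) 3L + length(s) + 1L, integer(1))
  )
}

# Fit one sex-varying logistic member. Parameters varying by sex get a
# female and a male copy; the rest (and the shape) are shared. Warm-started
# from the pooled logistic fit so each member's likelihood is never below
# the null member's.
fit_sex_logistic <- function(data, varying, pooled) {
  sex <- data$sex
  is_f <- sex == "female"
  t <- data$time_min
  y <- data$cort_ng_ml
  pars <- c("a", "b", "x0")
  layout <- lapply(pars, function(p) if (p %in% varying) c("f", "m") else "s")
  names(layout) <- pars
  pnames <- unlist(purrr::imap(layout, function(l, p) {
    if (identical(l, "s")) p else paste0(p, "_", c("female", "male"))
  }))
  npar <- length(pnames)
  logscale <- grepl("^a", pnames) # a (and copies) positive -> log scale

  unpack <- function(theta) {
    nat <- ifelse(c(logscale, TRUE), exp(theta), theta)
    idx <- 1
    out <- list()
    for (p in pars) {
      if (p %in% varying) {
        out[[p]] <- c(female = nat[idx], male = nat[idx + 1])
        idx <- idx + 2
      } else {
        out[[p]] <- c(female = nat[idx], male = nat[idx])
        idx <- idx + 1
      }
    }
    out$shape <- nat[length(nat)]
    out
  }

  mu_of <- function(pl) {
    a <- ifelse(is_f, pl$a["female"], pl$a["male"])
    b <- ifelse(is_f, pl$b["female"], pl$b["male"])
    x0 <- ifelse(is_f, pl$x0["female"], pl$x0["male"])
    logistic_mean(t, a, b, x0)
  }

  nll <- function(theta) {
    if (any(!is.finite(theta))) return(Inf)
    pl <- unpack(theta)
    mu <- mu_of(pl)
    if (pl$shape <= 0 || any(mu <= 0) || any(!is.finite(mu))) return(Inf)
    -sum(gamma_loglik_terms(y, mu, pl$shape))
  }

  pool <- pooled$params
  pack_start <- function(jitter) {
    th <- numeric(0)
    for (p in pars) {
      v <- pool[[p]]
      if (p %in% varying) {
        vv <- c(v, v) * (if (jitter) c(0.9, 1.1) else c(1, 1))
        if (p == "x0" && jitter) vv <- c(v - 3, v + 3)
        th <- c(th, vv)
      } else {
        th <- c(th, v)
      }
    }
    th <- c(th, pooled$shape)
    lg <- c(logscale, TRUE)
    th[lg] <- log(th[lg])
    th
  }
  # log() of non-positive shared b start would be NaN; only a-copies use log
  starts <- list(pack_start(FALSE), pack_start(TRUE))
  starts <- purrr::keep(starts, function(s) all(is.finite(s)))

  opt <- optimize_multistart(nll, starts)
  res <- opt$result
  pl <- unpack(res$par)
  k <- 3L + length(varying) + 1L

  structure(list(
    model = "logistic_sex",
    varying = varying,
    params = pl[pars],
    shape = pl$shape,
    log_lik = -res$value,
    n = length(y),
    k = k,
    resid_df = length(y) - (k - 1L),
    converged = res$convergence == 0,
    n_starts_used = opt$n_starts,
    fitted = mu_of(pl),
    data = tibble::tibble(time_min = t, cort_ng_ml = y, sex = sex)
  ), class = "cort_sex_fit")
}

#' @export
logLik.cort_sex_fit <- function(object, ...) {
  structure(object$log_lik, df = object$k, nobs = object$n,
            class = "logLik")
}

#' Fit and compare the sex-varying logistic model family
#'
#' Fits all eight members of [build_sex_model_family()] by gamma maximum
#' likelihood — parameters in the `varying` set duplicated per sex, the
#' rest and the gamma shape shared — and compares them by AICc with Akaike
#' weights. Every member is warm-started from the pooled (no-sex-effect)
#' logistic fit, so the family respects the nesting of the null member.
#'
#' @param data A data frame with `time_min`, `cort_ng_ml` and `sex`
#'   (`"female"` / `"male"` for every row; a sex with fewer than 4 birds
#'   makes its per-sex parameters inestimable and is an error).
#' @return A `cort_model_comparison` tibble with one row per family member
#'   (`name`, `resid_df`, `aicc`, `delta_aicc`, `k`, `weight`,
#'   `converged`), sorted by AICc; fits attached as the `"fits"` attribute.
#' @export
#' @examples
#' ds <- simulate_cort_data()
#' fit_sex_family(ds)
fit_sex_family <- function(data) {
  if (!"sex" %in% names(data)) abort("data must contain a sex column")
  if (!all(data$sex %in% c("female", "male"))) {
    abort("all rows must have known sex (female or male)")
  }
  tab <- table(data$sex)
  if (length(tab) < 2 || any(tab < 4)) {
    abort("each sex needs at least 4 birds to estimate per-sex parameters")
  }
  pooled <- fit_curve(data, "logistic")
  family <- build_sex_model_family()
  fits <- purrr::map(family$varying, function(v) {
    fit_sex_logistic(data, v, pooled)
  })
  names(fits) <- family$name
  rows <- purrr::map2(fits, family$name, function(f, nm) {
    tibble::tibble(
      name = nm, resid_df = f$resid_df,
      aicc = aicc(f$log_lik, f$k, f$n), k = f$k,
      log_lik = f$log_lik, converged = f$converged
    )
  })
  out <- dplyr::bind_rows(rows)
  out$delta_aicc <- out$aicc - min(out$aicc)
  out$weight <- akaike_weights(out$aicc)
  out <- out |>
    dplyr::arrange(.data$aicc) |>
    dplyr::select("name", "resid_df", "aicc", "delta_aicc", "k", "weight",
                  "log_lik", "converged")
  attr(out, "fits") <- fits
  class(out) <- c("cort_model_comparison", class(out))
  out
}

#' Plot an AICc model-comparison table
#'
#' Akaike weights per model, annotated with delta-AICc.
#'
#' @param object A `cort_model_comparison` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cort_model_comparison <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$name <- factor(df$name, levels = rev(df$name))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$weight, y = .data$name)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("ΔAICc %.1f", .data$delta_aicc)),
      hjust = -0.05, size = 3
    ) +
    ggplot2::xlim(0, 1.15) +
    ggplot2::labs(x = "Akaike weight", y = NULL) +
    ggplot2::theme_minimal()
}
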