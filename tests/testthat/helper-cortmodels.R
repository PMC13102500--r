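# Shared fixtures, all generated in code.

toy_table <- function() {
  tibble::tibble(
    bird_id = c("b1", "b2", "b3"),
    treatment = c("shot", "baseline", "trapped"),
    sex = c("female", "male", "unknown"),
    time_min = c(0, 2.5, 45),
    cort_ng_ml = c(2.4, 3.99, 38.75)
  )
}

# Gamma observations on an exact logistic time course.
logistic_gamma_data <- function(n, a, b, x0, shape, seed,
                                tmin = 0, tmax = 210) {
  withr::with_seed(seed, {
    t <- runif(n, tmin, tmax)
    mu <- a / (1 + exp(-b * (t - x0)))
    tibble::tibble(
      bird_id = sprintf("s%04d", seq_len(n)),
      treatment = "trapped", sex = rep_len(c("female", "male"), n),
      time_min = t,
      cort_ng_ml = rgamma(n, shape = shape, scale = mu / shape)
    )
  })
}

# Constant-mean gamma observations (no time effect).
constant_gamma_data <- function(n, mu, shape, seed, tmax = 210) {
  withr::with_seed(seed, tibble::tibble(
    bird_id = sprintf("c%04d", seq_len(n)),
    treatment = "trapped", sex = rep_len(c("female", "male"), n),
    time_min = runif(n, 0, tmax),
    cort_ng_ml = rgamma(n, shape = shape, scale = mu / shape)
  ))
}

# Independent oracle for the gamma log-likelihood: direct dgamma summation.
oracle_gamma_loglik <- function(y, mu, shape) {
  sum(dgamma(y, shape = shape, scale = mu / shape, log = TRUE))
}
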