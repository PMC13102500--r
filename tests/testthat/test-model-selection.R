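test_that("AICc follows the closed form and its large-n limit", {
  expect_equal(aicc(-5, 2, 10), 10 + 4 + 12 / 7)
  expect_equal(aicc(-5, 2, 10), 15.7142857, tolerance = 1e-7)
  # converges to AIC as n grows
  expect_lt(abs(aicc(-100, 3, 1e7) - (200 + 6)), 1e-3)
  # correction term for k = 4, n = 63
  expect_equal(aicc(0, 4, 63) - 8, 2 * 4 * 5 / 58)
  expect_error(aicc(-5, 9, 10), "n > k")
  # strictly increasing in k at fixed log-lik and n
  ks <- 1:8
  vals <- vapply(ks, function(k) aicc(-50, k, 63), numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("Akaike weights normalize exp(-delta/2) and shift-invariantly", {
  expect_equal(akaike_weights(123.4), 1)
  expect_equal(akaike_weights(c(10, 10)), c(0.5, 0.5))
  w <- akaike_weights(c(0, 2.8, 111.4))
  expect_equal(round(w[1:2], 4), c(0.8022, 0.1978))
  expect_lt(w[3], 1e-23)
  expect_equal(sum(w), 1, tolerance = 1e-9)
  expect_equal(akaike_weights(c(0, 2.8, 111.4) + 456.7), w)
})

test_that("deviance pseudo-R2 spans its null and saturated limits", {
  ds <- simulate_cort_data()
  null <- fit_curve(ds, "null")
  expect_equal(pseudo_r2(null, null), 0)
  # noiseless limit: logistic truth at shape 1e4 explains almost everything
  d <- logistic_gamma_data(150, 45, 0.12, 25, shape = 1e4, seed = 31)
  fit <- fit_curve(d, "logistic")
  expect_gt(pseudo_r2(fit, fit_curve(d, "null")), 0.99)
  # lr variant lives on the same scale
  r2lr <- pseudo_r2_lr(fit, fit_curve(d, "null"))
  expect_gt(r2lr, 0.9)
  expect_error(pseudo_r2(fit, null), "same dataset")
})

test_that("comparison tables carry the study's df and k bookkeeping", {
  ds <- simulate_cort_data()
  cmp <- compare_time_models(ds)
  expect_equal(nrow(cmp), 3)
  expect_equal(cmp$resid_df[cmp$name == "null"], 62L)
  expect_equal(sort(cmp$resid_df), c(60L, 60L, 62L))
  expect_equal(sort(cmp$k), c(2L, 4L, 4L))
  expect_equal(sum(cmp$delta_aicc == 0), 1L)
  expect_true(all(cmp$delta_aicc >= 0))
  expect_equal(sum(cmp$weight), 1, tolerance = 1e-9)
  expect_true(is.na(cmp$pseudo_r2[cmp$name == "null"]))
  r2 <- cmp$pseudo_r2[!is.na(cmp$pseudo_r2)]
  expect_true(all(r2 >= 0 & r2 <= 1))
})

test_that("comparison is invariant to the row order of the data", {
  ds <- simulate_cort_data(sim_config(seed = 88))
  cmp1 <- compare_time_models(ds)
  cmp2 <- compare_time_models(withr::with_seed(1, ds[sample(nrow(ds)), ]))
  expect_equal(tibble::as_tibble(cmp1), tibble::as_tibble(cmp2),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("model selection matches the generating truth on seeded data", {
  d <- logistic_gamma_data(63, 45, 0.15, 20, shape = 6, seed = 7)
  cmp <- compare_time_models(d)
  expect_equal(cmp$name[cmp$delta_aicc == 0], "logistic")
  expect_equal(select_best(cmp), "logistic")

  dc <- constant_gamma_data(63, 20, 5, seed = 13)
  expect_equal(select_best(compare_time_models(dc)), "null")
})

test_that("the parsimony rule picks the simplest supported model", {
  rows <- tibble::tibble(name = c("logistic", "null"),
                         delta_aicc = c(0, 1.5), k = c(4L, 2L))
  expect_equal(select_best(rows), "null") # within 2 -> simplest wins
  rows2 <- tibble::tibble(name = c("logistic", "quadratic"),
                          delta_aicc = c(0, 2.8), k = c(4L, 4L))
  expect_equal(select_best(rows2), "logistic") # only the delta-0 model left
  expect_equal(select_best(rows2[1, ]), "logistic")
  # equal k ties break by name order
  rows3 <- tibble::tibble(name = c("b", "a"), delta_aicc = c(0, 1), k = c(4L, 4L))
  expect_equal(select_best(rows3), "a")
})

test_that("the sex family is the null plus all subsets of {a, b, x0}", {
  fam <- build_sex_model_family()
  expect_equal(nrow(fam), 8)
  expect_equal(sort(fam$k), c(4L, 5L, 5L, 5L, 6L, 6L, 6L, 7L))
  expect_equal(fam$k[fam$name == "null"], 4L)
  expect_equal(fam$k[fam$name == "a"], 5L)
  expect_equal(fam$k[fam$name == "a+b+x0"], 7L)
  # brute-force enumeration oracle: all subsets, k = 3 + |subset| + 1
  all_subsets <- unlist(lapply(0:3, function(m) {
    combn(c("a", "b", "x0"), m, simplify = FALSE)
  }), recursive = FALSE)
  expect_equal(length(all_subsets), 8)
  expect_setequal(fam$k, vapply(all_subsets,
                                function(s) 4L + length(s), integer(1)))
})

test_that("sex-family fits respect nesting and structure", {
  ds <- simulate_cort_data(sim_config(seed = 21))
  tab <- fit_sex_family(ds)
  expect_equal(nrow(tab), 8)
  expect_equal(sum(tab$delta_aicc == 0), 1)
  ll_null <- tab$log_lik[tab$name == "null"]
  expect_true(all(tab$log_lik >= ll_null - 1e-6))
  # no simulated sex effect: the null stays within 2 AICc of the best
  expect_lt(tab$delta_aicc[tab$name == "null"], 2)

  bad <- ds
  bad$sex[1] <- "unknown"
  expect_error(fit_sex_family(bad), "known sex")
  few <- ds[c(which(ds$sex == "female")[1:3], which(ds$sex == "male")), ]
  expect_error(fit_sex_family(few), "at least 4")
})

test_that("a strong simulated sex effect in 'a' is detected", {
  cfg <- sim_config(
    n_shot = 0, n_baseline = 0, n_trapped = 200,
    n_female = 100, n_male = 100,
    curve_female = list(a = 30, b = 0.12, x0 = 25),
    curve_male = list(a = 60, b = 0.12, x0 = 25),
    seed = 99
  )
  tab <- fit_sex_family(simulate_cort_data(cfg))
  best <- select_best(tab)
  expect_match(best, "a") # selected model lets a vary by sex
  expect_gt(tab$delta_aicc[tab$name == "null"], 2)
})
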