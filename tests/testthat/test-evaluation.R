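test_that("p95 absolute error matches closed forms", {
  expect_equal(p95_abs_error(rep(0, 10)), 0)
  expect_equal(p95_abs_error(rep(c(0.05, -0.05), 50)), 0.05)
  set.seed(71)
  draws <- rnorm(1000, 0, 0.04)
  # half-normal 95th percentile = 1.96 sigma
  expect_equal(p95_abs_error(draws), 0.04 * qnorm(0.975),
               tolerance = 0.08)
  # permutation invariance
  e <- rnorm(50)
  expect_equal(p95_abs_error(e), p95_abs_error(rev(e)))
  expect_error(p95_abs_error(numeric(0)), class = "bg_empty")
})

test_that("agreement fraction counts errors within the bound", {
  expect_equal(clia_agreement(rep(0, 5), 0.04), 1)
  expect_equal(clia_agreement(c(0.01, 0.05, 0.03, 0.10), 0.04), 0.5)
  e <- rnorm(100)
  bounds <- c(0.5, 1, 2)
  fr <- vapply(bounds, clia_agreement, numeric(1), errors = e)
  expect_true(all(diff(fr) >= 0))
  expect_error(clia_agreement(e, 0), class = "bg_config")
})

test_that("range coverage uses interval intersection with the true bin", {
  # interval entirely inside the true bin
  expect_equal(range_coverage(7.35, 0.02, 7.36)$overall, 1)
  # boundary intersection: [7.42, 7.46] touches the >= 7.45 bin
  expect_equal(range_coverage(7.44, 0.02, 7.46)$overall, 1)
  # zero half-width reduces to point-in-bin classification
  expect_equal(range_coverage(7.29, 0, 7.31)$overall, 0)
  expect_equal(range_coverage(7.31, 0, 7.32)$overall, 1)
  pb <- range_coverage(c(7.2, 7.35, 7.5), 0.01,
                       c(7.25, 7.36, 7.55))$per_bin
  expect_equal(pb$n, c(1, 1, 1))
})

test_that("lag analysis bins errors and flags sparse bins", {
  lag <- c(1, 1.5, 3, 3.2, 5)
  err <- c(0.01, 0.02, 0.03, 0.04, 0.05)
  la <- lag_analysis(lag, err, bin_edges = c(0, 2, 4, 6), min_n = 3)
  expect_equal(nrow(la), 3)
  expect_equal(la$n, c(2, 2, 1))
  expect_true(all(la$low_n))
  # all rows in one bin reproduce the global p95
  la1 <- lag_analysis(rep(1, 5), err, bin_edges = c(0, 2))
  expect_equal(la1$p95, p95_abs_error(err))
  # empty bins are absent, not zero
  la2 <- lag_analysis(c(1, 1), c(0.1, 0.2), bin_edges = c(0, 2, 4))
  expect_equal(la2$bin, "0-2h")
})

test_that("Bland-Altman limits match their definition", {
  expect_equal(bland_altman(c(1, 2, 3), c(1, 2, 3)),
               list(mean_error = 0, lower = 0, upper = 0, sd = 0))
  ba <- bland_altman(c(1.1, 2.1, 3.1), c(1, 2, 3))
  expect_equal(ba$mean_error, 0.1, tolerance = 1e-12)
  expect_equal(ba$lower, 0.1, tolerance = 1e-12)
  set.seed(72)
  d <- rnorm(10000)
  ba2 <- bland_altman(d, rep(0, 10000))
  expect_equal(ba2$upper, 1.96, tolerance = 0.05)
  expect_equal(ba2$lower, -1.96, tolerance = 0.05)
  expect_error(bland_altman(1, 1), class = "bg_shape")
})

test_that("model comparison matches the exact Mann-Whitney enumeration", {
  set.seed(73)
  # identical error sets -> p near 1
  e <- rnorm(30)
  expect_gt(compare_models(e, e)$p_value, 0.9)
  # disjoint magnitude ranges -> overwhelming evidence
  a <- runif(20, 0, 0.1)
  b <- runif(20, 10, 20)
  expect_lt(compare_models(a, b)$p_value, 1e-5)
  # exact enumeration oracle at tiny n (no ties)
  x <- c(0.11, 0.23, 0.35, 0.52)
  y <- c(0.08, 0.19, 0.41, 0.77)
  expect_equal(compare_models(x, y)$p_value, exact_mwu_p(x, y),
               tolerance = 1e-12)
  x2 <- c(0.01, 0.02, 0.03, 0.04)
  y2 <- c(0.05, 0.06, 0.07, 0.9)
  expect_equal(compare_models(x2, y2)$p_value, exact_mwu_p(x2, y2),
               tolerance = 1e-12)
  # rank statistic: invariant under common monotone transforms
  expect_equal(compare_models(exp(x), exp(y))$p_value,
               compare_models(x, y)$p_value)
  expect_error(compare_models(numeric(0), e), class = "bg_empty")
})

make_predictions <- function(n = 400, seed = 74) {
  set.seed(seed)
  ph_truth <- rnorm(n, 7.38, 0.06)
  data.frame(ph_truth = ph_truth,
             ph_est = ph_truth + rnorm(n, 0, 0.03),
             paco2_truth = rnorm(n, 45, 8),
             paco2_est = rnorm(n, 45, 8),
             abstained = runif(n) < 0.2,
             lag_hours = runif(n, 0.5, 23),
             ph_half_width = runif(n, 0.01, 0.08))
}

test_that("evaluation report partitions samples and round-trips as JSON", {
  pred <- make_predictions()
  rep <- evaluation_report(pred)
  expect_equal(rep$n_total, 400)
  expect_equal(rep$n_estimated, sum(!pred$abstained))
  expect_equal(sum(rep$p95_ph_ranges$n), rep$n_estimated)
  expect_equal(sum(rep$p95_pco2_ranges$n), rep$n_estimated)
  expect_true(all(c(rep$clia_fraction_ph, rep$clia_fraction_pco2,
                    rep$abstention_rate,
                    rep$range_coverage$overall) >= 0))
  path <- withr::local_tempfile(fileext = ".json")
  write_evaluation_report(rep, path)
  back <- read_evaluation_report(path)
  expect_equal(back$p95_ph, rep$p95_ph, tolerance = 1e-12)
  expect_equal(back$p95_ph_ranges$p95, rep$p95_ph_ranges$p95,
               tolerance = 1e-12)
  expect_equal(back$bland_altman_ph$upper, rep$bland_altman_ph$upper,
               tolerance = 1e-12)
  expect_output(print(rep), "estimated")
})

test_that("two-observation patients make the two linkages coincide", {
  co <- simulate_cohort(bg_generator_config(n_patients = 40,
                                            mean_obs_per_patient = 6,
                                            seed = 75))
  co2 <- do.call(rbind, lapply(split(co, co$patient_id), utils::head, 2))
  rownames(co2) <- NULL
  train <- simulate_cohort(bg_generator_config(n_patients = 60,
                                               seed = 76))
  fv <- first_vs_previous_bg_analysis(train, co2)
  expect_equal(fv$p95_previous, fv$p95_first)
  expect_equal(fv$n_previous, fv$n_first)
})
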