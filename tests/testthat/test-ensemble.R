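make_ensemble <- function(n_patients = 150, seed = 50, target = "ph",
                          ...) {
  rows <- small_rows(n_patients = n_patients, seed = seed, ...)
  plan <- make_split_plan(rows, seed = seed)
  list(rows = rows, plan = plan,
       ens = bg_ensemble(rows, plan, target, lambda = 1))
}

test_that("ensemble uncertainty is the population variance of replicate predictions", {
  fx <- make_ensemble(60, 51)
  ens <- fx$ens
  # identical replicate models -> zero variance everywhere
  ens0 <- ens
  ens0$fold_models <- list(ens$final_model, ens$final_model)
  expect_equal(ensemble_uncertainty(ens0, fx$rows),
               rep(0, nrow(fx$rows)))
  # two replicates predicting 7.30 and 7.40 -> variance 0.0025
  row1 <- fx$rows[1, , drop = FALSE]
  mk_const <- function(v) {
    m <- ens$final_model
    m$weights[] <- 0
    # constant block with normalized basis sums to v for every z
    m$weights[".const", ] <- v
    m
  }
  ens2 <- ens
  ens2$fold_models <- list(mk_const(7.30), mk_const(7.40))
  expect_equal(ensemble_uncertainty(ens2, row1), 0.0025)
  # shift invariance: adding a constant to all replicate predictions
  ens3 <- ens
  ens3$fold_models <- lapply(ens$fold_models, function(m) {
    m$weights[".const", ] <- m$weights[".const", ] + 5
    m
  })
  expect_equal(ensemble_uncertainty(ens3, fx$rows),
               ensemble_uncertainty(ens, fx$rows), tolerance = 1e-8)
  ens$fold_models <- ens$fold_models[1]
  expect_error(ensemble_uncertainty(ens, fx$rows),
               class = "bg_too_few_models")
})

test_that("rate calibration abstains exactly the configured fraction", {
  fx <- make_ensemble(200, 52)
  ens <- calibrate_threshold(fx$ens, fx$rows, criterion = "rate",
                             rate = 0.25)
  u <- ensemble_uncertainty(ens, fx$rows)
  n <- length(u)
  expect_equal(sum(u > ens$threshold), n - floor(0.75 * (n - 1) + 1))
  # 100 distinct uncertainties at rate 25% -> exactly 25 abstained
  set.seed(1)
  u100 <- runif(100)
  thr100 <- quantile(u100, 0.75, names = FALSE, type = 7)
  expect_equal(sum(u100 > thr100), 25)
  # determinism
  ens2 <- calibrate_threshold(fx$ens, fx$rows, criterion = "rate")
  expect_equal(ens2$threshold, ens$threshold)
})

test_that("all-equal uncertainties abstain nothing (strict threshold rule)", {
  fx <- make_ensemble(60, 53)
  ens <- fx$ens
  ens$fold_models <- list(ens$final_model, ens$final_model)
  ens <- calibrate_threshold(ens, fx$rows, criterion = "rate")
  pr <- predict_or_abstain(ens, fx$rows, importance = FALSE)
  expect_false(any(pr$abstained))
  # boundary: uncertainty exactly at the threshold is NOT abstained
  expect_true(all(ensemble_uncertainty(ens, fx$rows) == ens$threshold |
                    !pr$abstained))
})

test_that("error-bound calibration meets the bound at minimal abstention", {
  fx <- make_ensemble(250, 54)
  bound <- 0.04  # tight enough to force nonzero abstention
  res <- tryCatch(
    calibrate_threshold(fx$ens, fx$rows, criterion = "error_bound",
                        bound = bound),
    bg_unsatisfiable = function(e) e)
  if (inherits(res, "bg_unsatisfiable")) {
    succeed("bound not attainable on this cohort; error path exercised")
  } else {
    u <- ensemble_uncertainty(res, fx$rows)
    err <- predict(res$final_model, fx$rows) - fx$rows$ph_t
    expect_lte(p95_abs_error(err[u <= res$threshold]), bound)
    # patients with any abstained sample stay under the cap
    abst <- u > res$threshold
    pat <- vapply(split(abst, fx$rows$patient_id), any, logical(1))
    expect_lte(mean(pat), 0.5)
  }
  # an impossible bound fails loudly, reporting the best achievable
  err <- expect_error(
    calibrate_threshold(fx$ens, fx$rows, criterion = "error_bound",
                        bound = 0),
    class = "bg_unsatisfiable")
  expect_match(conditionMessage(err), "best achievable")
})

test_that("predict-or-abstain requires calibration and attaches importances", {
  fx <- make_ensemble(80, 55)
  expect_error(predict_or_abstain(fx$ens, fx$rows),
               class = "bg_uncalibrated")
  ens <- calibrate_threshold(fx$ens, fx$rows, criterion = "rate")
  pr <- predict_or_abstain(ens, fx$rows[1:20, ])
  est <- pr[!pr$abstained, ]
  expect_true(all(!is.na(est$top1)))
  expect_true(all(abs(est$top1_importance) >=
                    abs(est$top2_importance) - 1e-12))
  # interval contains the point and abstention matches the variance rule
  expect_true(all(pr$lower <= pr$point & pr$point <= pr$upper))
  expect_equal(pr$abstained, pr$uncertainty > ens$threshold)
})

test_that("held-out abstention stays near the calibrated 25% rate", {
  fx <- make_ensemble(400, 56)
  ens <- calibrate_threshold(fx$ens, fx$rows, criterion = "rate")
  held <- small_rows(n_patients = 200, seed = 57)
  pr <- predict_or_abstain(ens, held, importance = FALSE)
  expect_lt(abs(mean(pr$abstained) - 0.25), 0.03)
})

test_that("risk-coverage curves start equal and favor uncertainty ordering", {
  fx <- make_ensemble(200, 58)
  held <- small_rows(n_patients = 150, seed = 59)
  rc <- risk_coverage_curve(fx$ens, held, rates = c(0, 0.1, 0.25, 0.4),
                            seed = 3)
  expect_equal(rc$p95_uncertainty[1], rc$p95_random[1])
  base <- p95_abs_error(predict(fx$ens$final_model, held) - held$ph_t)
  expect_equal(rc$p95_uncertainty[1], base)
  expect_true(all(rc$p95_uncertainty[-1] <= rc$p95_random[-1]))
  # rates that retain nothing are excluded from the curve
  rc2 <- risk_coverage_curve(fx$ens, held[1:4, ], rates = c(0, 1))
  expect_equal(rc2$rate, 0)
  expect_error(risk_coverage_curve(fx$ens, held, rates = numeric(0)),
               class = "bg_config")
})

test_that("bootstrap replicates provide an alternative uncertainty source", {
  rows <- small_rows(n_patients = 60, seed = 60)
  plan <- make_split_plan(rows, seed = 1)
  ens <- bg_ensemble(rows, plan, "ph", lambda = 1, method = "bootstrap",
                     B = 5, seed = 2)
  expect_length(ens$fold_models, 5)
  expect_true(all(ensemble_uncertainty(ens, rows) >= 0))
})
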