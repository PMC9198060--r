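test_that("raw sigmoid basis functions are monotone on (0,1); normalized bank sums to 1", {
  b <- sigmoid_basis(c(7.2, 7.35, 7.5), slope = 10, normalize = FALSE)
  z <- seq(6.8, 7.9, by = 0.01)
  F <- sigmoid_basis_eval(b, z)
  expect_true(all(F > 0 & F < 1))
  expect_true(all(apply(F, 2, function(col) all(diff(col) > 0))))

  bn <- sigmoid_basis(c(7.2, 7.35, 7.5), slope = 10)
  Fn <- sigmoid_basis_eval(bn, z)
  expect_equal(rowSums(Fn), rep(1, length(z)), tolerance = 1e-12)

  expect_error(sigmoid_basis(c(7.4, 7.2), 10), class = "bg_basis")
  expect_error(sigmoid_basis(7.3, -1), class = "bg_basis")
})

test_that("design expansion matches hand-computed sigmoid-times-predictor values", {
  rows <- data.frame(ph_prev = c(7.20, 7.35, 7.50),
                     x1 = c(1, -2, 0.5), x2 = c(0, 3, -1),
                     ph_t = c(7.3, 7.4, 7.35))
  b <- sigmoid_basis(c(7.25, 7.45), slope = 8, normalize = FALSE)
  std <- list(center = c(x1 = 0, x2 = 0), scale = c(x1 = 1, x2 = 1))
  X <- expand_design(rows, b, key = "ph_prev",
                     predictors = c("x1", "x2"), standardization = std)
  f <- function(z, c) 1 / (1 + exp(-8 * (z - c)))
  for (r in 1:3) for (j in 1:2) {
    expect_equal(unname(X[r, paste0(".const|", j)]),
                 f(rows$ph_prev[r], b$centers[j]), tolerance = 1e-12)
    expect_equal(unname(X[r, paste0("x1|", j)]),
                 f(rows$ph_prev[r], b$centers[j]) * rows$x1[r],
                 tolerance = 1e-12)
  }
  # an all-zero predictor yields all-zero columns
  expect_equal(unname(X[1, c("x2|1", "x2|2")]), c(0, 0))
  # a single saturated raw sigmoid reduces the design to the plain matrix
  bsat <- sigmoid_basis(6.0, slope = 200, normalize = FALSE)
  Xsat <- expand_design(rows, bsat, key = "ph_prev",
                        predictors = c("x1", "x2"), standardization = std)
  expect_equal(unname(Xsat[, "x1|1"]), rows$x1, tolerance = 1e-10)
  # non-finite predictors are rejected
  rows$x1[1] <- Inf
  expect_error(expand_design(rows, b, key = "ph_prev",
                             predictors = c("x1", "x2"),
                             standardization = std),
               class = "bg_nonfinite")
})

test_that("ridge solution matches the independent normal-equation oracle", {
  set.seed(21)
  X <- matrix(rnorm(120), 20, 6)
  y <- rnorm(20)
  w <- fit_ridge(X, y, lambda = 1)
  w_oracle <- solve(crossprod(X) + diag(1, 6), crossprod(X, y))
  expect_equal(unname(w), drop(w_oracle), tolerance = 1e-8)

  # lambda = 0 on a square invertible system interpolates exactly
  Xs <- matrix(rnorm(36), 6, 6)
  ys <- rnorm(6)
  w0 <- fit_ridge(Xs, ys, 0)
  expect_equal(as.numeric(Xs %*% w0), ys, tolerance = 1e-8)

  # huge penalty drives penalized weights to zero
  whuge <- fit_ridge(X, y, 1e12)
  expect_lt(max(abs(whuge)), 1e-6)
  # unpenalized columns survive a huge penalty
  wmix <- fit_ridge(cbind(1, X), y, 1e12,
                    penalized = c(FALSE, rep(TRUE, 6)))
  expect_equal(wmix[[1]], mean(y), tolerance = 1e-6)

  # singular unpenalized system fails with advice
  Xsing <- cbind(X[, 1], X[, 1])
  expect_error(fit_ridge(Xsing, y, 0), class = "bg_singular")
})

test_that("prediction equals the bilinear form and decomposes exactly", {
  rows <- small_rows(n_patients = 80, seed = 31)
  fit <- pairwise_reg(rows, "ph", lambda = 0.5)
  # additive decomposition reproduces predictions to near machine precision
  contr <- contributions(fit, rows)
  expect_equal(rowSums(contr), predict(fit, rows), tolerance = 1e-10)
  # zero weights give zero predictions and contributions
  fit0 <- fit
  fit0$weights[] <- 0
  expect_equal(predict(fit0, rows), rep(0, nrow(rows)))
  expect_true(all(contributions(fit0, rows) == 0))
  # a predictor sitting at its standardization center contributes zero
  r1 <- rows[1, , drop = FALSE]
  r1$d_spo2 <- fit$standardization$center[["d_spo2"]]
  expect_equal(unname(contributions(fit, r1)[1, "d_spo2"]), 0,
               tolerance = 1e-12)
})

test_that("hand-set two-predictor model predicts per hand arithmetic", {
  rows <- data.frame(ph_prev = 7.3, x1 = 2, x2 = -1, ph_t = 7.35)
  b <- sigmoid_basis(c(7.25, 7.4), slope = 5, normalize = FALSE)
  train <- data.frame(ph_prev = c(7.2, 7.3, 7.4, 7.5),
                      x1 = c(-1, 0, 1, 2), x2 = c(2, 1, 0, -1),
                      ph_t = c(7.3, 7.35, 7.4, 7.45))
  fit <- pairwise_reg(train, "ph", key = "ph_prev",
                      predictors = c("x1", "x2"), basis = b, lambda = 1)
  W <- matrix(c(0.5, -0.2,   # .const
                0.1,  0.3,   # x1
                -0.4, 0.0),  # x2
              nrow = 3, byrow = TRUE,
              dimnames = list(c(".const", "x1", "x2"), c("f1", "f2")))
  fit$weights <- W
  f <- function(z, c) 1 / (1 + exp(-5 * (z - c)))
  f1 <- f(7.3, 7.25); f2 <- f(7.3, 7.4)
  std <- fit$standardization
  x1s <- (2 - std$center[["x1"]]) / std$scale[["x1"]]
  x2s <- (-1 - std$center[["x2"]]) / std$scale[["x2"]]
  by_hand <- (0.5 * f1 - 0.2 * f2) +
    (0.1 * f1 + 0.3 * f2) * x1s + (-0.4 * f1 + 0.0 * f2) * x2s
  expect_equal(predict(fit, rows), by_hand, tolerance = 1e-12)

  # importances match hand arithmetic: I_i = slope_i(z) * (x - xbar)/scale
  imp <- rank_importance(fit, rows)
  i1 <- (0.1 * f1 + 0.3 * f2) * (2 - fit$nonkey_means[["x1"]]) /
    std$scale[["x1"]]
  i2 <- (-0.4 * f1 + 0.0 * f2) * (-1 - fit$nonkey_means[["x2"]]) /
    std$scale[["x2"]]
  expect_equal(unname(imp$importance[match(c("x1", "x2"), imp$predictor)]),
               unname(c(i1, i2)), tolerance = 1e-12)
  expect_equal(imp$predictor[1],
               c("x1", "x2")[which.max(abs(c(i1, i2)))])
})

test_that("importance is zero at the population mean and isolates perturbations", {
  rows <- small_rows(n_patients = 80, seed = 32)
  fit <- pairwise_reg(rows, "ph", lambda = 1)
  at_mean <- rows[1, , drop = FALSE]
  for (p in fit$predictors) at_mean[[p]] <- fit$nonkey_means[[p]]
  imp <- rank_importance(fit, at_mean)
  expect_equal(imp$importance, rep(0, nrow(imp)), tolerance = 1e-12)

  one_off <- at_mean
  one_off$etco2_t <- one_off$etco2_t + 10
  imp2 <- rank_importance(fit, one_off)
  expect_equal(imp2$predictor[1], "etco2_t")
  expect_true(all(abs(imp2$importance[-1]) < 1e-12))
})

test_that("pairwise surface agrees with the decomposition and is linear in x", {
  rows <- small_rows(n_patients = 80, seed = 33)
  fit <- pairwise_reg(rows, "ph", lambda = 1)
  z0 <- 7.33
  xg <- seq(30, 55, length.out = 5)
  surf <- pairwise_surface(fit, "etco2_t", key_grid = z0, x_grid = xg)
  # surface values equal the contribution of that predictor for a row
  # with those values
  for (k in seq_along(xg)) {
    r <- rows[1, , drop = FALSE]
    r$ph_prev <- z0
    r$etco2_t <- xg[k]
    expect_equal(surf[1, k], unname(contributions(fit, r)[1, "etco2_t"]),
                 tolerance = 1e-10)
  }
  # linear in x with the analytic key-conditional slope
  f <- sigmoid_basis_eval(fit$basis, z0)[1, ]
  slope <- sum(fit$weights["etco2_t", ] * f) /
    fit$standardization$scale[["etco2_t"]]
  fd <- diff(surf[1, ]) / diff(xg)
  expect_equal(unname(fd), rep(slope, 4), tolerance = 1e-10)
  # zero-weight model -> flat zero surface
  fit0 <- fit
  fit0$weights[] <- 0
  expect_true(all(pairwise_surface(fit0, "etco2_t") == 0))
  expect_error(pairwise_surface(fit, "nope"),
               class = "bg_unknown_predictor")
})

test_that("learned etCO2 effect on pH is negative at fixed previous pH", {
  rows <- small_rows(n_patients = 300, seed = 34)
  fit <- pairwise_reg(rows, "ph", lambda = 1)
  # higher measured end-tidal CO2 must lower the estimated pH
  for (z in c(7.25, 7.35, 7.45)) {
    s <- pairwise_surface(fit, "etco2_t", key_grid = z,
                          x_grid = c(30, 50))
    expect_lt(s[1, 2], s[1, 1])
  }
})

test_that("hyperparameter selection is deterministic and honors the grid", {
  rows <- small_rows(n_patients = 60, seed = 35)
  plan <- make_split_plan(rows, outer = 2, inner = 3, seed = 1)
  one <- select_hyperparameters(rows, plan, lambda_grid = 1, m_grid = 3,
                                slope_grid = 10)
  expect_equal(one$lambda, 1)
  expect_equal(one$m, 3)
  expect_equal(nrow(one$scores), 1)

  sel <- select_hyperparameters(rows, plan, lambda_grid = c(0.1, 10),
                                m_grid = c(3, 5), slope_grid = 10)
  expect_equal(sel$score, min(sel$scores$score))
  sel2 <- select_hyperparameters(rows, plan, lambda_grid = c(0.1, 10),
                                 m_grid = c(3, 5), slope_grid = 10)
  expect_equal(sel$scores, sel2$scores)
  # duplicated grid points keep the first occurrence (strict improvement)
  dup <- select_hyperparameters(rows, plan, lambda_grid = c(1, 1),
                                m_grid = 3, slope_grid = 10)
  expect_equal(dup$scores$score[1], dup$scores$score[2])
  expect_equal(dup$lambda, 1)
  expect_error(select_hyperparameters(rows, plan, lambda_grid = numeric(0)),
               class = "bg_config")
})

test_that("model serialization round-trips predictions", {
  rows <- small_rows(n_patients = 60, seed = 36)
  fit <- pairwise_reg(rows, "ph", lambda = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_bg_model(fit, path)
  back <- read_bg_model(path)
  expect_equal(predict(back, rows), predict(fit, rows), tolerance = 1e-12)
  expect_equal(back$basis$centers, fit$basis$centers)
  expect_output(print(back), "Pairwise blood-gas model")
})

test_that("missing predictors are reported by name", {
  rows <- small_rows(n_patients = 40, seed = 37)
  fit <- pairwise_reg(rows, "ph", lambda = 1)
  rows$etco2_t <- NULL
  expect_error(predict(fit, rows), "etco2_t",
               class = "bg_missing_columns")
})

test_that("model simulation adds residual-scale noise around predictions", {
  rows <- small_rows(n_patients = 60, seed = 38)
  fit <- pairwise_reg(rows, "ph", lambda = 1)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(nrow(rows), 3))
  expect_equal(simulate(fit, nsim = 2, seed = 5),
               simulate(fit, nsim = 2, seed = 5))
  expect_lt(abs(sd(sims[, 1] - fitted(fit)) - fit$sigma),
            0.2 * fit$sigma)
})
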