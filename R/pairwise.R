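# The key-predictor pairwise regression model.
#
# One predictor (the previous pH, "key") modulates the linear effect of
# every other predictor through a bank of sigmoid basis functions:
#   yhat = sum_j sum_i  w[i, j] * f_j(z) * x_i,
# where z is the key value, f_j(z) = 1 / (1 + exp(-slope (z - c_j))) and
# the x_i are standardized non-key predictors plus a constant term
# (x_0 = 1) through which the key's own effect enters. Weights are fitted
# by ridge regression; the bilinear form makes the prediction an exact
# sum of per-predictor contributions, which powers the importance
# ranking and the pairwise visualization.

BG_CONST <- ".const"

#' Sigmoid basis over the key predictor
#'
#' A bank of M logistic sigmoids `1/(1+exp(-slope (z - c_j)))` of the key
#' predictor. By default the basis is normalized to a partition of unity
#' (each function divided by the sum over the bank), so the bank spans
#' constants and each weight acts as the local effect level near its
#' center; set `normalize = FALSE` for the raw monotone logistics.
#'
#' @param centers Strictly increasing vector of key-predictor values (pH
#'   units) at which the sigmoids are centered.
#' @param slope Shared sharpness (> 0), per pH unit.
#' @param normalize Normalize the bank to sum to 1 at every `z`.
#' @return Object of class `sigmoid_basis`.
#' @export
sigmoid_basis <- function(centers, slope, normalize = TRUE) {
  if (!length(centers) || any(!is.finite(centers)) ||
      (length(centers) > 1 && any(diff(centers) <= 0)))
    stop_bg("centers must be finite and strictly increasing", "bg_basis")
  if (!is.finite(slope) || slope <= 0)
    stop_bg("slope must be a positive number", "bg_basis")
  structure(list(centers = as.numeric(centers), slope = as.numeric(slope),
                 normalize = isTRUE(normalize)),
            class = "sigmoid_basis")
}

#' Evaluate a sigmoid basis
#'
#' @param basis A [sigmoid_basis()].
#' @param z Key-predictor values.
#' @return `length(z) x M` matrix of basis values; raw logistics map to
#'   (0, 1) and are monotone in `z`, normalized values sum to 1 per row.
#' @export
sigmoid_basis_eval <- function(basis, z) {
  out <- vapply(basis$centers,
                function(cj) stats::plogis(basis$slope * (z - cj)),
                numeric(length(z)))
  out <- matrix(out, nrow = length(z), ncol = length(basis$centers))
  if (isTRUE(basis$normalize)) out <- out / rowSums(out)
  out
}

#' Default basis from training key values
#'
#' Centers at the M equally spaced quantiles (probabilities `k/(M+1)`) of
#' the observed key-predictor values, so the bank always covers the range
#' where the data live.
#'
#' @param key_values Training key-predictor values (previous pH).
#' @param m Number of centers.
#' @param slope Sharpness per pH unit.
#' @param normalize Passed to [sigmoid_basis()].
#' @return A [sigmoid_basis()].
#' @export
bg_default_basis <- function(key_values, m = 5L, slope = 10,
                             normalize = TRUE) {
  ctr <- unique(stats::quantile(key_values, seq_len(m) / (m + 1),
                                names = FALSE, type = 7))
  sigmoid_basis(ctr, slope, normalize)
}

#' @export
print.sigmoid_basis <- function(x, ...) {
  cat(sprintf("Sigmoid basis: M = %d centers (%s), slope %.3g%s\n",
              length(x$centers),
              paste(signif(x$centers, 4), collapse = ", "), x$slope,
              if (x$normalize) ", normalized (partition of unity)" else ""))
  invisible(x)
}

#' Standardization parameters for the non-key predictors
#'
#' @param rows Feature rows.
#' @param predictors Predictor column names.
#' @return List with named `center` (means) and `scale` (SDs; zero or
#'   non-finite SDs are replaced by 1 so constant columns survive).
#' @export
bg_standardization <- function(rows, predictors) {
  center <- vapply(predictors, function(p) mean(rows[[p]]), numeric(1))
  scl <- vapply(predictors, function(p) stats::sd(rows[[p]]), numeric(1))
  bad <- !is.finite(scl) | scl <= 0
  scl[bad] <- 1
  list(center = center, scale = scl)
}

#' Expand feature rows into the pairwise design matrix
#'
#' Builds the `K x M` interaction columns `f_j(z) * x_i`, with the
#' standardized non-key predictors preceded by a constant term (through
#' which the key predictor's own effect is expressed). Columns are
#' ordered predictor-major: all M basis columns of predictor i are
#' contiguous.
#'
#' @param rows Feature rows.
#' @param basis A [sigmoid_basis()].
#' @param key Key predictor column (default `"ph_prev"`).
#' @param predictors Non-key predictor columns.
#' @param standardization Centers/scales from [bg_standardization()]
#'   (computed from `rows` if omitted; pass the training values when
#'   expanding new data).
#' @return Design matrix with attribute `nonkey_names`.
#' @export
expand_design <- function(rows, basis, key = "ph_prev",
                          predictors = bg_default_predictors(),
                          standardization = bg_standardization(rows,
                                                               predictors)) {
  assert_columns(rows, c(key, predictors), "feature rows")
  z <- rows[[key]]
  Xraw <- as.matrix(rows[, predictors, drop = FALSE])
  if (any(!is.finite(z)) || any(!is.finite(Xraw)))
    stop_bg("non-finite predictor values in design expansion",
            "bg_nonfinite")
  Xs <- sweep(sweep(Xraw, 2, standardization$center[predictors]), 2,
              standardization$scale[predictors], "/")
  Xs <- cbind(1, Xs)
  nonkey <- c(BG_CONST, predictors)
  colnames(Xs) <- nonkey
  F <- sigmoid_basis_eval(basis, z)
  M <- ncol(F)
  out <- matrix(0, nrow(Xs), length(nonkey) * M)
  cn <- character(ncol(out))
  for (i in seq_along(nonkey)) {
    cols <- (i - 1L) * M + seq_len(M)
    out[, cols] <- F * Xs[, i]
    cn[cols] <- paste0(nonkey[i], "|", seq_len(M))
  }
  colnames(out) <- cn
  attr(out, "nonkey_names") <- nonkey
  out
}

#' Ridge regression weights
#'
#' Minimizes `||y - X w||^2 + lambda * sum(penalized w^2)` in closed form
#' via QR on the lambda-augmented system. Constant-term columns are
#' typically left unpenalized.
#'
#' @param X Design matrix.
#' @param y Targets.
#' @param lambda Ridge penalty (>= 0).
#' @param penalized Logical per column; `FALSE` columns carry no penalty.
#' @return Named weight vector.
#' @export
fit_ridge <- function(X, y, lambda, penalized = rep(TRUE, ncol(X))) {
  if (nrow(X) != length(y) || nrow(X) < 1)
    stop_bg("X and y must have matching, positive row count", "bg_shape")
  if (!is.finite(lambda) || lambda < 0)
    stop_bg("lambda must be >= 0", "bg_config")
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop_bg("non-finite values in ridge system", "bg_nonfinite")
  pen <- which(rep_len(penalized, ncol(X)))
  if (lambda > 0 && length(pen)) {
    P <- matrix(0, length(pen), ncol(X))
    P[cbind(seq_along(pen), pen)] <- sqrt(lambda)
    A <- rbind(X, P)
    b <- c(y, numeric(length(pen)))
  } else {
    A <- X
    b <- y
  }
  w <- tryCatch(qr.solve(A, b),
                error = function(e)
                  stop_bg(paste0("singular ridge system (", conditionMessage(e),
                                 "); use lambda > 0"), "bg_singular"))
  stats::setNames(as.numeric(w), colnames(X))
}

#' Fit the key-predictor pairwise regression
#'
#' Fits `yhat = sum_j sum_i w[i,j] f_j(z) x_i` by ridge regression on the
#' expanded design, with the constant-term columns unpenalized. Targets
#' are fitted on their natural scale; non-key predictors are standardized
#' with training-set centers and scales stored in the object.
#'
#' @param data Feature rows (see [build_feature_rows()]).
#' @param target `"ph"` or `"paco2"` (target columns `ph_t` / `paco2_t`).
#' @param key Key predictor column, default previous pH.
#' @param predictors Non-key predictor columns.
#' @param basis A [sigmoid_basis()]; by default 5 normalized sigmoids
#'   centered at the training quantiles of the key predictor
#'   ([bg_default_basis()]).
#' @param lambda Ridge penalty.
#' @return Object of class `bg_pairwise` with `print`, `summary`, `coef`,
#'   `predict`, `residuals`, `fitted`, `plot` and `simulate` methods.
#' @examples
#' cohort <- simulate_cohort(bg_generator_config(n_patients = 40, seed = 7))
#' rows <- build_feature_rows(cohort)
#' fit <- pairwise_reg(rows, target = "ph", lambda = 1)
#' summary(fit)
#' @export
pairwise_reg <- function(data, target = c("ph", "paco2"),
                         key = "ph_prev",
                         predictors = bg_default_predictors(),
                         basis = NULL,
                         lambda = 1) {
  target <- match.arg(target)
  target_col <- paste0(target, "_t")
  assert_columns(data, c(target_col, key, predictors), "feature rows")
  if (is.null(basis)) basis <- bg_default_basis(data[[key]])
  y <- data[[target_col]]
  std <- bg_standardization(data, predictors)
  X <- expand_design(data, basis, key, predictors, std)
  nonkey <- attr(X, "nonkey_names")
  M <- length(basis$centers)
  penalized <- rep(nonkey != BG_CONST, each = M)
  w <- fit_ridge(X, y, lambda, penalized)
  fitted <- as.numeric(X %*% w)
  res <- y - fitted
  W <- matrix(w, nrow = length(nonkey), ncol = M, byrow = TRUE,
              dimnames = list(nonkey, paste0("f", seq_len(M))))
  structure(list(target = target, target_col = target_col, key = key,
                 predictors = predictors, nonkey_names = nonkey,
                 basis = basis, lambda = lambda, weights = W,
                 standardization = std,
                 key_mean = mean(data[[key]]),
                 nonkey_means = c(stats::setNames(1, BG_CONST),
                                  std$center),
                 n = nrow(data), sigma = stats::sd(res),
                 fitted.values = fitted, residuals = res,
                 call = match.call()),
            class = "bg_pairwise")
}

#' @export
predict.bg_pairwise <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  X <- expand_design(newdata, object$basis, object$key, object$predictors,
                     object$standardization)
  as.numeric(X %*% as.numeric(t(object$weights)))
}

#' Per-predictor contributions to a prediction
#'
#' Splits each prediction into the exact additive contributions
#' `g(x_i) = sum_j w[i,j] f_j(z) x_i` of the constant term and every
#' non-key predictor; rows of the result sum to the prediction to
#' machine precision.
#'
#' @param model A fitted [pairwise_reg()] model.
#' @param rows Feature rows.
#' @return `nrow(rows) x (K+1)` matrix, one column per term.
#' @export
contributions <- function(model, rows) {
  stopifnot(inherits(model, "bg_pairwise"))
  X <- expand_design(rows, model$basis, model$key, model$predictors,
                     model$standardization)
  M <- length(model$basis$centers)
  K <- length(model$nonkey_names)
  out <- matrix(0, nrow(rows), K,
                dimnames = list(NULL, model$nonkey_names))
  for (i in seq_len(K)) {
    cols <- (i - 1L) * M + seq_len(M)
    out[, i] <- X[, cols, drop = FALSE] %*% model$weights[i, ]
  }
  out
}

#' Rank predictors by importance for one estimation
#'
#' The importance of predictor i is the change in its contribution when
#' its value is moved from the population mean (stored at fit time) to
#' the observed value, holding the key predictor at its observed value:
#' `I_i = g(x_i) - g(xbar_i)`. Predictors near their population mean get
#' importance near 0; the ranking is by `|I_i|`, ties broken by the fixed
#' predictor order.
#'
#' @param model A fitted [pairwise_reg()] model.
#' @param row A single feature row.
#' @return data.frame of class `bg_importance`: predictor, importance
#'   (target units), observed value, population mean.
#' @export
rank_importance <- function(model, row) {
  stopifnot(inherits(model, "bg_pairwise"))
  if (nrow(row) != 1L)
    stop_bg("rank_importance() expects a single row", "bg_shape")
  assert_columns(row, c(model$key, model$predictors), "row")
  f <- sigmoid_basis_eval(model$basis, row[[model$key]])[1, ]
  preds <- model$predictors
  std <- model$standardization
  # key-conditional linear slope of each predictor's contribution
  slope_i <- as.numeric(model$weights[preds, , drop = FALSE] %*% f)
  x_obs <- vapply(preds, function(p) row[[p]], numeric(1))
  x_bar <- model$nonkey_means[preds]
  imp <- slope_i * (x_obs - x_bar) / std$scale[preds]
  ord <- order(-abs(imp), match(preds, preds))
  structure(data.frame(predictor = preds[ord], importance = imp[ord],
                       value = x_obs[ord], population_mean = x_bar[ord],
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("bg_importance", "data.frame"))
}

#' Learned pairwise contribution surface
#'
#' The contribution of one non-key predictor over a grid of (key value,
#' predictor value) pairs — the quantity rendered as a colormap to
#' inspect what the model learned (e.g., that a low current end-tidal CO2
#' raises the estimated pH).
#'
#' @param model A fitted [pairwise_reg()] model.
#' @param predictor Name of a non-key predictor.
#' @param key_grid Grid of key-predictor (previous pH) values; defaults
#'   to the basis-center range widened by 0.1 pH on each side.
#' @param x_grid Grid of predictor values; defaults to the training mean
#'   +/- 2.5 SD.
#' @return Matrix (`length(key_grid)` x `length(x_grid)`) of class
#'   `bg_pairwise_surface` with the grids as attributes.
#' @export
pairwise_surface <- function(model, predictor, key_grid = NULL,
                             x_grid = NULL) {
  stopifnot(inherits(model, "bg_pairwise"))
  if (is.null(key_grid))
    key_grid <- seq(min(model$basis$centers) - 0.1,
                    max(model$basis$centers) + 0.1, length.out = 61)
  if (!predictor %in% model$predictors)
    stop_bg(sprintf("unknown predictor '%s'", predictor),
            "bg_unknown_predictor")
  std <- model$standardization
  if (is.null(x_grid))
    x_grid <- std$center[predictor] +
      seq(-2.5, 2.5, length.out = 61) * std$scale[predictor]
  f <- sigmoid_basis_eval(model$basis, key_grid)
  slope_z <- as.numeric(f %*% model$weights[predictor, ])
  xs <- (x_grid - std$center[predictor]) / std$scale[predictor]
  out <- outer(slope_z, xs)
  dimnames(out) <- list(signif(key_grid, 5), signif(x_grid, 5))
  structure(out, key_grid = key_grid, x_grid = x_grid,
            predictor = predictor, target = model$target,
            class = c("bg_pairwise_surface", "matrix", "array"))
}

#' @export
plot.bg_pairwise_surface <- function(x, ...) {
  graphics::image(attr(x, "key_grid"), attr(x, "x_grid"),
                  unclass(x),
                  col = grDevices::gray.colors(64, start = 0, end = 1),
                  xlab = "previous pH (key predictor)",
                  ylab = attr(x, "predictor"),
                  main = sprintf("Contribution to estimated %s",
                                 attr(x, "target")), ...)
  invisible(x)
}

#' @export
plot.bg_pairwise <- function(x, predictor = x$predictors[1], ...) {
  plot(pairwise_surface(x, predictor), ...)
}

#' @export
coef.bg_pairwise <- function(object, ...) object$weights

#' @export
residuals.bg_pairwise <- function(object, ...) object$residuals

#' @export
fitted.bg_pairwise <- function(object, ...) object$fitted.values

#' @export
simulate.bg_pairwise <- function(object, nsim = 1, seed = NULL,
                                 newdata = NULL, ...) {
  mu <- if (is.null(newdata)) object$fitted.values
        else predict(object, newdata)
  local_seed(seed, {
    out <- as.data.frame(replicate(
      nsim, mu + stats::rnorm(length(mu), 0, object$sigma)))
    names(out) <- paste0("sim_", seq_len(nsim))
    out
  })
}

#' @export
print.bg_pairwise <- function(x, ...) {
  cat(sprintf("Pairwise blood-gas model (target: %s)\n", x$target))
  cat(sprintf("  key: %s, %d non-key predictors + constant, M = %d, slope %.3g, lambda %.3g\n",
              x$key, length(x$predictors), length(x$basis$centers),
              x$basis$slope, x$lambda))
  cat(sprintf("  n = %d, residual SD %.4g\n", x$n, x$sigma))
  invisible(x)
}

#' @export
summary.bg_pairwise <- function(object, ...) {
  ae <- abs(object$residuals)
  out <- list(model = object,
              p95_abs_error = p95_abs_error(object$residuals),
              mean_abs_error = mean(ae),
              residual_quantiles = stats::quantile(object$residuals,
                                                   c(0.05, 0.25, 0.5,
                                                     0.75, 0.95)))
  class(out) <- "summary.bg_pairwise"
  out
}

#' @export
print.summary.bg_pairwise <- function(x, ...) {
  print(x$model)
  cat(sprintf("  training MAE %.4g, p95 |error| %.4g\n",
              x$mean_abs_error, x$p95_abs_error))
  cat("  residual quantiles:\n")
  print(signif(x$residual_quantiles, 4))
  invisible(x)
}

#' Select basis and penalty on inner cross-validation folds
#'
#' Scores every (M, slope, lambda) combination by the mean inner-fold
#' 95th-percentile absolute error (train on the other inner folds,
#' standardization recomputed per training split) and returns the first
#' grid point attaining the minimum (ties keep earlier grid order: M
#' outermost, then slope, then lambda).
#'
#' @param rows Feature rows (derivation data).
#' @param plan A [make_split_plan()]; its inner folds drive the scoring.
#' @param target `"ph"` or `"paco2"`.
#' @param lambda_grid,m_grid,slope_grid Candidate values.
#' @param key,predictors As in [pairwise_reg()].
#' @return List of class `bg_hyperparameters`: `basis`, `lambda`, and the
#'   full `scores` table.
#' @export
select_hyperparameters <- function(rows, plan, target = c("ph", "paco2"),
                                   lambda_grid = 10^seq(-3, 3),
                                   m_grid = c(3, 5, 7),
                                   slope_grid = c(5, 10, 20),
                                   key = "ph_prev",
                                   predictors = bg_default_predictors()) {
  target <- match.arg(target)
  if (!length(lambda_grid) || !length(m_grid) || !length(slope_grid))
    stop_bg("empty hyperparameter grid", "bg_config")
  target_col <- paste0(target, "_t")
  folds <- split_assignment(plan, rows)$inner_fold
  y <- rows[[target_col]]
  scores <- list()
  best <- list(score = Inf)
  for (m in m_grid) for (sl in slope_grid) {
    basis <- bg_default_basis(rows[[key]], m, sl)
    M <- length(basis$centers)
    fold_parts <- lapply(sort(unique(folds)), function(k) {
      tr <- folds != k
      std <- bg_standardization(rows[tr, , drop = FALSE], predictors)
      list(Xtr = expand_design(rows[tr, , drop = FALSE], basis, key,
                               predictors, std),
           Xte = expand_design(rows[!tr, , drop = FALSE], basis, key,
                               predictors, std),
           ytr = y[tr], yte = y[!tr])
    })
    penalized <- rep(c(FALSE, rep(TRUE, length(predictors))), each = M)
    for (lam in lambda_grid) {
      errs <- vapply(fold_parts, function(fp) {
        w <- fit_ridge(fp$Xtr, fp$ytr, lam, penalized)
        p95_abs_error(fp$yte - as.numeric(fp$Xte %*% w))
      }, numeric(1))
      sc <- mean(errs)
      scores[[length(scores) + 1L]] <-
        data.frame(m = m, slope = sl, lambda = lam, score = sc)
      if (sc < best$score)
        best <- list(score = sc, basis = basis, lambda = lam,
                     m = m, slope = sl)
    }
  }
  structure(list(basis = best$basis, lambda = best$lambda,
                 m = best$m, slope = best$slope, score = best$score,
                 scores = do.call(rbind, scores)),
            class = "bg_hyperparameters")
}

#' @export
print.bg_hyperparameters <- function(x, ...) {
  cat(sprintf("Selected: M = %d, slope %.3g, lambda %.3g (inner-CV p95 %.4g)\n",
              x$m, x$slope, x$lambda, x$score))
  invisible(x)
}

#' Serialize a fitted pairwise model to JSON
#'
#' @param model A fitted [pairwise_reg()] model.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bg_model <- function(model, path) {
  stopifnot(inherits(model, "bg_pairwise"))
  payload <- list(format = "bloodgas-pairwise", version = 1L,
                  target = model$target, key = model$key,
                  predictors = model$predictors,
                  basis = list(centers = model$basis$centers,
                               slope = model$basis$slope,
                               normalize = model$basis$normalize),
                  lambda = model$lambda,
                  weights = model$weights,
                  standardization = list(
                    center = as.list(model$standardization$center),
                    scale = as.list(model$standardization$scale)),
                  key_mean = model$key_mean,
                  nonkey_means = as.list(model$nonkey_means),
                  n = model$n, sigma = model$sigma)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a serialized pairwise model
#'
#' @param path JSON file written by [write_bg_model()].
#' @return A `bg_pairwise` model (without training fitted values).
#' @export
read_bg_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "bloodgas-pairwise"))
    stop_bg("not a serialized pairwise blood-gas model", "bg_io")
  nonkey <- c(BG_CONST, p$predictors)
  W <- matrix(as.numeric(p$weights), nrow = length(nonkey),
              dimnames = list(nonkey, NULL))
  structure(list(target = p$target, target_col = paste0(p$target, "_t"),
                 key = p$key, predictors = p$predictors,
                 nonkey_names = nonkey,
                 basis = sigmoid_basis(p$basis$centers, p$basis$slope,
                                       isTRUE(p$basis$normalize)),
                 lambda = p$lambda, weights = W,
                 standardization = list(
                   center = unlist(p$standardization$center),
                   scale = unlist(p$standardization$scale)),
                 key_mean = p$key_mean,
                 nonkey_means = unlist(p$nonkey_means),
                 n = p$n, sigma = p$sigma,
                 fitted.values = NULL, residuals = NULL,
                 call = NULL),
            class = "bg_pairwise")
}
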