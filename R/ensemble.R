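# Prediction uncertainty and selective abstention.
#
# The point estimate comes from a final model trained on all derivation
# data; uncertainty is the spread among replicate models (one per outer
# CV fold, or bootstrap resamples), and the system abstains whenever
# that spread exceeds a calibrated threshold.

#' Train a final model plus replicate models for uncertainty
#'
#' @param rows Derivation feature rows.
#' @param plan A [make_split_plan()]; with `method = "folds"`, replicate
#'   k is trained on all rows outside outer fold k.
#' @param target `"ph"` or `"paco2"`.
#' @param basis,lambda,key,predictors Passed to [pairwise_reg()].
#' @param method `"folds"` (default, one replicate per outer fold) or
#'   `"bootstrap"` (`B` patient-level bootstrap resamples).
#' @param B Number of bootstrap replicates when `method = "bootstrap"`.
#' @param seed Seed for the bootstrap resampling.
#' @return Object of class `bg_ensemble` with an uncalibrated
#'   (`NULL`) threshold.
#' @export
bg_ensemble <- function(rows, plan, target = c("ph", "paco2"),
                        basis = NULL,
                        lambda = 1, key = "ph_prev",
                        predictors = bg_default_predictors(),
                        method = c("folds", "bootstrap"), B = 20L,
                        seed = 1L) {
  target <- match.arg(target)
  method <- match.arg(method)
  # final and replicate models share one basis, fixed from all rows
  if (is.null(basis)) basis <- bg_default_basis(rows[[key]])
  final <- pairwise_reg(rows, target = target, key = key,
                        predictors = predictors, basis = basis,
                        lambda = lambda)
  fold_models <- if (method == "folds") {
    folds <- split_assignment(plan, rows)$outer_fold
    lapply(sort(unique(folds)), function(o)
      pairwise_reg(rows[folds != o, , drop = FALSE], target = target,
                   key = key, predictors = predictors, basis = basis,
                   lambda = lambda))
  } else {
    ids <- unique(rows$patient_id)
    local_seed(seed, lapply(seq_len(B), function(b) {
      take <- sample(ids, length(ids), replace = TRUE)
      idx <- unlist(lapply(take, function(id)
        which(rows$patient_id == id)), use.names = FALSE)
      pairwise_reg(rows[idx, , drop = FALSE], target = target, key = key,
                   predictors = predictors, basis = basis,
                   lambda = lambda)
    }))
  }
  if (length(fold_models) < 2L)
    stop_bg("an ensemble needs at least 2 replicate models",
            "bg_too_few_models")
  structure(list(final_model = final, fold_models = fold_models,
                 threshold = NULL, target = target, method = method,
                 calibration = NULL),
            class = "bg_ensemble")
}

#' Per-row ensemble prediction uncertainty
#'
#' The variance, across the replicate models, of the predicted target
#' (population variance: denominator = number of replicate models).
#'
#' @param ensemble A [bg_ensemble()].
#' @param rows Feature rows.
#' @return Numeric vector of variances (target units squared).
#' @export
ensemble_uncertainty <- function(ensemble, rows) {
  stopifnot(inherits(ensemble, "bg_ensemble"))
  if (length(ensemble$fold_models) < 2L)
    stop_bg("need >= 2 replicate models", "bg_too_few_models")
  preds <- vapply(ensemble$fold_models, predict, numeric(nrow(rows)),
                  newdata = rows)
  preds <- matrix(preds, nrow = nrow(rows))
  mu <- rowMeans(preds)
  rowMeans((preds - mu)^2)
}

# Retained p95 |error| after abstaining on uncertainties > thr.
retained_p95 <- function(err, u, thr) {
  keep <- u <= thr
  if (!any(keep)) return(NA_real_)
  p95_abs_error(err[keep])
}

#' Calibrate the abstention threshold
#'
#' Two criteria:
#' \describe{
#'   \item{`"rate"`}{abstain a fixed fraction of samples: the threshold is
#'     the `1 - rate` quantile of calibration uncertainties (default
#'     abstention rate 25%).}
#'   \item{`"error_bound"`}{the pre-defined accuracy criterion: find the
#'     smallest abstention rate whose retained 95th-percentile absolute
#'     error is at or below `bound` (0.1 pH units by default), subject to
#'     abstaining on at most `max_patient_fraction` of patients (a patient
#'     counts as abstained-on if any of its samples is abstained).}
#' }
#' The abstention rule is strict (`uncertainty > threshold`), so when all
#' uncertainties are equal nothing is abstained.
#'
#' @param ensemble A [bg_ensemble()].
#' @param rows Calibration rows with known targets.
#' @param criterion `"rate"` or `"error_bound"`.
#' @param rate Target abstention fraction for `"rate"`.
#' @param bound Retained p95 absolute-error bound for `"error_bound"`
#'   (target units).
#' @param max_patient_fraction Patient-level abstention cap for
#'   `"error_bound"`.
#' @return The ensemble with `$threshold` set and calibration details in
#'   `$calibration`; errors loudly (reporting the best achievable
#'   retained p95) if the error-bound criterion cannot be met.
#' @export
calibrate_threshold <- function(ensemble, rows,
                                criterion = c("rate", "error_bound"),
                                rate = 0.25, bound = 0.1,
                                max_patient_fraction = 0.5) {
  stopifnot(inherits(ensemble, "bg_ensemble"))
  criterion <- match.arg(criterion)
  u <- ensemble_uncertainty(ensemble, rows)
  if (criterion == "rate") {
    thr <- stats::quantile(u, 1 - rate, names = FALSE, type = 7)
  } else {
    ycol <- ensemble$final_model$target_col
    assert_columns(rows, ycol, "calibration rows")
    err <- predict(ensemble$final_model, rows) - rows[[ycol]]
    # scan thresholds from most permissive (abstain nothing) downwards
    cand <- sort(unique(u), decreasing = TRUE)
    best <- list(p95 = Inf, thr = NA_real_, rate = NA_real_)
    thr <- NA_real_
    for (t in cand) {
      abst <- u > t
      pat_frac <- mean(vapply(split(abst, rows$patient_id), any,
                              logical(1)))
      if (pat_frac > max_patient_fraction) break
      p95 <- retained_p95(err, u, t)
      if (is.na(p95)) break
      if (p95 < best$p95)
        best <- list(p95 = p95, thr = t, rate = mean(abst))
      if (p95 <= bound) { thr <- t; break }
    }
    if (is.na(thr))
      stop_bg(sprintf(
        paste0("abstention criterion unsatisfiable: best achievable ",
               "retained p95 |error| is %.4g (at abstention rate %.1f%%) ",
               "against bound %.4g"),
        best$p95, 100 * best$rate, bound),
        "bg_unsatisfiable", best = best)
  }
  ensemble$threshold <- as.numeric(thr)
  ensemble$calibration <- list(criterion = criterion, rate = rate,
                               bound = bound,
                               max_patient_fraction = max_patient_fraction,
                               n_calibration = nrow(rows),
                               abstained_fraction = mean(u > thr))
  ensemble
}

#' Predict or abstain
#'
#' Point estimates come from the final model; rows whose ensemble
#' uncertainty strictly exceeds the calibrated threshold are abstained.
#' The uncertainty interval is the point estimate +/- 1.96 times the
#' ensemble standard deviation. For non-abstained rows the top three
#' predictors by importance are attached.
#'
#' @param ensemble A calibrated [bg_ensemble()].
#' @param rows Feature rows.
#' @param importance Attach the top-3 importance columns (set `FALSE` to
#'   skip the per-row ranking in bulk evaluations).
#' @return data.frame of class `bg_predictions`: `point`, `uncertainty`
#'   (variance), `lower`, `upper`, `abstained`, and `top1`-`top3`
#'   predictor names with importances.
#' @export
predict_or_abstain <- function(ensemble, rows, importance = TRUE) {
  stopifnot(inherits(ensemble, "bg_ensemble"))
  if (is.null(ensemble$threshold))
    stop_bg("ensemble is not calibrated; run calibrate_threshold() first",
            "bg_uncalibrated")
  point <- predict(ensemble$final_model, rows)
  u <- ensemble_uncertainty(ensemble, rows)
  hw <- 1.96 * sqrt(u)
  abst <- u > ensemble$threshold
  out <- data.frame(point = point, uncertainty = u,
                    lower = point - hw, upper = point + hw,
                    abstained = abst,
                    top1 = NA_character_, top1_importance = NA_real_,
                    top2 = NA_character_, top2_importance = NA_real_,
                    top3 = NA_character_, top3_importance = NA_real_,
                    stringsAsFactors = FALSE)
  if (importance) for (r in which(!abst)) {
    imp <- rank_importance(ensemble$final_model, rows[r, , drop = FALSE])
    k <- min(3L, nrow(imp))
    out[r, paste0("top", seq_len(k))] <- imp$predictor[seq_len(k)]
    out[r, paste0("top", seq_len(k), "_importance")] <-
      imp$importance[seq_len(k)]
  }
  class(out) <- c("bg_predictions", "data.frame")
  out
}

#' @export
predict.bg_ensemble <- function(object, newdata, ...) {
  predict_or_abstain(object, newdata)
}

#' @export
print.bg_ensemble <- function(x, ...) {
  cat(sprintf("Blood-gas ensemble predictor (target: %s, %d %s replicates)\n",
              x$target, length(x$fold_models),
              if (x$method == "folds") "outer-fold" else "bootstrap"))
  if (is.null(x$threshold)) cat("  threshold: uncalibrated\n")
  else cat(sprintf("  threshold: %.4g (%s criterion, %.1f%% abstained at calibration)\n",
                   x$threshold, x$calibration$criterion,
                   100 * x$calibration$abstained_fraction))
  invisible(x)
}

#' Risk-coverage curves: uncertainty-ordered vs random abstention
#'
#' For each abstention rate, drops that fraction of rows either in
#' decreasing order of ensemble uncertainty or uniformly at random
#' (averaged over `n_random` orderings) and reports the retained
#' 95th-percentile absolute error.
#'
#' @param ensemble A [bg_ensemble()] (calibration not required).
#' @param rows Rows with known targets.
#' @param rates Abstention-rate grid in `[0, 1)`; rates that would retain
#'   nothing are dropped.
#' @param n_random Number of random orderings averaged.
#' @param seed Seed for the random orderings.
#' @return data.frame: `rate`, `p95_uncertainty`, `p95_random`.
#' @export
risk_coverage_curve <- function(ensemble, rows,
                                rates = seq(0, 0.5, by = 0.05),
                                n_random = 20L, seed = 1L) {
  if (!length(rates))
    stop_bg("empty abstention-rate grid", "bg_config")
  ycol <- ensemble$final_model$target_col
  assert_columns(rows, ycol, "rows")
  err <- abs(predict(ensemble$final_model, rows) - rows[[ycol]])
  u <- ensemble_uncertainty(ensemble, rows)
  n <- length(err)
  ord_u <- order(u)  # retained set = lowest-uncertainty rows
  perms <- local_seed(seed, replicate(n_random, sample(n),
                                      simplify = FALSE))
  res <- lapply(rates, function(r) {
    k <- floor(r * n)
    if (k >= n) return(NULL)
    keep_u <- ord_u[seq_len(n - k)]
    p_rand <- mean(vapply(perms, function(p)
      p95_abs_error(err[p[seq_len(n - k)]]), numeric(1)))
    data.frame(rate = r,
               p95_uncertainty = p95_abs_error(err[keep_u]),
               p95_random = p_rand)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
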