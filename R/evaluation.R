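# Performance statistics: error percentiles, CLIA agreement, per-range
# breakdowns, time-lag analysis, pH-range coverage, Bland-Altman limits,
# and nonparametric model comparison.

#' 95th percentile of absolute error
#'
#' The headline accuracy statistic: the error magnitude that bounds all
#' but the worst 5% of samples. Quantiles use linear interpolation
#' between order statistics (type 7), fixed because small-bin percentiles
#' are method-sensitive.
#'
#' @param errors Signed or absolute errors.
#' @return Scalar 95th percentile of `abs(errors)`.
#' @export
p95_abs_error <- function(errors) {
  if (!length(errors) || any(is.na(errors)))
    stop_bg("p95_abs_error() needs at least one non-missing error",
            "bg_empty")
  stats::quantile(abs(errors), 0.95, names = FALSE, type = 7)
}

#' Fraction of errors within an agreement bound
#'
#' Fraction of samples with `|error| <= bound`; with the CLIA blood-gas
#' bounds (0.04 pH units, 5 mmHg PCO2) this is the laboratory-equivalence
#' agreement rate.
#'
#' @param errors Signed errors.
#' @param bound Positive agreement bound (same units as errors).
#' @return Fraction in `[0, 1]`.
#' @export
clia_agreement <- function(errors, bound) {
  if (!length(errors))
    stop_bg("clia_agreement() needs at least one error", "bg_empty")
  if (!is.finite(bound) || bound <= 0)
    stop_bg("bound must be positive", "bg_config")
  mean(abs(errors) <= bound)
}

# bin index per pH-range convention: 1 = < lo, 2 = [lo, hi), 3 = >= hi
range_labels <- function(edges) {
  c(sprintf("<%.4g", edges[1]),
    paste0(sprintf("%.4g", edges[1]), "-", sprintf("%.4g", edges[2])),
    sprintf(">=%.4g", edges[2]))
}

#' Does the uncertainty interval cover the correct pH range?
#'
#' A prediction covers the truth's range when the interval
#' `[point - hw, point + hw]` intersects the bin containing the true
#' value (bins `(-Inf, e1)`, `[e1, e2)`, `[e2, Inf)`). With zero
#' half-width this reduces to point-in-bin classification.
#'
#' @param point Point estimates (non-abstained predictions).
#' @param half_width Interval half-widths (>= 0).
#' @param truth True values.
#' @param edges Two bin edges, default `c(7.3, 7.45)`.
#' @return List: `overall` fraction covered, and `per_bin` data.frame
#'   (bin label, n, fraction).
#' @export
range_coverage <- function(point, half_width, truth,
                           edges = c(7.3, 7.45)) {
  if (!length(point))
    stop_bg("range_coverage() needs at least one prediction", "bg_empty")
  stopifnot(length(point) == length(truth),
            length(half_width) %in% c(1L, length(point)))
  half_width <- rep_len(half_width, length(point))
  bin <- ph_bin(truth, edges)
  lo <- c(-Inf, edges)[bin]
  hi <- c(edges, Inf)[bin]
  covered <- (point + half_width) >= lo & (point - half_width) < hi
  per_bin <- do.call(rbind, lapply(1:3, function(b) {
    sel <- bin == b
    data.frame(bin = range_labels(edges)[b], n = sum(sel),
               fraction = if (any(sel)) mean(covered[sel]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(overall = mean(covered), per_bin = per_bin)
}

#' Estimation accuracy as a function of time since the last blood gas
#'
#' Bins samples by the age of the linked previous blood gas and reports
#' the 95th-percentile absolute error per bin. Empty bins are omitted;
#' bins with fewer than `min_n` samples are flagged `low_n`.
#'
#' @param lag_hours Per-sample lag (hours).
#' @param errors Per-sample errors.
#' @param bin_edges Bin boundaries in hours (left-closed, right-open;
#'   last bin right-closed).
#' @param min_n Low-sample flag threshold.
#' @return data.frame: bin label, lower/upper edge, n, `p95`, `low_n`.
#' @export
lag_analysis <- function(lag_hours, errors,
                         bin_edges = c(0, 2, 4, 6, 8, 12, 24),
                         min_n = 20L) {
  stopifnot(length(lag_hours) == length(errors))
  nb <- length(bin_edges) - 1L
  idx <- findInterval(lag_hours, bin_edges, rightmost.closed = TRUE)
  out <- lapply(seq_len(nb), function(b) {
    sel <- idx == b
    if (!any(sel)) return(NULL)
    data.frame(bin = paste0(bin_edges[b], "-", bin_edges[b + 1], "h"),
               lower = bin_edges[b], upper = bin_edges[b + 1],
               n = sum(sel), p95 = p95_abs_error(errors[sel]),
               low_n = sum(sel) < min_n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Bland-Altman agreement statistics
#'
#' Mean difference (bias) between estimates and reference values and the
#' 1.96-SD limits of agreement.
#'
#' @param estimates,truths Paired values (>= 2 pairs).
#' @return List: `mean_error`, `lower`, `upper`, `sd`.
#' @export
bland_altman <- function(estimates, truths) {
  if (length(estimates) < 2L || length(estimates) != length(truths))
    stop_bg("bland_altman() needs >= 2 paired values", "bg_shape")
  d <- estimates - truths
  m <- mean(d)
  s <- stats::sd(d)
  list(mean_error = m, lower = m - 1.96 * s, upper = m + 1.96 * s, sd = s)
}

#' Compare two models' absolute errors (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test on the absolute
#' errors: exact at small sample sizes without ties, normal approximation
#' with tie correction otherwise.
#'
#' @param errors_a,errors_b Signed errors from the two models.
#' @return List: `statistic` (U), `p_value`.
#' @export
compare_models <- function(errors_a, errors_b) {
  if (!length(errors_a) || !length(errors_b))
    stop_bg("compare_models() needs non-empty error sets", "bg_empty")
  ht <- suppressWarnings(stats::wilcox.test(abs(errors_a), abs(errors_b),
                                            alternative = "two.sided"))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Most-recent versus first-available previous blood gas
#'
#' Trains the pairwise model on derivation rows built with the
#' most-recent-previous-blood-gas linkage, then evaluates it on
#' evaluation-cohort rows built under both linkages (most recent prior BG
#' vs the patient's first BG for all subsequent estimations) and reports
#' the two 95th-percentile absolute errors.
#'
#' @param derivation_cohort,evaluation_cohort Cohort data.frames.
#' @param target `"ph"` or `"paco2"`.
#' @param max_lag_hours Previous-BG age limit used for both linkages.
#' @param basis,lambda Model settings (`basis = NULL` uses the training
#'   default).
#' @return List: `p95_previous`, `p95_first`, `n_previous`, `n_first`.
#' @export
first_vs_previous_bg_analysis <- function(derivation_cohort,
                                          evaluation_cohort,
                                          target = c("ph", "paco2"),
                                          max_lag_hours = 24,
                                          basis = NULL,
                                          lambda = 1) {
  target <- match.arg(target)
  train_rows <- build_feature_rows(derivation_cohort, max_lag_hours)
  rows_prev <- build_feature_rows(evaluation_cohort, max_lag_hours,
                                  linkage = "previous")
  rows_first <- build_feature_rows(evaluation_cohort, max_lag_hours,
                                   linkage = "first")
  if (!nrow(rows_prev) || !nrow(rows_first))
    stop_bg("no patients with multiple blood gases in the evaluation cohort",
            "bg_empty")
  fit <- pairwise_reg(train_rows, target = target, basis = basis,
                      lambda = lambda)
  ycol <- fit$target_col
  list(p95_previous = p95_abs_error(predict(fit, rows_prev) -
                                      rows_prev[[ycol]]),
       p95_first = p95_abs_error(predict(fit, rows_first) -
                                   rows_first[[ycol]]),
       n_previous = nrow(rows_prev), n_first = nrow(rows_first))
}

per_range_p95 <- function(truth, err, edges, labels) {
  bin <- findInterval(truth, edges) + 1L
  out <- lapply(seq_along(labels), function(b) {
    sel <- bin == b
    data.frame(range = labels[b], n = sum(sel),
               p95 = if (any(sel)) p95_abs_error(err[sel]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Assemble a full evaluation report
#'
#' Computes every performance statistic on the non-abstained samples:
#' overall and per-range 95th-percentile absolute errors (pH ranges
#' < 7.3 / 7.3-7.45 / >= 7.45; PCO2 ranges 20-35 / 35-60 / 60-120 mmHg),
#' CLIA agreement fractions (|pH error| <= 0.04, |PCO2 error| <= 5 mmHg),
#' pH-range coverage of the uncertainty interval, Bland-Altman limits,
#' and the per-lag-bin p95.
#'
#' @param predictions data.frame with columns `ph_truth`, `ph_est`,
#'   `paco2_truth`, `paco2_est`, `abstained`, `lag_hours`, and
#'   `ph_half_width` (uncertainty interval half-width of the pH
#'   estimate).
#' @param ph_edges,pco2_edges Range boundaries.
#' @param clia_ph,clia_pco2 Agreement bounds.
#' @return List of class `bg_evaluation_report`.
#' @export
evaluation_report <- function(predictions,
                              ph_edges = c(7.3, 7.45),
                              pco2_edges = c(35, 60),
                              clia_ph = 0.04, clia_pco2 = 5) {
  assert_columns(predictions,
                 c("ph_truth", "ph_est", "paco2_truth", "paco2_est",
                   "abstained", "lag_hours", "ph_half_width"),
                 "predictions")
  keep <- !predictions$abstained
  est <- predictions[keep, , drop = FALSE]
  if (!nrow(est))
    stop_bg("all predictions abstained; nothing to evaluate", "bg_empty")
  ph_err <- est$ph_est - est$ph_truth
  pco2_err <- est$paco2_est - est$paco2_truth
  ph_ranges <- per_range_p95(est$ph_truth, ph_err, ph_edges,
                             range_labels(ph_edges))
  pco2_labels <- c("20-35", "35-60", "60-120")
  pco2_ranges <- per_range_p95(est$paco2_truth, pco2_err, pco2_edges,
                               pco2_labels)
  cov <- range_coverage(est$ph_est, est$ph_half_width, est$ph_truth,
                        ph_edges)
  rep <- list(
    n_total = nrow(predictions),
    n_estimated = nrow(est),
    abstention_rate = mean(predictions$abstained),
    p95_ph = p95_abs_error(ph_err),
    p95_ph_ranges = ph_ranges,
    p95_pco2 = p95_abs_error(pco2_err),
    p95_pco2_ranges = pco2_ranges,
    clia_fraction_ph = clia_agreement(ph_err, clia_ph),
    clia_fraction_pco2 = clia_agreement(pco2_err, clia_pco2),
    range_coverage = cov,
    bland_altman_ph = bland_altman(est$ph_est, est$ph_truth),
    bland_altman_pco2 = bland_altman(est$paco2_est, est$paco2_truth),
    lag_p95 = lag_analysis(est$lag_hours, ph_err))
  class(rep) <- "bg_evaluation_report"
  rep
}

#' @export
print.bg_evaluation_report <- function(x, ...) {
  cat(sprintf("Blood-gas estimation report: %d/%d samples estimated (%.1f%% abstained)\n",
              x$n_estimated, x$n_total, 100 * x$abstention_rate))
  cat(sprintf("  pH:   p95 |error| %.3f, CLIA (+/-0.04) %.1f%%\n",
              x$p95_ph, 100 * x$clia_fraction_ph))
  cat(sprintf("  PCO2: p95 |error| %.2f mmHg, CLIA (+/-5) %.1f%%\n",
              x$p95_pco2, 100 * x$clia_fraction_pco2))
  cat(sprintf("  pH-range coverage: %.1f%%\n",
              100 * x$range_coverage$overall))
  cat("  per-range pH p95:\n")
  print(x$p95_ph_ranges, row.names = FALSE)
  cat("  lag bins (pH p95):\n")
  print(x$lag_p95, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report A [evaluation_report()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, path) {
  stopifnot(inherits(report, "bg_evaluation_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' Read an evaluation report written by [write_evaluation_report()]
#'
#' @param path JSON file.
#' @return A `bg_evaluation_report`.
#' @export
read_evaluation_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(rep) <- "bg_evaluation_report"
  rep
}
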