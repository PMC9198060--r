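# Feature engineering: turn per-patient blood-gas timelines into
# predictor/target rows (previous blood gas + current noninvasive
# measurements), with plausibility filtering, pH-balancing resampling of
# derivation data, and patient-grouped pH-stratified nested CV splits.

#' Default physiologic plausibility ranges
#'
#' Generous bounds used to drop implausible measurements before feature
#' construction; every range is configurable.
#'
#' @return Named list of `c(min, max)` per cohort variable.
#' @export
bg_plausibility_ranges <- function() {
  list(ph = c(6.5, 7.8), paco2 = c(10, 150), hco3 = c(2, 60),
       petco2 = c(0, 150), spo2 = c(0, 100), fio2 = c(21, 100),
       peep = c(0, 25), pip = c(0, 60), mnawp = c(0, 45),
       tv_in = c(0, 25), tv_exp = c(0, 25))
}

#' Plausibility filter
#'
#' Removes observations with any measurement outside its plausible range
#' and logs every violation. `NA` values are not treated as violations
#' (missingness is handled downstream).
#'
#' @param cohort A cohort data.frame.
#' @param ranges Named list of `c(min, max)`; must cover every variable it
#'   names that exists in the cohort. Defaults to
#'   [bg_plausibility_ranges()].
#' @return List with `cohort` (surviving rows, class preserved) and
#'   `rejections` (data.frame: patient_id, time, variable, value, min,
#'   max).
#' @export
plausibility_filter <- function(cohort, ranges = bg_plausibility_ranges()) {
  vars <- intersect(names(ranges), names(cohort))
  bad <- rep(FALSE, nrow(cohort))
  logs <- list()
  for (v in vars) {
    r <- ranges[[v]]
    viol <- !is.na(cohort[[v]]) & (cohort[[v]] < r[1] | cohort[[v]] > r[2])
    if (any(viol))
      logs[[v]] <- data.frame(patient_id = cohort$patient_id[viol],
                              time = cohort$time[viol], variable = v,
                              value = cohort[[v]][viol],
                              min = r[1], max = r[2],
                              stringsAsFactors = FALSE)
    bad <- bad | viol
  }
  rejections <- if (length(logs)) do.call(rbind, logs) else
    data.frame(patient_id = character(0), time = numeric(0),
               variable = character(0), value = numeric(0),
               min = numeric(0), max = numeric(0))
  rownames(rejections) <- NULL
  kept <- cohort[!bad, , drop = FALSE]
  rownames(kept) <- NULL
  list(cohort = kept, rejections = rejections)
}

#' Predictor names of the estimation model
#'
#' The non-key predictors: previous blood-gas values, current and previous
#' end-tidal CO2, and current-minus-previous deltas of ventilator and
#' oximetry measurements. The key predictor (previous pH, `ph_prev`) is
#' kept separate.
#'
#' @return Character vector of feature-row column names.
#' @export
bg_default_predictors <- function() {
  c("paco2_prev", "hco3_prev", "etco2_t", "etco2_prev", "d_fio2",
    "d_peep", "d_pip", "d_mnawp", "d_spo2", "d_tvin", "d_tvexp")
}

#' Build predictor/target rows from a cohort
#'
#' Each blood-gas observation with a prior blood gas within
#' `max_lag_hours` yields one row: targets are the current pH and PaCO2;
#' predictors are the linked previous blood gas (pH, PaCO2, HCO3-),
#' end-tidal CO2 at both times, and delta terms
#' `d_x = x[t] - x[t-1]`. The first observation of a patient yields no
#' row, and rows with missing end-tidal CO2 at either time are dropped.
#' Current FiO2 and mean airway pressure are carried along (columns
#' `fio2_t`, `mnawp_t`) for the capnography-free baseline.
#'
#' @param cohort Cohort data.frame, time-sorted within patient (strictly
#'   increasing times; violations are an error).
#' @param max_lag_hours Maximum allowed age of the previous blood gas.
#' @param linkage `"previous"` links each observation to the most recent
#'   prior blood gas; `"first"` links every observation to the patient's
#'   first blood gas (used by the accuracy-over-time analysis).
#' @return A data.frame of class `bg_feature_rows`.
#' @export
build_feature_rows <- function(cohort, max_lag_hours = 24,
                               linkage = c("previous", "first")) {
  linkage <- match.arg(linkage)
  assert_columns(cohort, cohort_columns(), "cohort")
  pieces <- lapply(split(seq_len(nrow(cohort)), cohort$patient_id),
                   function(idx) {
    d <- cohort[idx[order(cohort$time[idx])], , drop = FALSE]
    if (any(diff(d$time) <= 0))
      stop_bg(sprintf("non-increasing timestamps for patient %s",
                      d$patient_id[1]), "bg_unordered_times")
    n <- nrow(d)
    if (n < 2) return(NULL)
    cur <- 2:n
    prev <- if (linkage == "previous") cur - 1L else rep(1L, n - 1L)
    lag <- d$time[cur] - d$time[prev]
    keep <- lag > 0 & lag <= max_lag_hours &
      !is.na(d$petco2[cur]) & !is.na(d$petco2[prev])
    cur <- cur[keep]; prev <- prev[keep]
    if (!length(cur)) return(NULL)
    data.frame(patient_id = d$patient_id[cur],
               t_current = d$time[cur], t_previous = d$time[prev],
               lag_hours = d$time[cur] - d$time[prev],
               ph_t = d$ph[cur], paco2_t = d$paco2[cur],
               ph_prev = d$ph[prev], paco2_prev = d$paco2[prev],
               hco3_prev = d$hco3[prev],
               etco2_t = d$petco2[cur], etco2_prev = d$petco2[prev],
               d_fio2 = d$fio2[cur] - d$fio2[prev],
               d_peep = d$peep[cur] - d$peep[prev],
               d_pip = d$pip[cur] - d$pip[prev],
               d_mnawp = d$mnawp[cur] - d$mnawp[prev],
               d_spo2 = d$spo2[cur] - d$spo2[prev],
               d_tvin = d$tv_in[cur] - d$tv_in[prev],
               d_tvexp = d$tv_exp[cur] - d$tv_exp[prev],
               bg_type_prev = d$bg_type[prev],
               bg_type_t = d$bg_type[cur],
               fio2_t = d$fio2[cur], mnawp_t = d$mnawp[cur],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- build_feature_rows_empty()
  rownames(out) <- NULL
  class(out) <- c("bg_feature_rows", "data.frame")
  out
}

build_feature_rows_empty <- function() {
  cols <- c("patient_id", "t_current", "t_previous", "lag_hours", "ph_t",
            "paco2_t", "ph_prev", "paco2_prev", "hco3_prev", "etco2_t",
            "etco2_prev", "d_fio2", "d_peep", "d_pip", "d_mnawp",
            "d_spo2", "d_tvin", "d_tvexp", "bg_type_prev", "bg_type_t",
            "fio2_t", "mnawp_t")
  out <- as.data.frame(stats::setNames(
    lapply(cols, function(cn)
      if (cn %in% c("patient_id", "bg_type_prev", "bg_type_t"))
        character(0) else numeric(0)), cols))
  out
}

ph_bin <- function(ph, edges = c(7.3, 7.45)) {
  findInterval(ph, edges) + 1L  # 1: < edges[1], 2: mid, 3: >= edges[2]
}

#' Resample rows to balance the pH distribution
#'
#' Derivation data is rebalanced so that sparsely represented pH regions
#' carry more weight: rows in over-represented bins are subsampled without
#' replacement and rows in under-represented bins are duplicated by
#' sampling with replacement, until bin masses match `target_weights`.
#' Multiplicities of every original row are recorded in
#' `attr(, "resample_map")`, so the original distribution is recoverable.
#' Never apply this to validation data: validation performance should
#' reflect the natural blood-gas distribution.
#'
#' @param rows Feature rows.
#' @param bin_edges pH bin edges (default 7.3, 7.45).
#' @param target_weights Target bin masses, one per bin (default the
#'   derivation rebalancing weights 0.17/0.54/0.29), normalized to sum 1.
#' @param seed Seed for the per-bin sampling.
#' @return Resampled rows (same class) with `attr(, "resample_map")`:
#'   data.frame `orig_index`, `multiplicity` covering all input rows.
#' @export
resample_by_ph <- function(rows, bin_edges = c(7.3, 7.45),
                           target_weights = c(0.17, 0.54, 0.29),
                           seed = 1L) {
  if (!nrow(rows)) return(rows)
  if (length(target_weights) != length(bin_edges) + 1L)
    stop_bg("need one target weight per pH bin", "bg_config")
  bins <- ph_bin(rows$ph_t, bin_edges)
  counts <- tabulate(bins, nbins = length(target_weights))
  w <- target_weights
  if (any(w[counts == 0] > 0)) {
    warning("empty pH bin(s) with positive target weight; weight redistributed",
            call. = FALSE)
    w[counts == 0] <- 0
  }
  w <- w / sum(w)
  n <- nrow(rows)
  target_n <- floor(n * w)
  # distribute the remainder to the largest fractional parts, ties by bin
  rem <- n - sum(target_n)
  if (rem > 0) {
    frac <- n * w - floor(n * w)
    add <- order(-frac, seq_along(w))[seq_len(rem)]
    target_n[add] <- target_n[add] + 1L
  }
  local_seed(seed, {
    picked <- unlist(lapply(seq_along(w), function(b) {
      idx <- which(bins == b)
      k <- target_n[b]
      if (k == 0L || !length(idx)) return(integer(0))
      if (k == length(idx)) idx
      else if (k < length(idx)) sort(sample(idx, k, replace = FALSE))
      else c(idx, sample(idx, k - length(idx), replace = TRUE))
    }), use.names = FALSE)
    out <- rows[picked, , drop = FALSE]
    rownames(out) <- NULL
    mult <- tabulate(picked, nbins = n)
    attr(out, "resample_map") <- data.frame(orig_index = seq_len(n),
                                            multiplicity = mult)
    class(out) <- class(rows)
    out
  })
}

#' Patient-grouped, pH-stratified nested cross-validation plan
#'
#' Assigns whole patients to `outer` folds (no patient appears in two
#' outer folds) and, within each outer fold, to `inner` folds.
#' Stratification orders patients by their mean target pH and deals
#' consecutive blocks across folds in random order, so each fold's pH
#' composition tracks the global one.
#'
#' @param rows Feature rows.
#' @param outer,inner Fold counts (default 5 and 5).
#' @param seed Seed for the within-block shuffles.
#' @return An object of class `bg_split_plan`: data.frame `patients`
#'   (patient_id, outer_fold, inner_fold) plus fold counts.
#' @export
make_split_plan <- function(rows, outer = 5L, inner = 5L, seed = 1L) {
  ids <- unique(rows$patient_id)
  if (length(ids) < outer)
    stop_bg(sprintf("need at least %d patients for %d outer folds (have %d)",
                    outer, outer, length(ids)), "bg_too_few_patients")
  mean_ph <- tapply(rows$ph_t, rows$patient_id, mean)[ids]
  local_seed(seed, {
    ord <- order(mean_ph + stats::rnorm(length(ids), 0, 1e-9))
    sorted <- ids[ord]
    assign_folds <- function(k, n_folds) {
      # serpentine block deal: each consecutive block of n_folds patients
      # receives a random permutation of the fold labels
      f <- integer(k)
      for (s in seq(1L, k, by = n_folds)) {
        blk <- s:min(s + n_folds - 1L, k)
        f[blk] <- sample(n_folds)[seq_along(blk)]
      }
      f
    }
    outer_fold <- assign_folds(length(sorted), outer)
    inner_fold <- integer(length(sorted))
    for (o in seq_len(outer)) {
      sel <- which(outer_fold == o)
      # preserve pH order within the outer fold, then deal inner blocks
      inner_fold[sel] <- assign_folds(length(sel), inner)
    }
    plan <- data.frame(patient_id = sorted, outer_fold = outer_fold,
                       inner_fold = inner_fold, stringsAsFactors = FALSE)
    plan <- plan[order(plan$patient_id), ]
    rownames(plan) <- NULL
    structure(list(patients = plan, outer = as.integer(outer),
                   inner = as.integer(inner), seed = seed),
              class = "bg_split_plan")
  })
}

#' Row-level fold assignment under a split plan
#'
#' @param plan A [make_split_plan()] result.
#' @param rows Feature rows.
#' @return data.frame with `outer_fold`, `inner_fold` per row.
#' @export
split_assignment <- function(plan, rows) {
  m <- match(rows$patient_id, plan$patients$patient_id)
  if (anyNA(m))
    stop_bg("rows contain patients absent from the split plan",
            "bg_unknown_patient")
  data.frame(outer_fold = plan$patients$outer_fold[m],
             inner_fold = plan$patients$inner_fold[m])
}

#' @export
print.bg_split_plan <- function(x, ...) {
  cat(sprintf("Nested CV plan: %d outer x %d inner folds, %d patients\n",
              x$outer, x$inner, nrow(x$patients)))
  print(table(outer = x$patients$outer_fold))
  invisible(x)
}
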