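# Physiologic baseline models: alveolar dead-space carry-forward with
# Henderson-Hasselbalch, and a capnography-free linear regression in the
# style of Baudin et al. (PetCO2 + FiO2 + mean airway pressure).

# Standard acid-base constants: apparent pK of the bicarbonate buffer
# system and the solubility of CO2 in plasma (mmol/L per mmHg).
HH_PK <- 6.1
HH_CO2_SOLUBILITY <- 0.03

#' Alveolar dead-space fraction
#'
#' `AVDSf = (PaCO2 - PetCO2) / PaCO2`, the fraction of tidal ventilation
#' reaching unperfused alveoli. Healthy lungs have AVDSf near 0; severe
#' ventilation/perfusion mismatch pushes it towards 1. Values can be
#' negative when measurement noise puts PetCO2 above PaCO2; such values
#' are returned as-is (a warning is emitted) rather than clipped.
#'
#' @param paco2 Arterial CO2 tension, mmHg. Must be positive.
#' @param petco2 End-tidal CO2, mmHg.
#' @return Dead-space fraction, dimensionless.
#' @examples
#' avdsf(45, 40) # 0.111...
#' @export
avdsf <- function(paco2, petco2) {
  if (any(!is.finite(paco2)) || any(!is.finite(petco2)))
    stop_bg("avdsf() requires finite inputs", "bg_nonfinite")
  if (any(paco2 <= 0))
    stop_bg("avdsf() requires paco2 > 0", "bg_domain")
  out <- (paco2 - petco2) / paco2
  n_neg <- sum(out < 0)
  if (n_neg > 0)
    warning(sprintf("%d negative AVDSf value(s) (PetCO2 > PaCO2); retained",
                    n_neg), call. = FALSE)
  out
}

#' Henderson-Hasselbalch pH
#'
#' Computes blood pH from the respiratory (PaCO2) and metabolic (HCO3-)
#' components: `pH = 6.1 + log10(HCO3 / (0.03 * PaCO2))`.
#'
#' @param paco2 Arterial CO2 tension, mmHg (> 0).
#' @param hco3 Bicarbonate, mmol/L (> 0).
#' @return pH (dimensionless).
#' @examples
#' henderson_hasselbalch_ph(40, 24) # 7.401
#' @export
henderson_hasselbalch_ph <- function(paco2, hco3) {
  if (any(!is.finite(paco2)) || any(!is.finite(hco3)) ||
      any(paco2 <= 0) || any(hco3 <= 0))
    stop_bg("henderson_hasselbalch_ph() requires positive finite inputs",
            "bg_domain")
  HH_PK + log10(hco3 / (HH_CO2_SOLUBILITY * paco2))
}

#' Bicarbonate consistent with a (pH, PaCO2) pair
#'
#' Inverts the Henderson-Hasselbalch relation; used by the cohort
#' simulator to seed metabolic state at a desired pH.
#'
#' @inheritParams henderson_hasselbalch_ph
#' @param ph Blood pH.
#' @return HCO3-, mmol/L.
#' @export
henderson_hasselbalch_hco3 <- function(ph, paco2) {
  if (any(!is.finite(ph)) || any(!is.finite(paco2)) || any(paco2 <= 0))
    stop_bg("henderson_hasselbalch_hco3() requires finite inputs, paco2 > 0",
            "bg_domain")
  HH_CO2_SOLUBILITY * paco2 * 10^(ph - HH_PK)
}

#' Dead-space carry-forward blood gas baseline
#'
#' The physiologic comparison model: the dead-space fraction observed at
#' the previous blood gas is assumed unchanged, so the current PaCO2 is
#' estimated by inflating the current end-tidal CO2, and the current pH
#' follows from Henderson-Hasselbalch with the previous bicarbonate
#' carried forward:
#' \deqn{PaCO2_t = PetCO2_t / (1 - AVDSf_{t-1}), \quad
#'       pH_t = 6.1 + log10(HCO3_{t-1} / (0.03 PaCO2_t)).}
#'
#' @param rows Feature rows (see [build_feature_rows()]); must carry
#'   `paco2_prev`, `etco2_prev`, `hco3_prev` and `etco2_t`.
#' @return A data.frame with columns `paco2_est`, `ph_est` and a logical
#'   `estimated` flag; rows whose previous dead-space fraction is >= 1
#'   (non-invertible) are flagged `FALSE` with `NA` estimates.
#' @export
avdsf_baseline_predict <- function(rows) {
  assert_columns(rows, c("paco2_prev", "etco2_prev", "hco3_prev", "etco2_t"),
                 "feature rows")
  avdsf_prev <- avdsf(rows$paco2_prev, rows$etco2_prev)
  ok <- avdsf_prev < 1
  paco2_est <- ifelse(ok, rows$etco2_t / (1 - avdsf_prev), NA_real_)
  ok <- ok & is.finite(paco2_est) & paco2_est > 0
  ph_est <- rep(NA_real_, nrow(rows))
  if (any(ok))
    ph_est[ok] <- henderson_hasselbalch_ph(paco2_est[ok], rows$hco3_prev[ok])
  data.frame(paco2_est = ifelse(ok, paco2_est, NA_real_),
             ph_est = ph_est, estimated = ok)
}

#' Capnography-free linear baseline
#'
#' Ordinary least-squares regression of a blood-gas target on current
#' end-tidal CO2, FiO2 and mean airway pressure, the predictor set used by
#' Baudin-style capnography-free models. Coefficients are refitted on the
#' derivation data at hand.
#'
#' @param rows Feature rows carrying `etco2_t`, `fio2_t`, `mnawp_t` and the
#'   target column.
#' @param target `"ph"` or `"paco2"`.
#' @return An object of class `bg_baudin` wrapping the `lm` fit.
#' @export
fit_baudin <- function(rows, target = c("ph", "paco2")) {
  target <- match.arg(target)
  ycol <- paste0(target, "_t")
  assert_columns(rows, c("etco2_t", "fio2_t", "mnawp_t", ycol),
                 "feature rows")
  fit <- stats::lm(stats::reformulate(c("etco2_t", "fio2_t", "mnawp_t"),
                                      response = ycol),
                   data = rows)
  if (any(is.na(stats::coef(fit))))
    stop_bg("rank-deficient design in fit_baudin()", "bg_rank_deficient")
  structure(list(target = target, fit = fit,
                 coefficients = stats::coef(fit)),
            class = "bg_baudin")
}

#' @export
predict.bg_baudin <- function(object, newdata, ...) {
  assert_columns(newdata, c("etco2_t", "fio2_t", "mnawp_t"), "newdata")
  unname(stats::predict(object$fit, newdata = newdata))
}

#' @export
print.bg_baudin <- function(x, ...) {
  cat("Capnography-free linear baseline (target:", x$target, ")\n")
  print(x$coefficients)
  invisible(x)
}
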