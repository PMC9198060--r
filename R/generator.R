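# Synthetic ventilated-patient cohort simulator.
#
# Latent physiology per patient: PaCO2 follows a mean-reverting AR(1)
# around a patient equilibrium that ventilator interventions shift;
# bicarbonate follows a slow random walk (the metabolic component); pH is
# computed exactly from the two via Henderson-Hasselbalch; end-tidal CO2
# is PaCO2 reduced by a per-patient alveolar dead-space fraction plus
# capnograph noise. Irregular sampling times mimic clinical blood-gas
# draws (lognormal inter-sample gaps).

#' Configuration for the synthetic cohort simulator
#'
#' Defaults emulate a general pediatric ICU cohort: inter-blood-gas
#' intervals with median ~4.5 h, alveolar dead-space fraction 0.11 +/- 0.06,
#' PaCO2 centered near 45 mmHg, roughly 70% of pH values in 7.3-7.45 with
#' acidotic and alkalotic tails, and 10% capillary samples.
#'
#' @param n_patients Number of patients.
#' @param mean_obs_per_patient Mean blood-gas count per patient (>= 1);
#'   counts are `1 + Poisson(mean - 1)`.
#' @param inter_bg_hours_median Median hours between consecutive blood
#'   gases (lognormal gaps, `sdlog = inter_bg_hours_sdlog`).
#' @param inter_bg_hours_sdlog Lognormal spread of the gaps.
#' @param avdsf_mean,avdsf_sd Population mean / SD of the per-patient
#'   alveolar dead-space fraction (truncated to `[0, 0.6]`).
#' @param paco2_ar_coeff AR(1) coefficient of the PaCO2 process per median
#'   inter-sample step, in `[0, 1)`; gaps of other lengths use
#'   `coeff^(dt/median)` so serial correlation decays with elapsed time.
#' @param paco2_noise_sd PaCO2 innovation SD (mmHg) per median step;
#'   scaled by `sqrt(dt/median)` for irregular gaps.
#' @param metabolic_drift_sd Bicarbonate random-walk SD (mmol/L) per
#'   median step.
#' @param petco2_noise_sd Capnograph measurement noise SD (mmHg).
#' @param intervention_prob Probability per step of a ventilator setting
#'   change.
#' @param intervention_effect_mmHg_per_cmH2O Shift of the PaCO2
#'   equilibrium per cmH2O of added ventilator pressure (sign: more
#'   pressure lowers CO2).
#' @param ph_tail_fraction Fraction of patients seeded outside 7.3-7.45.
#' @param acidotic_tail_share Share of tail patients seeded acidotic (the
#'   rest alkalotic).
#' @param noise_heterogeneity Lognormal sdlog of a per-patient multiplier
#'   applied to `paco2_noise_sd` and `petco2_noise_sd`; encodes
#'   between-patient differences in physiologic stability and makes the
#'   cohort heteroscedastic.
#' @param capillary_fraction Probability a sample is capillary rather than
#'   arterial.
#' @param seed Integer seed; identical seed + config gives a bit-identical
#'   cohort.
#' @return A validated list of class `bg_generator_config`.
#' @export
bg_generator_config <- function(n_patients = 100L,
                                mean_obs_per_patient = 6,
                                inter_bg_hours_median = 4.5,
                                inter_bg_hours_sdlog = 0.6,
                                avdsf_mean = 0.11,
                                avdsf_sd = 0.06,
                                paco2_ar_coeff = 0.85,
                                paco2_noise_sd = 3,
                                metabolic_drift_sd = 0.5,
                                petco2_noise_sd = 1.5,
                                intervention_prob = 0.25,
                                intervention_effect_mmHg_per_cmH2O = 0.8,
                                ph_tail_fraction = 0.29,
                                acidotic_tail_share = 0.38,
                                noise_heterogeneity = 0.4,
                                capillary_fraction = 0.10,
                                seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              mean_obs_per_patient = mean_obs_per_patient,
              inter_bg_hours_median = inter_bg_hours_median,
              inter_bg_hours_sdlog = inter_bg_hours_sdlog,
              avdsf_mean = avdsf_mean, avdsf_sd = avdsf_sd,
              paco2_ar_coeff = paco2_ar_coeff,
              paco2_noise_sd = paco2_noise_sd,
              metabolic_drift_sd = metabolic_drift_sd,
              petco2_noise_sd = petco2_noise_sd,
              intervention_prob = intervention_prob,
              intervention_effect_mmHg_per_cmH2O =
                intervention_effect_mmHg_per_cmH2O,
              ph_tail_fraction = ph_tail_fraction,
              acidotic_tail_share = acidotic_tail_share,
              noise_heterogeneity = noise_heterogeneity,
              capillary_fraction = capillary_fraction,
              seed = as.integer(seed))
  num <- unlist(cfg)
  if (any(!is.finite(num)))
    stop_bg("generator config contains non-finite values", "bg_config")
  fr <- c("avdsf_mean", "intervention_prob", "ph_tail_fraction",
          "acidotic_tail_share", "capillary_fraction")
  if (any(unlist(cfg[fr]) < 0) || any(unlist(cfg[fr]) > 1))
    stop_bg("generator config fractions must lie in [0, 1]", "bg_config")
  sds <- c("avdsf_sd", "paco2_noise_sd", "metabolic_drift_sd",
           "petco2_noise_sd", "noise_heterogeneity",
           "inter_bg_hours_sdlog")
  if (any(unlist(cfg[sds]) < 0))
    stop_bg("generator config SDs must be >= 0", "bg_config")
  if (cfg$paco2_ar_coeff < 0 || cfg$paco2_ar_coeff >= 1)
    stop_bg("paco2_ar_coeff must lie in [0, 1)", "bg_config")
  if (cfg$n_patients < 0 || cfg$mean_obs_per_patient < 1)
    stop_bg("need n_patients >= 0 and mean_obs_per_patient >= 1",
            "bg_config")
  structure(cfg, class = "bg_generator_config")
}

#' @export
print.bg_generator_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d patients, ~%.1f blood gases each, median gap %.1f h\n",
              x$n_patients, x$mean_obs_per_patient,
              x$inter_bg_hours_median))
  cat(sprintf("  AVDSf %.2f +/- %.2f, seed %d\n",
              x$avdsf_mean, x$avdsf_sd, x$seed))
  invisible(x)
}

# One patient's latent state draws. Seeded mid-band patients start near
# pH 7.38; acidotic tails near 7.22 (mostly respiratory: higher CO2
# equilibrium), alkalotic tails near 7.49.
simulate_patient <- function(id, cfg) {
  n_obs <- 1L + stats::rpois(1L, max(cfg$mean_obs_per_patient - 1, 0))
  in_tail <- stats::runif(1) < cfg$ph_tail_fraction
  grp <- if (!in_tail) "normal"
         else if (stats::runif(1) < cfg$acidotic_tail_share) "acidotic"
         else "alkalotic"
  ph0 <- switch(grp,
                normal    = stats::rnorm(1, 7.385, 0.035),
                acidotic  = stats::rnorm(1, 7.22, 0.05),
                alkalotic = stats::rnorm(1, 7.49, 0.03))
  ph0 <- clamp(ph0, 6.9, 7.65)
  mu_paco2 <- switch(grp,
                     normal    = stats::rnorm(1, 45, 5),
                     acidotic  = stats::rnorm(1, 57, 8),
                     alkalotic = stats::rnorm(1, 38, 4))
  mu_paco2 <- clamp(mu_paco2, 22, 90)
  avdsf_p <- clamp(stats::rnorm(1, cfg$avdsf_mean, cfg$avdsf_sd), 0, 0.6)
  noise_mult <- exp(stats::rnorm(1, 0, cfg$noise_heterogeneity))

  ref <- cfg$inter_bg_hours_median
  gaps <- if (n_obs > 1)
    stats::rlnorm(n_obs - 1L, meanlog = log(ref),
                  sdlog = cfg$inter_bg_hours_sdlog)
  else numeric(0)
  times <- cumsum(c(stats::runif(1, 0, 12), gaps))

  # ventilator settings
  peep <- clamp(stats::rnorm(1, 7, 2), 3, 14)
  pip <- peep + clamp(stats::rnorm(1, 14, 3), 8, 28)
  fio2 <- clamp(stats::rnorm(1, 45, 12), 21, 100)

  paco2 <- hco3 <- peep_v <- pip_v <- fio2_v <- numeric(n_obs)
  mu_k <- mu_paco2
  paco2[1] <- clamp(mu_k + stats::rnorm(1, 0, cfg$paco2_noise_sd * noise_mult),
                    12, 140)
  hco3[1] <- clamp(henderson_hasselbalch_hco3(ph0, paco2[1]), 8, 50)
  peep_v[1] <- peep; pip_v[1] <- pip; fio2_v[1] <- fio2
  if (n_obs > 1) for (k in 2:n_obs) {
    dt <- gaps[k - 1L]
    dpressure <- 0
    if (stats::runif(1) < cfg$intervention_prob) {
      dpip <- sample(c(-4, -2, 2, 4), 1L)
      pip <- clamp(pip + dpip, peep + 6, 55)
      dpressure <- dpressure + dpip
      if (stats::runif(1) < 0.3) {
        dpeep <- sample(c(-2, 2), 1L)
        peep <- clamp(peep + dpeep, 3, 16)
        dpressure <- dpressure + dpeep
      }
      if (stats::runif(1) < 0.5)
        fio2 <- clamp(fio2 + sample(c(-10, -5, 5, 10), 1L), 21, 100)
    }
    # interventions shift the CO2 equilibrium; more pressure ventilates
    # more and lowers CO2
    mu_k <- clamp(mu_k - cfg$intervention_effect_mmHg_per_cmH2O * dpressure,
                  18, 110)
    phi <- cfg$paco2_ar_coeff^(dt / ref)
    innov_sd <- cfg$paco2_noise_sd * noise_mult * sqrt(dt / ref)
    paco2[k] <- clamp(mu_k + phi * (paco2[k - 1L] - mu_k) +
                        stats::rnorm(1, 0, innov_sd), 12, 140)
    hco3[k] <- clamp(hco3[k - 1L] +
                       stats::rnorm(1, 0, cfg$metabolic_drift_sd *
                                      sqrt(dt / ref)), 8, 50)
    peep_v[k] <- peep; pip_v[k] <- pip; fio2_v[k] <- fio2
  }

  ph <- henderson_hasselbalch_ph(paco2, hco3)
  petco2 <- pmax(paco2 * (1 - avdsf_p) +
                   stats::rnorm(n_obs, 0, cfg$petco2_noise_sd * noise_mult),
                 0)
  # bounded monotone oxygenation map: SpO2 rises with FiO2, saturates at 100
  spo2 <- clamp(100 - 30 * exp(-0.05 * (fio2_v - 21)) +
                  stats::rnorm(n_obs, 0, 1.2), 70, 100)
  mnawp <- clamp((pip_v + 2 * peep_v) / 3 + stats::rnorm(n_obs, 0, 0.5),
                 2, 45)
  tv_in <- clamp(stats::rnorm(n_obs, 7.5, 1.0) +
                   0.05 * (pip_v - peep_v - 14), 3, 15)
  tv_exp <- pmax(tv_in - abs(stats::rnorm(n_obs, 0.3, 0.2)), 2)
  bg_type <- ifelse(stats::runif(n_obs) < cfg$capillary_fraction,
                    "capillary", "arterial")

  list(obs = data.frame(patient_id = sprintf("P%04d", id),
                        time = times, ph = ph, paco2 = paco2, hco3 = hco3,
                        bg_type = bg_type, petco2 = petco2, spo2 = spo2,
                        fio2 = fio2_v, peep = peep_v, pip = pip_v,
                        mnawp = mnawp, tv_in = tv_in, tv_exp = tv_exp,
                        stringsAsFactors = FALSE),
       latent = data.frame(patient_id = sprintf("P%04d", id),
                           avdsf = avdsf_p, paco2_setpoint = mu_paco2,
                           seeded_ph = ph0, group = grp,
                           noise_mult = noise_mult,
                           stringsAsFactors = FALSE))
}

#' Simulate a synthetic ventilated-patient cohort
#'
#' Generates per-patient timelines of blood-gas samples with
#' contemporaneous noninvasive measurements. pH is computed exactly from
#' the latent (PaCO2, HCO3-) pair via [henderson_hasselbalch_ph()], so
#' generated triples are Henderson-Hasselbalch consistent by construction;
#' before capnograph noise, PetCO2 never exceeds PaCO2.
#'
#' @param config A [bg_generator_config()].
#' @return A data.frame of class `bg_cohort`, one row per timestamped
#'   observation, with per-patient latent truth (dead-space fraction,
#'   equilibrium PaCO2, seeding group) in `attr(, "patients")` and the
#'   generating config in `attr(, "config")`.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "bg_generator_config"))
    config <- do.call(bg_generator_config, as.list(config))
  local_seed(config$seed, {
    if (config$n_patients == 0L) {
      out <- empty_cohort()
      attr(out, "patients") <- data.frame(patient_id = character(0),
                                          avdsf = numeric(0))
      attr(out, "config") <- config
      class(out) <- c("bg_cohort", "data.frame")
      return(out)
    }
    sims <- lapply(seq_len(config$n_patients), simulate_patient, cfg = config)
    out <- do.call(rbind, lapply(sims, `[[`, "obs"))
    rownames(out) <- NULL
    attr(out, "patients") <- do.call(rbind, lapply(sims, `[[`, "latent"))
    attr(out, "config") <- config
    class(out) <- c("bg_cohort", "data.frame")
    out
  })
}

cohort_columns <- function() {
  c("patient_id", "time", "ph", "paco2", "hco3", "bg_type", "petco2",
    "spo2", "fio2", "peep", "pip", "mnawp", "tv_in", "tv_exp")
}

empty_cohort <- function() {
  out <- data.frame(patient_id = character(0), time = numeric(0),
                    ph = numeric(0), paco2 = numeric(0), hco3 = numeric(0),
                    bg_type = character(0), petco2 = numeric(0),
                    spo2 = numeric(0), fio2 = numeric(0), peep = numeric(0),
                    pip = numeric(0), mnawp = numeric(0),
                    tv_in = numeric(0), tv_exp = numeric(0),
                    stringsAsFactors = FALSE)
  out
}

med_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, na.rm = TRUE)
  c(median = q[2], q25 = q[1], q75 = q[3])
}

#' Summary statistics of a simulated or loaded cohort
#'
#' Reports median (IQR) of pH, PaCO2, PetCO2, the empirical dead-space
#' fraction `(PaCO2 - PetCO2)/PaCO2`, inter-blood-gas hours, and the pH
#' range fractions (< 7.3, 7.3-7.45, >= 7.45) used throughout.
#'
#' @param cohort A `bg_cohort` (or any data.frame with the cohort columns).
#' @return A list of class `bg_realism_report`: `stats` (one row per
#'   variable: median/q25/q75) and `ph_fractions`.
#' @export
cohort_realism_report <- function(cohort) {
  if (nrow(cohort) == 0)
    stop_bg("cohort_realism_report() requires a non-empty cohort",
            "bg_empty")
  assert_columns(cohort, c("patient_id", "time", "ph", "paco2", "petco2"),
                 "cohort")
  gaps <- unlist(lapply(split(cohort$time, cohort$patient_id), function(t)
    diff(sort(t))), use.names = FALSE)
  vals <- list(ph = cohort$ph, paco2 = cohort$paco2,
               petco2 = cohort$petco2,
               avdsf = (cohort$paco2 - cohort$petco2) / cohort$paco2,
               inter_bg_hours = if (length(gaps)) gaps else NA_real_)
  stats_tbl <- do.call(rbind, lapply(vals, med_iqr))
  ph <- cohort$ph
  fr <- c(acidotic = mean(ph < 7.3),
          mid = mean(ph >= 7.3 & ph < 7.45),
          alkalotic = mean(ph >= 7.45))
  structure(list(stats = as.data.frame(stats_tbl),
                 ph_fractions = fr, n_obs = nrow(cohort),
                 n_patients = length(unique(cohort$patient_id))),
            class = "bg_realism_report")
}

#' @export
print.bg_realism_report <- function(x, digits = 3, ...) {
  cat(sprintf("Cohort: %d observations, %d patients\n",
              x$n_obs, x$n_patients))
  print(round(x$stats, digits))
  cat(sprintf("pH fractions: %.1f%% < 7.3, %.1f%% 7.3-7.45, %.1f%% >= 7.45\n",
              100 * x$ph_fractions[1], 100 * x$ph_fractions[2],
              100 * x$ph_fractions[3]))
  invisible(x)
}
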