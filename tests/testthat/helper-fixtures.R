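# Shared fixtures, built in code.

# Hand-written two-observation patient timeline with known values.
tiny_cohort <- function() {
  data.frame(
    patient_id = c("A", "A", "B"),
    time = c(1, 5, 2),
    ph = c(7.35, 7.30, 7.42),
    paco2 = c(45, 50, 40),
    hco3 = c(24, 23.5, 25),
    bg_type = c("arterial", "arterial", "capillary"),
    petco2 = c(40, 44, 36),
    spo2 = c(90, 95, 98),
    fio2 = c(40, 45, 30),
    peep = c(6, 8, 5),
    pip = c(20, 22, 18),
    mnawp = c(11, 12, 9),
    tv_in = c(7, 7.5, 8),
    tv_exp = c(6.8, 7.2, 7.7),
    stringsAsFactors = FALSE)
}

# Small simulated feature-row set for model tests.
small_rows <- function(n_patients = 60, seed = 42, ...) {
  co <- simulate_cohort(bg_generator_config(n_patients = n_patients,
                                            seed = seed, ...))
  build_feature_rows(co)
}

# Random feature-like data with standard-normal predictors; used where
# tests need full control over the design rather than physiologic
# structure.
random_rows <- function(n, seed = 1) {
  set.seed(seed)
  df <- data.frame(ph_prev = runif(n, 7.1, 7.6))
  for (p in bg_default_predictors()) df[[p]] <- rnorm(n)
  df$ph_t <- rnorm(n, 7.4, 0.05)
  df$paco2_t <- rnorm(n, 45, 5)
  df
}

# Exact Mann-Whitney U two-sided p-value by full enumeration (no ties).
exact_mwu_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  u_obs <- sum(rank(pooled)[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  r <- rank(pooled)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Drifting benchmark: default generator with a stronger, homogeneous
# metabolic drift so the bicarbonate channel (uncorrectable from current
# end-tidal CO2) carries the time-lag signal.
drifting_config <- function(n_patients, seed) {
  bg_generator_config(n_patients = n_patients, mean_obs_per_patient = 8,
                      metabolic_drift_sd = 1.0, noise_heterogeneity = 0,
                      seed = seed)
}
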