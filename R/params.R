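#' Synthetic-cohort generator parameters
#'
#' Defaults emulate the statistical structure of a 38-patient whole-body CD8
#' immuno-PET trial: patient-level geometric-mean baseline SUVmax 5.6 with
#' geometric coefficient of variation 0.72, an intraclass correlation of
#' 0.46 for the patient level, about 7 lesions per patient (zero-truncated
#' Poisson, ~266 lesions in 38 patients), best-overall-response mix
#' 19 PD / 4 SD / 8 PR / 4 CR among evaluable patients, a common true
#' uptake slope of -4.6% per week of therapy, response-dependent volume
#' change anchored to the RECIST thresholds, a partial-volume attenuation
#' for lesions below 2 cm^3, serum half-life 1.19 days, and an exponential
#' survival model tied to the patient's standardized baseline uptake.
#'
#' The total log-SUV variance is `log(1 + gcv_target^2)` and the patient
#' share is `icc_target` of it; the scan-rescan residual SD is a small fixed
#' component and the lesion SD absorbs the rest.
#'
#' @param n_patients Number of patients.
#' @param lesions_per_patient Mean of the zero-truncated Poisson lesion
#'   count per patient.
#' @param mu_log_suv Grand mean of log baseline SUVmax.
#' @param gcv_target Target geometric coefficient of variation of baseline
#'   SUVmax; sets the total log-scale variance. Ignored when the three SDs
#'   are given explicitly.
#' @param icc_target Fraction of log-SUV variance at the patient level.
#' @param sd_patient,sd_lesion,sd_residual Log-scale SDs; by default derived
#'   from `gcv_target` and `icc_target` with `sd_residual = 0.1`.
#' @param bor_probs Probabilities over `(PD, SD, PR, CR)`, summing to 1.
#' @param slope_per_week_by_bor Named log-scale uptake slopes per week for
#'   PD/SD/PR/CR; default `log(1 - 0.046)` for all (equal true slopes).
#' @param lesion_slope_sd SD of lesion-level slope noise (log per week).
#' @param shrinkage_per_week_by_bor Named relative volume change per week
#'   (linear in time); defaults anchored to RECIST response magnitudes:
#'   PD +0.05, SD -0.03, PR -0.11, CR -0.15.
#' @param pv_threshold_cm3 Volume below which partial-volume attenuation
#'   applies, default 2.
#' @param pv_gamma Attenuation exponent in
#'   `f(V) = min(1, (V / pv_threshold_cm3)^pv_gamma)`; default 0.3, set 0 to
#'   disable attenuation.
#' @param vol_meanlog,vol_sdlog Log-normal baseline volume distribution
#'   (cm^3); clamped to `vol_min_cm3` so every baseline lesion has a
#'   diameter of at least 1 cm.
#' @param vol_min_cm3 Minimum baseline volume, default 0.55.
#' @param prop_irradiated Fraction of lesions flagged as previously
#'   irradiated (excluded from uptake analyses).
#' @param organ_site_probs Named organ-site probabilities.
#' @param prob_dmmr Probability of a mismatch-repair-deficient tumor.
#' @param phenotype_probs Named probabilities for the immune phenotype
#'   (desert/stromal/inflamed).
#' @param serum_half_life_days Monoexponential serum half-life, default 1.19.
#' @param hr_per_sd Log hazard per SD of the patient's standardized baseline
#'   geometric-mean uptake; default `-log(1.6)` (higher uptake, lower
#'   hazard, HR 1.6 per SD decrease).
#' @param median_survival_months Baseline median survival at average uptake.
#' @param censor_horizon_months Administrative censoring horizon.
#' @param scan_day_range On-treatment PET day drawn uniformly (integer days)
#'   from this range, default 28 to 36.
#' @param response_ct_day Day of the first on-treatment response CT,
#'   default 42.
#' @param suv_mean_fraction SUVmean as a fraction of SUVmax, default 0.7.
#' @param seed Integer seed; identical parameters and seed give
#'   byte-identical output.
#' @return A validated list of class `cd8_generator_params`.
#' @export
generator_params <- function(n_patients = 38L,
                             lesions_per_patient = 7,
                             mu_log_suv = log(5.6),
                             gcv_target = 0.72,
                             icc_target = 0.46,
                             sd_patient = NULL,
                             sd_lesion = NULL,
                             sd_residual = 0.1,
                             bor_probs = c(PD = 19, SD = 4, PR = 8, CR = 4) / 35,
                             slope_per_week_by_bor = c(
                               PD = log(1 - 0.046), SD = log(1 - 0.046),
                               PR = log(1 - 0.046), CR = log(1 - 0.046)),
                             lesion_slope_sd = 0.01,
                             shrinkage_per_week_by_bor = c(
                               PD = 0.05, SD = -0.03, PR = -0.11, CR = -0.15),
                             pv_threshold_cm3 = 2,
                             pv_gamma = 0.3,
                             vol_meanlog = log(4),
                             vol_sdlog = 1.1,
                             vol_min_cm3 = 0.55,
                             prop_irradiated = 0.1,
                             organ_site_probs = c(
                               lymph_node = 99, liver = 35, bone = 17,
                               lung = 42, skin = 19) / 212,
                             prob_dmmr = 9 / 34,
                             phenotype_probs = c(desert = 15, stromal = 15,
                                                 inflamed = 4) / 34,
                             serum_half_life_days = 1.19,
                             hr_per_sd = -log(1.6),
                             median_survival_months = 8,
                             censor_horizon_months = 18,
                             scan_day_range = c(28L, 36L),
                             response_ct_day = 42,
                             suv_mean_fraction = 0.7,
                             seed = 1L) {
  total_var <- log(1 + gcv_target^2)
  if (is.null(sd_patient)) sd_patient <- sqrt(icc_target * total_var)
  if (is.null(sd_lesion)) {
    rest <- total_var - sd_patient^2 - sd_residual^2
    if (rest < 0) abort("sd_patient^2 + sd_residual^2 exceeds the total variance implied by `gcv_target`.")
    sd_lesion <- sqrt(rest)
  }
  p <- list(
    n_patients = as.integer(n_patients),
    lesions_per_patient = lesions_per_patient,
    mu_log_suv = mu_log_suv, gcv_target = gcv_target,
    icc_target = icc_target,
    sd_patient = sd_patient, sd_lesion = sd_lesion,
    sd_residual = sd_residual,
    bor_probs = bor_probs,
    slope_per_week_by_bor = slope_per_week_by_bor,
    lesion_slope_sd = lesion_slope_sd,
    shrinkage_per_week_by_bor = shrinkage_per_week_by_bor,
    pv_threshold_cm3 = pv_threshold_cm3, pv_gamma = pv_gamma,
    vol_meanlog = vol_meanlog, vol_sdlog = vol_sdlog,
    vol_min_cm3 = vol_min_cm3,
    prop_irradiated = prop_irradiated,
    organ_site_probs = organ_site_probs,
    prob_dmmr = prob_dmmr, phenotype_probs = phenotype_probs,
    serum_half_life_days = serum_half_life_days,
    hr_per_sd = hr_per_sd,
    median_survival_months = median_survival_months,
    censor_horizon_months = censor_horizon_months,
    scan_day_range = as.integer(scan_day_range),
    response_ct_day = response_ct_day,
    suv_mean_fraction = suv_mean_fraction,
    seed = as.integer(seed)
  )
  validate_generator_params(p)
  structure(p, class = "cd8_generator_params")
}

validate_generator_params <- function(p) {
  if (p$n_patients < 1L) abort("`n_patients` must be >= 1 (empty cohort).")
  for (nm in c("sd_patient", "sd_lesion", "sd_residual", "lesion_slope_sd")) {
    check_number(p[[nm]], nm, nonnegative = TRUE)
  }
  if (length(p$bor_probs) != 4L || any(p$bor_probs < 0) ||
      abs(sum(p$bor_probs) - 1) > 1e-12) {
    abort("`bor_probs` must be 4 nonnegative probabilities summing to 1.")
  }
  if (!setequal(names(p$bor_probs), c("PD", "SD", "PR", "CR"))) {
    abort("`bor_probs` must be named PD, SD, PR, CR.")
  }
  check_number(p$pv_threshold_cm3, "pv_threshold_cm3", positive = TRUE)
  check_number(p$pv_gamma, "pv_gamma", nonnegative = TRUE)
  check_number(p$serum_half_life_days, "serum_half_life_days", positive = TRUE)
  if (p$icc_target < 0 || p$icc_target > 1) {
    abort("`icc_target` must be in [0, 1].")
  }
  invisible(p)
}

#' @export
print.cd8_generator_params <- function(x, ...) {
  cat(sprintf(
    "Synthetic CD8 immuno-PET cohort parameters: %d patients, ~%.0f lesions each\n",
    x$n_patients, x$lesions_per_patient))
  cat(sprintf("  log SUV: mu %.3f, SDs patient %.3f / lesion %.3f / residual %.3f (ICC %.2f)\n",
              x$mu_log_suv, x$sd_patient, x$sd_lesion, x$sd_residual,
              x$icc_target))
  cat(sprintf("  partial volume: f(V) = min(1, (V/%.3g)^%.3g); seed %d\n",
              x$pv_threshold_cm3, x$pv_gamma, x$seed))
  invisible(x)
}
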