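#' Generate a synthetic immuno-PET trial cohort
#'
#' Draws a full synthetic trial dataset with the hierarchical structure the
#' downstream analyses assume: log baseline SUVmax is
#' `mu + u_patient + v_lesion + residual` with the configured SDs;
#' on-treatment log uptake adds the per-week response-group slope (plus
#' lesion-level slope noise) times treatment weeks; lesion volume changes
#' linearly in time at the response group's relative rate; the measured
#' SUVmax is the true value times the partial-volume attenuation
#' `f(V) = min(1, (V / threshold)^gamma)` evaluated at the lesion's true
#' volume at scan time; survival times are exponential with log hazard
#' proportional to the patient's standardized true uptake level, with
#' administrative censoring. Output is deterministic given the parameters
#' and seed.
#'
#' @param params A [generator_params()] object.
#' @return Object of class `cd8_cohort`: list with tibbles `lesions` (one
#'   row per lesion x scan, including `true_log_suv` and
#'   `true_volume_at_scan_cm3` ground truth), `patients` (BOR, survival,
#'   MMR status, immune phenotype, realized patient effect), and
#'   `ground_truth` (the parameter echo).
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cd8_generator_params"))
  p <- params
  withr::local_seed(p$seed)

  ## patients ------------------------------------------------------------
  np <- p$n_patients
  pid <- sprintf("P%03d", seq_len(np))
  bor_lv <- c("PD", "SD", "PR", "CR")
  bor <- factor(sample(bor_lv, np, replace = TRUE,
                       prob = p$bor_probs[bor_lv]), levels = bor_lv)
  u_p <- rnorm(np, 0, p$sd_patient)
  n_les <- rztpois(np, p$lesions_per_patient)
  mmr <- factor(ifelse(runif(np) < p$prob_dmmr, "dMMR", "pMMR"),
                levels = c("pMMR", "dMMR"))
  phen <- factor(sample(names(p$phenotype_probs), np, replace = TRUE,
                        prob = p$phenotype_probs),
                 levels = c("desert", "stromal", "inflamed"))
  scan_day <- sample(seq(p$scan_day_range[1], p$scan_day_range[2]),
                     np, replace = TRUE)

  ## lesions -------------------------------------------------------------
  nl <- sum(n_les)
  les_pat <- rep(seq_len(np), n_les)
  lesion_id <- unlist(lapply(n_les, function(k) sprintf("L%02d", seq_len(k))),
                      use.names = FALSE)
  site <- sample(names(p$organ_site_probs), nl, replace = TRUE,
                 prob = p$organ_site_probs)
  irradiated <- runif(nl) < p$prop_irradiated
  v_l <- rnorm(nl, 0, p$sd_lesion)
  slope <- unname(p$slope_per_week_by_bor[as.character(bor[les_pat])]) +
    rnorm(nl, 0, p$lesion_slope_sd)
  shrink <- unname(p$shrinkage_per_week_by_bor[as.character(bor[les_pat])])
  v0 <- pmax(p$vol_min_cm3, rlnorm(nl, p$vol_meanlog, p$vol_sdlog))
  aspect <- runif(nl, 0.6, 1)

  ## lesion x scan rows ---------------------------------------------------
  timepoints <- cbind(0, scan_day[les_pat])     # pretreatment, on-treatment
  ct_days <- cbind(0, p$response_ct_day)
  rows <- purrr::map_dfr(1:2, function(s) {
    t_d <- timepoints[, s]
    wk <- t_d / 7
    v_true <- v0 * pmax(0.01, 1 + shrink * wk)
    true_log <- p$mu_log_suv + u_p[les_pat] + v_l + slope * wk
    atten <- pv_attenuation(v_true, p$pv_threshold_cm3, p$pv_gamma)
    eps <- rnorm(nl, 0, p$sd_residual)
    suv <- exp(true_log + eps) * atten
    v_ct <- v0 * pmax(0.01, 1 + shrink * ct_days[, s] / 7)
    # diameters from the CT volume with the lesion's aspect ratio
    diam_l <- (6 * v_ct / (pi * aspect))^(1 / 3)
    tibble::tibble(
      patient_id = pid[les_pat], lesion_id = lesion_id,
      organ_site = site, irradiated = irradiated,
      timepoint = t_d,
      suv_max = suv, suv_mean = p$suv_mean_fraction * suv,
      diam_long_cm = diam_l, diam_short_cm = aspect * diam_l,
      ct_date_offset_days = ct_days[, s],
      true_log_suv = true_log,
      true_volume_at_scan_cm3 = v_true
    )
  })
  rows <- dplyr::arrange(rows, .data$patient_id, .data$lesion_id,
                         .data$timepoint)
  rows$bor <- bor[match(rows$patient_id, pid)]

  ## survival ------------------------------------------------------------
  # exposure: realized patient-level true uptake, standardized across patients
  z <- (u_p - mean(u_p)) / (if (np > 1 && sd(u_p) > 0) sd(u_p) else 1)
  lambda0 <- log(2) / p$median_survival_months
  draw_surv <- function(rate_scale) {
    t_raw <- rexp(np, lambda0 * exp(p$hr_per_sd * z) * rate_scale)
    event <- as.integer(t_raw <= p$censor_horizon_months)
    list(time = pmin(t_raw, p$censor_horizon_months), event = event)
  }
  os <- draw_surv(1)
  pfs <- draw_surv(2)           # progression happens about twice as fast
  pfs$time <- pmin(pfs$time, os$time)

  patients <- tibble::tibble(
    patient_id = pid, bor = bor, mmr_status = mmr, immune_phenotype = phen,
    n_lesions = n_les, on_treatment_scan_day = scan_day,
    pfs_months = pfs$time, pfs_event = pfs$event,
    os_months = os$time, os_event = os$event,
    true_patient_effect = u_p
  )

  structure(
    list(lesions = rows, patients = patients,
         ground_truth = unclass(p)),
    class = "cd8_cohort"
  )
}

## attenuation of measured uptake below the partial-volume knee
pv_attenuation <- function(v_cm3, threshold_cm3, gamma) {
  pmin(1, (v_cm3 / threshold_cm3)^gamma)
}

## zero-truncated Poisson with target mean `mu` (> 1)
rztpois <- function(n, mu) {
  # solve lambda so that lambda / (1 - exp(-lambda)) = mu
  lam <- if (mu <= 1) 1e-6 else {
    uniroot(function(l) l / (1 - exp(-l)) - mu,
            c(1e-8, max(10, 3 * mu)))$root
  }
  out <- integer(n)
  for (i in seq_len(n)) {
    repeat {
      k <- rpois(1, lam)
      if (k > 0) break
    }
    out[i] <- k
  }
  out
}

#' @export
print.cd8_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients, %d lesions, %d lesion-scan rows\n",
              nrow(x$patients), nrow(x$lesions) / 2L, nrow(x$lesions)))
  print(table(x$patients$bor))
  invisible(x)
}

#' Prepare the lesion table for the volume-adjusted analysis
#'
#' Adds CT-derived volumes ([oblate_volume()]), the linearly interpolated
#' volume at the PET scan time ([interpolate_volume()]; for pretreatment
#' rows this is the baseline volume itself), fits the pretreatment
#' volume-uptake spline on nonirradiated baseline lesions, and appends the
#' partial-volume-adjusted SUVmax.
#'
#' @param lesions Lesion-by-scan table as produced by [generate_cohort()]
#'   (or read from CSV with the same columns).
#' @param anchor_volume_cm3 Spline anchor volume, default 5.
#' @param spline Optionally a pre-fitted [fit_volume_uptake_spline()] model;
#'   by default the spline is fitted on the pretreatment rows of `lesions`.
#' @return A list with the augmented `lesions` tibble (columns
#'   `volume_cm3`, `volume_at_pet_cm3`, `suv_max_adjusted` added) and the
#'   fitted `spline`.
#' @export
prepare_volume_adjusted <- function(lesions, anchor_volume_cm3 = 5,
                                    spline = NULL) {
  check_columns(lesions, c("patient_id", "lesion_id", "timepoint", "suv_max",
                           "diam_long_cm", "diam_short_cm",
                           "ct_date_offset_days"), "lesions")
  lesions <- tibble::as_tibble(lesions)
  lesions$volume_cm3 <- oblate_volume(lesions$diam_long_cm,
                                      lesions$diam_short_cm)
  lesions <- lesions |>
    dplyr::group_by(.data$patient_id, .data$lesion_id) |>
    dplyr::mutate(volume_at_pet_cm3 = interp_volume_rows(
      .data$timepoint, .data$volume_cm3, .data$ct_date_offset_days)) |>
    dplyr::ungroup()
  if (is.null(spline)) {
    pre <- lesions[lesions$timepoint == 0, ]
    if ("irradiated" %in% names(pre)) pre <- pre[!pre$irradiated, ]
    spline <- fit_volume_uptake_spline(pre,
                                       anchor_volume_cm3 = anchor_volume_cm3)
  }
  lesions <- adjust_uptake(lesions, spline)
  list(lesions = lesions, spline = spline)
}

## per-lesion volume at PET time: baseline rows keep the baseline CT volume;
## on-treatment rows interpolate between the two CTs at the scan day
interp_volume_rows <- function(timepoint, volume, ct_day) {
  ib <- which(timepoint == 0)
  it <- which(timepoint > 0)
  out <- volume
  if (length(ib) >= 1L && length(it) >= 1L) {
    vb <- volume[ib[1]]; tb <- ct_day[ib[1]]
    vf <- volume[it[1]]; tf <- ct_day[it[1]]
    out[it] <- interpolate_volume(vb, vf, tb, tf, timepoint[it])
  }
  out
}

#' Generate a synthetic serum concentration-time table
#'
#' Monoexponential decay `C(t) = C0 * 2^(-t / t_half)` with optional
#' multiplicative log-normal noise, sampled by default at the part-A
#' schedule: before injection (entered as t = 0) and at 30 min, 3 h, one,
#' two, four and seven days.
#'
#' @param params A [generator_params()] (uses `serum_half_life_days` and
#'   `seed`).
#' @param n_subjects Number of subjects, default 1.
#' @param times_d Sampling times in days.
#' @param c0 Concentration at t = 0 (arbitrary units).
#' @param noise_cv Coefficient of variation of multiplicative measurement
#'   noise; 0 gives the exact curve.
#' @param subject_halflife_sd Between-subject SD of the half-life in days
#'   (default 0: all subjects share `serum_half_life_days`).
#' @return Tibble with `patient_id`, `time_d`, `concentration`.
#' @export
generate_pk_series <- function(params, n_subjects = 1L,
                               times_d = c(0, 0.5 / 24, 3 / 24, 1, 2, 4, 7),
                               c0 = 100, noise_cv = 0,
                               subject_halflife_sd = 0) {
  stopifnot(inherits(params, "cd8_generator_params"))
  if (max(times_d) < 2 * params$serum_half_life_days) {
    abort("Sampling times must span at least two half-lives.")
  }
  withr::local_seed(derive_seed(params$seed, 17L))
  purrr::map_dfr(seq_len(n_subjects), function(i) {
    th <- max(0.05, params$serum_half_life_days +
                (if (subject_halflife_sd > 0) rnorm(1, 0, subject_halflife_sd)
                 else 0))
    conc <- c0 * 2^(-times_d / th)
    if (noise_cv > 0) {
      conc <- conc * exp(rnorm(length(times_d), 0, sqrt(log(1 + noise_cv^2))))
    }
    tibble::tibble(patient_id = sprintf("P%03d", i), time_d = times_d,
                   concentration = conc)
  })
}
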