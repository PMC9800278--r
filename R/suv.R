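#' Compute a standardized uptake value (SUV)
#'
#' Normalizes a tissue activity concentration by the injected radioactivity
#' dose per unit body weight, the standard bodyweight SUV convention with a
#' tissue density of 1 g/mL. The result is unitless.
#'
#' @param activity_conc_kBq_per_mL Activity concentration in the volume of
#'   interest, in kBq/mL. May be a vector; zero is allowed (SUV 0).
#' @param body_weight_kg Patient body weight in kg.
#' @param injected_dose_MBq Net injected radioactivity dose in MBq,
#'   decay-corrected to injection time.
#' @return Numeric vector of SUVs.
#' @examples
#' compute_suv(0.5, body_weight_kg = 74, injected_dose_MBq = 37) # 1
#' @export
compute_suv <- function(activity_conc_kBq_per_mL, body_weight_kg,
                        injected_dose_MBq) {
  check_number(body_weight_kg, "body_weight_kg", positive = TRUE)
  check_number(injected_dose_MBq, "injected_dose_MBq", positive = TRUE)
  if (any(activity_conc_kBq_per_mL < 0, na.rm = TRUE)) {
    abort("`activity_conc_kBq_per_mL` must be >= 0.")
  }
  # dose in kBq divided by body weight in grams (1 g/mL tissue density)
  activity_conc_kBq_per_mL / (injected_dose_MBq * 1000 / (body_weight_kg * 1000))
}

#' Radioactive decay correction
#'
#' Rescales a radioactivity measurement to the injection reference time using
#' the isotope half-life (default: zirconium-89, 78.4 h). The default mode
#' corrects a later measurement back to reference (multiplies by
#' `2^(elapsed/half_life)`); `mode = "decay"` applies forward decay instead.
#' The two modes are exact inverses.
#'
#' @param value Measured value(s), any linear radioactivity scale.
#' @param elapsed_h Hours elapsed since the reference time. May be negative.
#' @param half_life_h Isotope half-life in hours; default 78.4 (89Zr).
#' @param mode `"correct"` (default) or `"decay"`.
#' @return Numeric vector, same length as `value`.
#' @examples
#' decay_correct(1, 78.4)                  # 2
#' decay_correct(1, 78.4, mode = "decay")  # 0.5
#' @export
decay_correct <- function(value, elapsed_h, half_life_h = ZR89_HALF_LIFE_H,
                          mode = c("correct", "decay")) {
  mode <- match.arg(mode)
  check_number(half_life_h, "half_life_h", positive = TRUE)
  f <- 2^(elapsed_h / half_life_h)
  if (mode == "decay") value / f else value * f
}

#' Geometric summary of uptake values
#'
#' Computes the geometric mean, the geometric coefficient of variation
#' (GCV = sqrt(exp(s2) - 1) with s2 the unbiased variance of the logs), and a
#' Student-t confidence interval for the geometric mean on the log scale.
#'
#' @param values Positive numeric vector (e.g. lesion SUVmax values).
#' @param conf_level Confidence level, default 0.95.
#' @return A one-row tibble with columns `geometric_mean`, `gcv`, `ci_low`,
#'   `ci_high`, `n`.
#' @examples
#' summarize_uptake(c(2, 8)) # geometric mean 4
#' @export
summarize_uptake <- function(values, conf_level = 0.95) {
  values <- values[!is.na(values)]
  if (length(values) < 1L) abort("`values` must contain at least one value.")
  if (any(values <= 0)) abort("`values` must all be > 0.")
  lx <- log(values)
  n <- length(lx)
  m <- mean(lx)
  if (n > 1L) {
    s2 <- var(lx)
    se <- sqrt(s2 / n)
    tcrit <- qt(1 - (1 - conf_level) / 2, df = n - 1L)
    ci <- m + c(-1, 1) * tcrit * se
    gcv <- sqrt(exp(s2) - 1)
  } else {
    ci <- c(NA_real_, NA_real_)
    gcv <- 0
  }
  tibble::tibble(
    geometric_mean = exp(m),
    gcv = gcv,
    ci_low = exp(ci[1]),
    ci_high = exp(ci[2]),
    n = n
  )
}
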