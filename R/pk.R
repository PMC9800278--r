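#' Terminal serum half-life by noncompartmental analysis
#'
#' Estimates the terminal elimination half-life from a serum
#' concentration-time profile by log-linear least squares on a terminal
#' window. Candidate windows are the last k points after the observed peak
#' (k >= 3); the window with the best adjusted R-squared is used, with ties
#' (within 1e-9) broken toward the window with the most points, the usual
#' "best fit" noncompartmental convention.
#'
#' @param pk A data frame with columns `time_d` (days post injection) and
#'   `concentration` (> 0). If a `patient_id` column is present the estimate
#'   is computed per patient and one row per patient is returned.
#' @param min_points Minimum number of terminal points, default 3.
#' @return A tibble with columns `t_half_days`, `lambda_z_per_day`,
#'   `n_points_used`, `adj_r2` (and `patient_id` when grouped).
#' @examples
#' tt <- c(0, 0.5 / 24, 3 / 24, 1, 2, 4, 7)
#' pk <- tibble::tibble(time_d = tt, concentration = 10 * 2^(-tt / 1.19))
#' estimate_terminal_half_life(pk)$t_half_days # 1.19
#' @export
estimate_terminal_half_life <- function(pk, min_points = 3L) {
  check_columns(pk, c("time_d", "concentration"), "pk")
  if ("patient_id" %in% names(pk)) {
    return(
      pk |>
        dplyr::group_by(.data$patient_id) |>
        dplyr::group_modify(~ terminal_fit_one(.x, min_points)) |>
        dplyr::ungroup()
    )
  }
  terminal_fit_one(pk, min_points)
}

terminal_fit_one <- function(pk, min_points) {
  pk <- dplyr::arrange(pk[!is.na(pk$concentration), ], .data$time_d)
  if (any(pk$concentration <= 0)) abort("Concentrations must be > 0.")
  # terminal candidates start after the observed peak
  ipeak <- which.max(pk$concentration)
  post <- pk[ipeak:nrow(pk), ]
  n <- nrow(post)
  if (n < min_points) {
    abort("Need at least `min_points` post-peak samples for a terminal fit.")
  }
  best <- NULL
  for (k in seq(min_points, n)) {
    w <- post[(n - k + 1L):n, ]
    fit <- lm(log(w$concentration) ~ w$time_d)
    slope <- coef(fit)[2]
    if (!is.finite(slope) || slope >= -1e-12) next
    ar2 <- suppressWarnings(summary(fit)$adj.r.squared)
    if (is.null(best) || ar2 > best$ar2 + 1e-9 ||
        (abs(ar2 - best$ar2) <= 1e-9 && k > best$k)) {
      best <- list(ar2 = ar2, k = k, lambda = -unname(slope))
    }
  }
  if (is.null(best)) {
    abort("No decreasing terminal phase found (nondecreasing concentrations).")
  }
  tibble::tibble(
    t_half_days = log(2) / best$lambda,
    lambda_z_per_day = best$lambda,
    n_points_used = best$k,
    adj_r2 = best$ar2
  )
}
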