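#' Uptake change per week of checkpoint-inhibitor therapy
#'
#' Fits the longitudinal lesion-uptake model: log SUVmax on treatment weeks
#' (days since therapy start divided by 7; pretreatment coded 0), with
#' random intercepts per patient and per lesion nested within patient.
#' Reports the overall percent change per week, the change in a PD versus a
#' non-PD (SD/PR/CR) group with the treatment-time-by-response interaction
#' p-value, and the expected change at 30 days of therapy. Runs on raw
#' (`suv_max`) or partial-volume-adjusted (`suv_max_adjusted`) uptake.
#'
#' @param data Lesion-by-scan data frame with columns `patient_id`,
#'   `lesion_id`, `timepoint` (days; pretreatment 0), `bor` and the response
#'   column. Irradiated lesions (column `irradiated`, if present) are
#'   excluded.
#' @param adjusted Use `suv_max_adjusted` instead of `suv_max`.
#' @param projection_days Day at which to summarize the expected change,
#'   default 30.
#' @return An object of class `cd8_treatment_report`: a list with tibbles
#'   `overall` (percent/week with CI and p, plus projection at
#'   `projection_days`), `by_group` (PD and non-PD slopes) and
#'   `interaction` (interaction p-value), and the two underlying `cd8_lmm`
#'   fits.
#' @export
treatment_change_model <- function(data, adjusted = FALSE,
                                   projection_days = 30) {
  response <- if (adjusted) "suv_max_adjusted" else "suv_max"
  check_columns(data, c("patient_id", "lesion_id", "timepoint", "bor",
                        response), "data")
  data <- tibble::as_tibble(data)
  if ("irradiated" %in% names(data)) data <- data[!data$irradiated, ]
  data <- data[!is.na(data[[response]]) & !is.na(data$bor), ]
  if (!any(data$timepoint > 0)) abort("No on-treatment rows in `data`.")
  if (!all(dplyr::count(data, .data$patient_id, .data$lesion_id)$n >= 2)) {
    data <- data |>
      dplyr::group_by(.data$patient_id, .data$lesion_id) |>
      dplyr::filter(dplyr::n() >= 2, any(.data$timepoint == 0)) |>
      dplyr::ungroup()
  }
  data$weeks <- data$timepoint / 7
  data$response_group <- factor(ifelse(data$bor == "PD", "PD", "non-PD"),
                                levels = c("PD", "non-PD"))

  fit_overall <- fit_lmm(data, ~weeks, response = response,
                         random = c("patient", "lesion"))
  fit_inter <- fit_lmm(data, ~ weeks * response_group, response = response,
                       random = c("patient", "lesion"))

  overall <- percent_effect(fit_overall, c(weeks = 1))
  rate <- overall$percent / 100
  proj <- 100 * ((1 + rate)^(projection_days / 7) - 1)
  proj_ci <- 100 * ((1 + c(overall$ci_low, overall$ci_high) / 100)^
                      (projection_days / 7) - 1)

  pd <- percent_effect(fit_inter, c(weeks = 1))
  nonpd <- percent_effect(fit_inter, c(weeks = 1, `weeks:response_groupnon-PD` = 1))
  inter <- tidy(fit_inter)
  inter <- inter[inter$term == "weeks:response_groupnon-PD", ]

  structure(
    list(
      overall = dplyr::mutate(overall,
                              projection_days = projection_days,
                              projection_percent = proj,
                              projection_ci_low = proj_ci[1],
                              projection_ci_high = proj_ci[2]),
      by_group = dplyr::bind_rows(
        dplyr::mutate(pd, group = "PD", .before = 1),
        dplyr::mutate(nonpd, group = "non-PD", .before = 1)
      ),
      interaction = tibble::tibble(
        term = "weeks:response_group",
        estimate = inter$estimate, std_error = inter$std_error,
        df = inter$df, p_value = inter$p_value
      ),
      response = response,
      fit_overall = fit_overall,
      fit_interaction = fit_inter
    ),
    class = "cd8_treatment_report"
  )
}

#' @export
print.cd8_treatment_report <- function(x, ...) {
  o <- x$overall
  cat(sprintf("Uptake change on treatment (%s):\n", x$response))
  cat(sprintf("  %.2f%%/week (95%% CI %.2f to %.2f), p = %.3g\n",
              o$percent, o$ci_low, o$ci_high, o$p_value))
  cat(sprintf("  expected at %d days: %.1f%%\n", o$projection_days,
              o$projection_percent))
  cat(sprintf("  interaction with response group: p = %.3g\n",
              x$interaction$p_value))
  invisible(x)
}

#' @export
tidy.cd8_treatment_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$overall[, c("percent", "ci_low", "ci_high", "p_value")],
                  term = "percent_per_week", .before = 1),
    dplyr::mutate(
      dplyr::rename(x$by_group[, c("group", "percent", "ci_low", "ci_high",
                                   "p_value")], term = "group"),
      term = paste0("percent_per_week_", .data$term)
    ),
    tibble::tibble(term = "interaction", percent = NA_real_,
                   ci_low = NA_real_, ci_high = NA_real_,
                   p_value = x$interaction$p_value)
  )
}
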