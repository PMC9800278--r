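#' RECIST response category for one assessment
#'
#' Categorizes a response assessment from sums of longest diameters (SLD):
#' CR when the current SLD is 0, PR at a >= 30% decrease from baseline, PD at
#' a >= 20% and >= 5 mm absolute increase over the nadir or upon new lesions,
#' SD otherwise.
#'
#' @param sld_baseline_mm,sld_nadir_mm,sld_current_mm Sums of longest
#'   diameters in mm (vectors allowed).
#' @param new_lesions Logical flag(s) for unequivocal new lesions.
#' @return Factor with levels PD, SD, PR, CR.
#' @export
recist_categorize <- function(sld_baseline_mm, sld_nadir_mm, sld_current_mm,
                              new_lesions = FALSE) {
  if (any(c(sld_baseline_mm, sld_nadir_mm, sld_current_mm) < 0, na.rm = TRUE)) {
    abort("SLDs must be >= 0.")
  }
  if (any(sld_nadir_mm > sld_baseline_mm, na.rm = TRUE)) {
    abort("`sld_nadir_mm` cannot exceed `sld_baseline_mm`.")
  }
  n <- max(length(sld_baseline_mm), length(sld_nadir_mm),
           length(sld_current_mm), length(new_lesions))
  b <- rep_len(sld_baseline_mm, n); nd <- rep_len(sld_nadir_mm, n)
  cur <- rep_len(sld_current_mm, n); nl <- rep_len(new_lesions, n)
  pd <- nl | (cur - nd >= 0.2 * nd & cur - nd >= 5)
  out <- ifelse(pd, "PD",
         ifelse(cur == 0, "CR",
         ifelse(b - cur >= 0.3 * b, "PR", "SD")))
  factor(out, levels = c("PD", "SD", "PR", "CR"))
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator with Greenwood variances and median survival with
#' confidence interval, via [survival::survfit()].
#'
#' @param data Data frame with columns `time` (> 0, e.g. months) and `event`
#'   (0/1; PFS events are progression or death, OS events death). An
#'   optional `group` column yields stratified curves.
#' @param conf_level Confidence level, default 0.95.
#' @return Object of class `cd8_km`: tibble of steps (`time`, `n_risk`,
#'   `n_event`, `survival`, `std_error`, `ci_low`, `ci_high`, `group`) plus
#'   a `median` tibble.
#' @export
km_estimate <- function(data, conf_level = 0.95) {
  check_columns(data, c("time", "event"), "data")
  if (any(data$time <= 0, na.rm = TRUE)) abort("`time` must be > 0.")
  if (!all(data$event %in% c(0, 1))) abort("`event` must be 0/1.")
  has_group <- "group" %in% names(data)
  form <- if (has_group) {
    survival::Surv(time, event) ~ group
  } else {
    survival::Surv(time, event) ~ 1
  }
  sf <- survival::survfit(form, data = data, conf.int = conf_level)
  smry <- summary(sf, censored = TRUE)
  steps <- tibble::tibble(
    time = smry$time, n_risk = smry$n.risk, n_event = smry$n.event,
    survival = smry$surv, std_error = smry$std.err,
    ci_low = smry$lower, ci_high = smry$upper,
    group = if (has_group) {
      sub("^group=", "", as.character(smry$strata))
    } else "all"
  )
  med <- summary(sf)$table
  if (is.null(dim(med))) med <- t(as.matrix(med))
  median_tbl <- tibble::tibble(
    group = if (has_group) sub("^group=", "", rownames(med)) else "all",
    median = med[, "median"],
    ci_low = med[, grep("LCL$", colnames(med))],
    ci_high = med[, grep("UCL$", colnames(med))],
    n = med[, "records"], events = med[, "events"]
  )
  structure(list(steps = steps, median = median_tbl, survfit = sf),
            class = "cd8_km")
}

#' @export
print.cd8_km <- function(x, ...) {
  cat("Kaplan-Meier estimate\n")
  print(x$median)
  invisible(x)
}

#' @export
tidy.cd8_km <- function(x, ...) x$steps

#' @export
glance.cd8_km <- function(x, ...) x$median

#' @export
autoplot.cd8_km <- function(object, ...) {
  df <- object$steps |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ dplyr::bind_rows(
      tibble::tibble(time = 0, survival = 1, ci_low = 1, ci_high = 1), .x
    )) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Survival probability", colour = NULL)
}

#' Log-rank test between two (or more) groups
#'
#' Standard one-degree-of-freedom log-rank statistic via
#' [survival::survdiff()].
#'
#' @param data Data frame with columns `time`, `event`, `group`.
#' @return One-row tibble with `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(data) {
  check_columns(data, c("time", "event", "group"), "data")
  if (length(unique(data$group)) < 2L) {
    abort("`group` must have at least two levels, both nonempty.")
  }
  if (sum(data$event) == 0) {
    abort("All observations censored; log-rank test undefined.")
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = data)
  df <- length(sd$n) - 1L
  tibble::tibble(statistic = sd$chisq, df = df,
                 p_value = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Firth-penalized Cox regression (single covariate)
#'
#' Maximizes the Breslow partial log-likelihood plus the Firth/Jeffreys
#' penalty `0.5 * log I(beta)`, which removes first-order small-sample bias
#' and guarantees a finite estimate even under monotone likelihood (complete
#' separation). Confidence limits come from the profile penalized
#' likelihood and the p-value from the penalized likelihood ratio against
#' `beta = 0`. Ties are handled by the Breslow approximation.
#'
#' @param data Data frame with columns `time`, `event`, and the covariate
#'   column named by `covariate`.
#' @param covariate Covariate column name.
#' @param standardize Scale the covariate by its sample standard deviation
#'   (hazard ratio "per population SD"); default `FALSE`.
#' @param direction `"increase"` (default) or `"decrease"`: report the
#'   hazard ratio per unit (or SD) increase or decrease of the covariate.
#' @param conf_level Confidence level, default 0.95.
#' @param tol Convergence tolerance on beta, default 1e-8.
#' @return Object of class `cd8_firth_cox`: one-row tibble fields
#'   `log_hr`, `hr`, `ci_low`, `ci_high`, `p_value`, plus fit metadata.
#' @export
firth_cox <- function(data, covariate, standardize = FALSE,
                      direction = c("increase", "decrease"),
                      conf_level = 0.95, tol = 1e-8) {
  direction <- match.arg(direction)
  check_columns(data, c("time", "event", covariate), "data")
  x <- data[[covariate]]
  keep <- !is.na(x) & !is.na(data$time) & !is.na(data$event)
  x <- x[keep]; time <- data$time[keep]; event <- data$event[keep]
  if (sd(x) == 0) abort("Covariate has zero variance.")
  if (length(unique(time[event == 1])) < 2L) {
    abort("Need at least two distinct event times.")
  }
  if (standardize) x <- x / sd(x)
  if (direction == "decrease") x <- -x
  ll <- cox_penalized_loglik_factory(time, event, x)
  # penalized log-likelihood is unimodal and -> -Inf in both tails
  opt <- optimize(ll$pll, interval = c(-30, 30), maximum = TRUE,
                  tol = tol / 10)
  beta <- opt$maximum
  pll_max <- opt$objective
  crit <- qchisq(conf_level, 1) / 2
  bound <- function(side) {
    f <- function(b) ll$pll(b) - (pll_max - crit)
    lo <- beta; hi <- beta + side
    while (f(hi) > 0 && abs(hi) < 80) hi <- hi + side
    if (f(hi) > 0) return(sign(side) * Inf)
    uniroot(f, sort(c(lo, hi)), tol = 1e-8)$root
  }
  ci <- c(bound(-10), bound(10))
  stat <- 2 * (pll_max - ll$pll(0))
  structure(
    list(
      log_hr = beta, hr = exp(beta),
      ci_low = exp(ci[1]), ci_high = exp(ci[2]),
      p_value = pchisq(max(0, stat), 1, lower.tail = FALSE),
      penalized = TRUE, standardize = standardize, direction = direction,
      n = length(x), events = sum(event),
      loglik = ll$loglik(beta), penalized_loglik = pll_max,
      covariate = covariate
    ),
    class = "cd8_firth_cox"
  )
}

## Breslow partial log-likelihood, observed information and Firth penalty
## for a single covariate; returns closures over the (sorted) data.
cox_penalized_loglik_factory <- function(time, event, x) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  n <- length(time)
  et <- unique(time[event == 1])
  # risk set index: first position with time >= t (data sorted ascending)
  risk_start <- vapply(et, function(t) match(TRUE, time >= t), integer(1))
  d_sum_x <- vapply(et, function(t) sum(x[event == 1 & time == t]), numeric(1))
  d_n <- vapply(et, function(t) sum(event == 1 & time == t), numeric(1))
  loglik_info <- function(beta) {
    l <- 0; info <- 0
    for (i in seq_along(et)) {
      idx <- risk_start[i]:n
      w <- exp(beta * x[idx])
      s0 <- sum(w); s1 <- sum(w * x[idx]); s2 <- sum(w * x[idx]^2)
      l <- l + beta * d_sum_x[i] - d_n[i] * log(s0)
      info <- info + d_n[i] * (s2 / s0 - (s1 / s0)^2)
    }
    c(l, info)
  }
  list(
    loglik = function(beta) loglik_info(beta)[1],
    info = function(beta) loglik_info(beta)[2],
    pll = function(beta) {
      li <- loglik_info(beta)
      if (li[2] <= 0) return(-Inf)
      li[1] + 0.5 * log(li[2])
    }
  )
}

#' @export
print.cd8_firth_cox <- function(x, ...) {
  cat(sprintf(
    "Firth-penalized Cox: HR %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
    x$hr, x$ci_low, x$ci_high, x$p_value))
  cat(sprintf("  per %s of %s%s; %d subjects, %d events\n",
              if (x$standardize) "SD" else "unit",
              x$covariate,
              if (x$direction == "decrease") " (decrease)" else "",
              x$n, x$events))
  invisible(x)
}

#' @export
tidy.cd8_firth_cox <- function(x, ...) {
  tibble::tibble(
    term = x$covariate, log_hr = x$log_hr, hr = x$hr,
    ci_low = x$ci_low, ci_high = x$ci_high, p_value = x$p_value
  )
}

#' @export
glance.cd8_firth_cox <- function(x, ...) {
  tibble::tibble(n = x$n, events = x$events, loglik = x$loglik,
                 penalized_loglik = x$penalized_loglik,
                 standardize = x$standardize, direction = x$direction)
}

#' Per-patient baseline uptake exposure for survival analysis
#'
#' Summarizes baseline tracer uptake per patient as the geometric mean
#' SUVmax over nonirradiated baseline lesions, and derives the median-split
#' group (patients exactly at the median go to the lower group; the median
#' split is predefined, no cutoff optimization) and the standardized value
#' (per population SD of the per-patient geometric means).
#'
#' @param lesions Lesion-by-scan table with `patient_id`, `timepoint`,
#'   `suv_max` and optionally `irradiated`.
#' @return Tibble with `patient_id`, `geomean_suv`, `uptake_group`
#'   (`"low"`/`"high"`), `suv_z` (standardized geometric mean).
#' @export
patient_uptake_exposure <- function(lesions) {
  check_columns(lesions, c("patient_id", "timepoint", "suv_max"), "lesions")
  base <- lesions[lesions$timepoint == 0 & !is.na(lesions$suv_max), ]
  if ("irradiated" %in% names(base)) base <- base[!base$irradiated, ]
  out <- base |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(geomean_suv = exp(mean(log(.data$suv_max)))) |>
    dplyr::ungroup()
  med <- median(out$geomean_suv)
  out |>
    dplyr::mutate(
      uptake_group = factor(ifelse(.data$geomean_suv <= med, "low", "high"),
                            levels = c("low", "high")),
      suv_z = (.data$geomean_suv - mean(.data$geomean_suv)) /
        sd(.data$geomean_suv)
    )
}
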