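#' Restricted cubic spline basis
#'
#' Evaluates the restricted (natural) cubic spline basis with the standard
#' truncated-power parameterization: cubic between the boundary knots and
#' linear beyond them. The nonlinear terms are scaled by the squared boundary
#' knot span so coefficients are on a comparable scale to the linear term.
#'
#' @param x Numeric vector at which to evaluate the basis.
#' @param knots Strictly increasing numeric vector of knot locations
#'   (length >= 3).
#' @return A matrix with `length(knots) - 1` columns: the linear term
#'   followed by the restricted cubic terms (no intercept column).
#' @export
rcs_basis <- function(x, knots) {
  k <- length(knots)
  if (k < 3L || is.unsorted(knots, strictly = TRUE)) {
    abort("`knots` must be strictly increasing with length >= 3.")
  }
  tk <- knots[k]
  tk1 <- knots[k - 1L]
  norm <- (tk - knots[1L])^2
  pos3 <- function(u) pmax(u, 0)^3
  out <- matrix(0, nrow = length(x), ncol = k - 1L)
  out[, 1L] <- x
  for (j in seq_len(k - 2L)) {
    tj <- knots[j]
    out[, j + 1L] <- (pos3(x - tj) -
      pos3(x - tk1) * (tk - tj) / (tk - tk1) +
      pos3(x - tk) * (tk1 - tj) / (tk - tk1)) / norm
  }
  colnames(out) <- c("x", paste0("rcs", seq_len(k - 2L)))
  out
}

#' Fit the pretreatment volume-uptake spline
#'
#' Models expected log SUVmax as a 5-knot restricted cubic spline in lesion
#' volume, using treatment-naive lesions only. This captures the empirical
#' partial-volume attenuation: small lesions read lower than their true
#' uptake, while above the attenuation knee uptake is unrelated to volume.
#' The fitted expectation is later used by [adjust_uptake()] to re-express
#' every lesion's uptake relative to a reference volume (default 5 cm^3).
#'
#' Knots are placed at the (0.05, 0.275, 0.5, 0.725, 0.95) quantiles of the
#' (transformed) volumes, and the predictor defaults to log volume since
#' lesion volumes are right-skewed over orders of magnitude.
#'
#' @param data Data frame of pretreatment lesions with columns `volume_cm3`
#'   (> 0) and `suv_max` (> 0). When a `patient_id` column is present the
#'   spline is fitted as a mixed model with a patient random intercept, in
#'   line with the patient-clustered treatment of every other
#'   uptake-determinant relation; otherwise ordinary least squares is used.
#' @param predictor_transform `"log"` (default) or `"identity"` volume scale
#'   for the spline predictor.
#' @param n_knots Number of knots, default 5.
#' @param knot_quantiles Quantiles for knot placement; default the Harrell
#'   positions for 5 knots.
#' @param anchor_volume_cm3 Reference volume to which lesions are projected,
#'   default 5.
#' @param trim_upper_quantile If non-`NULL`, lesions above this volume
#'   quantile are excluded from the fit (e.g. 0.95).
#' @return An object of class `cd8_spline` with elements `knots`,
#'   `coefficients`, `predictor_transform`, `anchor_volume_cm3`,
#'   `expected_at_anchor` (log scale), `sigma`, `n`.
#' @export
fit_volume_uptake_spline <- function(data,
                                     predictor_transform = c("log", "identity"),
                                     n_knots = 5L,
                                     knot_quantiles = NULL,
                                     anchor_volume_cm3 = 5,
                                     trim_upper_quantile = NULL) {
  predictor_transform <- match.arg(predictor_transform)
  check_columns(data, c("volume_cm3", "suv_max"), "data")
  data <- data[!is.na(data$volume_cm3) & !is.na(data$suv_max), ]
  if (any(data$volume_cm3 <= 0) || any(data$suv_max <= 0)) {
    abort("Volumes and SUVs must be > 0.")
  }
  if (!is.null(trim_upper_quantile)) {
    vmax <- quantile(data$volume_cm3, trim_upper_quantile, names = FALSE)
    data <- data[data$volume_cm3 <= vmax, ]
  }
  if (is.null(knot_quantiles)) {
    knot_quantiles <- switch(as.character(n_knots),
      "3" = c(0.1, 0.5, 0.9),
      "4" = c(0.05, 0.35, 0.65, 0.95),
      "5" = c(0.05, 0.275, 0.5, 0.725, 0.95),
      seq(0.05, 0.95, length.out = n_knots)
    )
  }
  xf <- if (predictor_transform == "log") log else identity
  x <- xf(data$volume_cm3)
  if (length(unique(data$volume_cm3)) < n_knots) {
    abort("Degenerate volume spread: need at least `n_knots` distinct volumes.")
  }
  knots <- unname(quantile(x, knot_quantiles, type = 7))
  if (is.unsorted(knots, strictly = TRUE)) {
    abort("Degenerate volume spread: knot quantiles are not distinct.")
  }
  X <- rcs_basis(x, knots)
  clustered <- "patient_id" %in% names(data) &&
    length(unique(data$patient_id)) >= 2L
  if (clustered) {
    df <- data.frame(y = log(data$suv_max), X, patient_id = data$patient_id)
    xcols <- colnames(X)
    form <- stats::as.formula(paste(
      "y ~", paste(xcols, collapse = " + "), "+ (1 | patient_id)"))
    mfit <- lme4::lmer(form, data = df, REML = TRUE,
                       control = lme4::lmerControl(
                         check.conv.singular = "ignore",
                         calc.derivs = FALSE))
    beta <- lme4::fixef(mfit)[c("(Intercept)", xcols)]
    sigma <- stats::sigma(mfit)
  } else {
    fit <- lm(log(data$suv_max) ~ X)
    beta <- coef(fit)
    sigma <- summary(fit)$sigma
  }
  if (anyNA(beta)) abort("Spline fit is rank deficient; check the volumes.")
  obj <- structure(
    list(
      knots = knots,
      coefficients = unname(beta),
      predictor_transform = predictor_transform,
      anchor_volume_cm3 = anchor_volume_cm3,
      sigma = sigma,
      clustered = clustered,
      n = nrow(data)
    ),
    class = "cd8_spline"
  )
  obj$expected_at_anchor <- predict(obj, anchor_volume_cm3)
  obj
}

#' Predict expected log uptake at given volumes
#'
#' @param object A fitted [fit_volume_uptake_spline()] model.
#' @param volume_cm3 Positive volumes at which to evaluate the expectation.
#' @param ... Unused.
#' @return Expected log SUVmax at each volume.
#' @export
predict.cd8_spline <- function(object, volume_cm3, ...) {
  if (any(volume_cm3 <= 0, na.rm = TRUE)) abort("Volumes must be > 0.")
  xf <- if (object$predictor_transform == "log") log else identity
  X <- rcs_basis(xf(volume_cm3), object$knots)
  drop(cbind(1, X) %*% object$coefficients)
}

#' @export
print.cd8_spline <- function(x, ...) {
  cat("Restricted cubic spline of log SUVmax vs",
      if (x$predictor_transform == "log") "log volume" else "volume", "\n")
  cat(sprintf("  %d lesions, %d knots; expected log uptake at %g cm^3: %.4f\n",
              x$n, length(x$knots), x$anchor_volume_cm3, x$expected_at_anchor))
  invisible(x)
}

#' Tidy spline predictions over a volume grid
#'
#' @param x A `cd8_spline` object.
#' @param volumes Optional volume grid; defaults to a log-spaced grid over
#'   the knot range.
#' @param ... Unused.
#' @return Tibble with `volume_cm3`, `expected_log_suv`, `expected_suv`.
#' @export
tidy.cd8_spline <- function(x, volumes = NULL, ...) {
  if (is.null(volumes)) {
    kn <- x$knots
    rng <- if (x$predictor_transform == "log") exp(range(kn)) else range(kn)
    volumes <- exp(seq(log(rng[1]), log(rng[2]), length.out = 100))
  }
  el <- predict(x, volumes)
  tibble::tibble(volume_cm3 = volumes, expected_log_suv = el,
                 expected_suv = exp(el))
}

#' @export
autoplot.cd8_spline <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$volume_cm3, y = .data$expected_suv)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$anchor_volume_cm3, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Lesion volume (cm³)",
                  y = "Expected geometric-mean SUVmax",
                  title = "Pretreatment volume–uptake spline")
}

#' Partial-volume adjust lesion uptake
#'
#' Re-expresses each lesion's observed SUVmax relative to the expected
#' pretreatment uptake of a lesion of the same volume, projected to the
#' spline's anchor volume: on the log scale,
#' `adjusted = log(suv) - E(V) + E(anchor)`, returned as `exp(adjusted)`.
#' Lesions at the anchor volume are unchanged, as is every lesion when the
#' fitted expectation is flat. A linear-scale mode
#' (`suv - exp(E(V)) + exp(E(anchor))`) is available.
#'
#' @param data Data frame with columns `suv_max` and `volume_at_pet_cm3`
#'   (lesion volume at the PET scan, from [interpolate_volume()]).
#' @param spline A fitted [fit_volume_uptake_spline()] model.
#' @param scale `"log"` (default, geometric differences) or `"linear"`.
#' @return `data` with an added `suv_max_adjusted` column.
#' @export
adjust_uptake <- function(data, spline, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  if (!inherits(spline, "cd8_spline")) {
    abort("`spline` must be a fitted cd8_spline (see fit_volume_uptake_spline).")
  }
  check_columns(data, c("suv_max", "volume_at_pet_cm3"), "data")
  ev <- predict(spline, data$volume_at_pet_cm3)
  ea <- spline$expected_at_anchor
  adj <- if (scale == "log") {
    exp(log(data$suv_max) - ev + ea)
  } else {
    data$suv_max - exp(ev) + exp(ea)
  }
  dplyr::mutate(tibble::as_tibble(data), suv_max_adjusted = adj)
}
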