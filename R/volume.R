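#' Lesion volume from two orthogonal CT diameters
#'
#' Converts two orthogonal diameter measurements to a volume assuming an
#' oblate spheroid: the two equal (equatorial) axes take the long diameter,
#' giving V = (pi/6) * L^2 * S. The alternative prolate convention
#' V = (pi/6) * L * S^2 is available via `convention = "prolate"`.
#'
#' @param diam_long_cm,diam_short_cm Long and short diameters in cm
#'   (vectors allowed); `diam_long_cm >= diam_short_cm >= 0` required.
#' @param convention `"oblate"` (default) or `"prolate"`.
#' @return Volume(s) in cm^3.
#' @examples
#' oblate_volume(2, 2) # sphere, 4*pi/3
#' oblate_volume(2, 1) # (pi/6)*4*1
#' @export
oblate_volume <- function(diam_long_cm, diam_short_cm,
                          convention = c("oblate", "prolate")) {
  convention <- match.arg(convention)
  if (any(diam_short_cm < 0, na.rm = TRUE)) {
    abort("Diameters must be >= 0.")
  }
  if (any(diam_short_cm > diam_long_cm, na.rm = TRUE)) {
    abort("`diam_long_cm` must be >= `diam_short_cm` (check argument order).")
  }
  if (convention == "oblate") {
    pi / 6 * diam_long_cm^2 * diam_short_cm
  } else {
    pi / 6 * diam_long_cm * diam_short_cm^2
  }
}

#' Interpolate lesion volume at the PET scan time
#'
#' Linearly interpolates the volume change between the baseline CT and the
#' first on-treatment response CT to obtain the expected lesion volume at the
#' time of the PET scan. Queries after the follow-up CT are clamped to the
#' follow-up volume (volumes are never extrapolated below zero).
#'
#' @param v_baseline_cm3,v_followup_cm3 Volumes (cm^3, >= 0) at the two CTs.
#' @param t_baseline_d,t_followup_d CT times in days; `t_followup_d` must be
#'   greater than `t_baseline_d`.
#' @param t_query_d Query time(s) in days, `>= t_baseline_d`.
#' @return Interpolated volume(s) in cm^3.
#' @examples
#' interpolate_volume(10, 6, 0, 42, 30) # 10 - 4*30/42
#' @export
interpolate_volume <- function(v_baseline_cm3, v_followup_cm3,
                               t_baseline_d, t_followup_d, t_query_d) {
  if (any(c(v_baseline_cm3, v_followup_cm3) < 0, na.rm = TRUE)) {
    abort("Volumes must be >= 0.")
  }
  if (any(t_followup_d <= t_baseline_d)) {
    abort("`t_followup_d` must be > `t_baseline_d`.")
  }
  if (any(t_query_d < t_baseline_d)) {
    abort("`t_query_d` must be >= `t_baseline_d`.")
  }
  frac <- pmin(1, (t_query_d - t_baseline_d) / (t_followup_d - t_baseline_d))
  v_baseline_cm3 + frac * (v_followup_cm3 - v_baseline_cm3)
}
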