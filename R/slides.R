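#' Generate a synthetic autoradiography / CD8-IHC slide pair
#'
#' Builds a paired slide with known ground truth for validating the
#' coregistration and tile-correlation pipeline. A smooth random blob field
#' inside an elliptical tumor ROI defines the local CD8 density, scaled per
#' immune phenotype: `desert` (near-zero density inside the tumor),
#' `stromal` (density concentrated in a rim at the tumor border) or
#' `inflamed` (diffuse). The binary IHC positivity image is Bernoulli in the
#' density. The autoradiography signal is the PSF-blurred density scaled by
#' the physical decay factor `2^(-scan_delay_h / 78.4)`, plus a constant
#' background and Gaussian noise, resampled into its own frame through the
#' known affine misalignment. Landmarks are exact corresponding points.
#'
#' @param shape Image shape `c(rows, cols)`, at least 64 x 64 (256 x 256 is
#'   typical for tests at desk scale).
#' @param phenotype `"desert"`, `"stromal"` or `"inflamed"`.
#' @param affine The true misalignment, a `cd8_affine` mapping IHC
#'   coordinates to autoradiography coordinates; default identity.
#' @param noise_sd Gaussian noise SD added to the autoradiography image.
#' @param scan_delay_h Hours from injection to plate scanning.
#' @param psf_sigma Point-spread blur of the autoradiography signal in
#'   pixels (0 disables blurring).
#' @param background Constant autoradiography background level.
#' @param amplitude Autoradiography signal amplitude at density 1.
#' @param n_landmarks Number of landmark pairs, default 4.
#' @param blob_sigma Smoothing scale of the density blob field; default
#'   1/16 of the smaller image side.
#' @param seed Integer seed.
#' @return Object of class `cd8_slide_pair`: matrices `ihc_positivity`,
#'   `arg_image`, `roi_mask`, `background_mask`, tibble `landmarks`
#'   (`x_ihc`, `y_ihc`, `x_arg`, `y_arg`), `scan_delay_h`, `true_affine`,
#'   `true_density_field`.
#' @export
generate_slide_pair <- function(shape = c(256L, 256L),
                                phenotype = c("inflamed", "stromal", "desert"),
                                affine = NULL,
                                noise_sd = 0,
                                scan_delay_h = 0,
                                psf_sigma = 2,
                                background = 0.02,
                                amplitude = 1,
                                n_landmarks = 4L,
                                blob_sigma = NULL,
                                seed = 1L) {
  phenotype <- match.arg(phenotype)
  if (any(shape < 64L)) abort("`shape` must be at least 64 x 64 pixels.")
  if (is.null(affine)) affine <- affine_from_params()
  stopifnot(inherits(affine, "cd8_affine"))
  h <- shape[1]; w <- shape[2]
  if (is.null(blob_sigma)) blob_sigma <- min(h, w) / 16
  withr::local_seed(seed)

  ## elliptical tumor ROI, background band along the image border
  rr <- matrix(rep(seq_len(h), w), h, w)
  cc <- matrix(rep(seq_len(w), each = h), h, w)
  roi <- ((rr - h / 2) / (0.36 * h))^2 + ((cc - w / 2) / (0.32 * w))^2 <= 1
  border <- pmin(rr - 1, h - rr, cc - 1, w - cc)
  bg_mask <- border < round(0.05 * min(h, w))
  bg_mask[roi] <- FALSE

  ## smooth blob field in [0, 1]
  field <- gaussian_blur(matrix(runif(h * w), h, w), blob_sigma)
  field <- (field - min(field)) / max(1e-12, diff(range(field)))

  density <- matrix(0, h, w)
  if (phenotype == "desert") {
    density[roi] <- 0.01 * field[roi]
  } else if (phenotype == "inflamed") {
    density[roi] <- 0.05 + 0.45 * field[roi]
  } else {
    rim <- gaussian_blur(roi * 1, min(h, w) / 40)
    rimw <- 4 * rim * (1 - rim)          # peaks at the ROI boundary
    density[roi] <- (0.05 + 0.55 * field[roi]) * rimw[roi]
  }
  density <- pmin(pmax(density, 0), 1)

  ihc <- matrix(as.numeric(rbinom(h * w, 1L, density)), h, w)

  signal <- if (psf_sigma > 0) gaussian_blur(density, psf_sigma) else density
  signal <- signal * amplitude * 2^(-scan_delay_h / ZR89_HALF_LIFE_H) +
    background

  ## resample the IHC-frame signal into the autoradiography frame
  arg <- warp_image(signal, affine_invert(affine), out_shape = c(h, w))
  arg[is.na(arg)] <- background
  if (noise_sd > 0) arg <- arg + rnorm(h * w, 0, noise_sd)
  arg <- pmax(arg, 0)

  ## landmarks: corners of an interior rectangle plus extra interior points
  base_pts <- cbind(
    x = c(0.25, 0.75, 0.75, 0.25) * (w - 1),
    y = c(0.25, 0.25, 0.75, 0.75) * (h - 1)
  )
  if (n_landmarks > 4L) {
    extra <- cbind(x = runif(n_landmarks - 4L, 0.2, 0.8) * (w - 1),
                   y = runif(n_landmarks - 4L, 0.2, 0.8) * (h - 1))
    base_pts <- rbind(base_pts, extra)
  } else {
    base_pts <- base_pts[seq_len(max(3L, n_landmarks)), , drop = FALSE]
  }
  mapped <- affine_apply(affine, base_pts)
  landmarks <- tibble::tibble(
    x_ihc = base_pts[, 1], y_ihc = base_pts[, 2],
    x_arg = mapped[, 1], y_arg = mapped[, 2]
  )

  structure(
    list(
      ihc_positivity = ihc, arg_image = arg,
      roi_mask = roi * 1L, background_mask = bg_mask * 1L,
      landmarks = landmarks, scan_delay_h = scan_delay_h,
      true_affine = affine, true_density_field = density,
      phenotype = phenotype
    ),
    class = "cd8_slide_pair"
  )
}

#' @export
print.cd8_slide_pair <- function(x, ...) {
  cat(sprintf("Synthetic slide pair (%s phenotype), %d x %d px, %d landmarks\n",
              x$phenotype, nrow(x$ihc_positivity), ncol(x$ihc_positivity),
              nrow(x$landmarks)))
  invisible(x)
}

## separable Gaussian blur with edge replication
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur_1d <- function(m) {
    # pad rows by replication, convolve down columns
    top <- m[rep(1L, r), , drop = FALSE]
    bot <- m[rep(nrow(m), r), , drop = FALSE]
    mp <- rbind(top, m, bot)
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * mp[j:(j + nrow(m) - 1L), , drop = FALSE]
    }
    out
  }
  t(blur_1d(t(blur_1d(img))))
}

#' Register a slide pair and summarize it
#'
#' Convenience wrapper: estimates the affine from the landmarks, warps the
#' autoradiography image into the IHC frame, and computes the slide summary
#' at the requested tile sizes.
#'
#' @param pair A `cd8_slide_pair` (or a list with the same fields read from
#'   files).
#' @param tile_sizes_px Tile side lengths in pixels.
#' @param slide_id Identifier for the outputs.
#' @return A [summarize_slide()] result, with the estimated transform in
#'   attribute `"transform"`.
#' @export
register_and_summarize <- function(pair, tile_sizes_px, slide_id = "slide") {
  tr <- estimate_affine(pair$landmarks)
  arg_aligned <- warp_image(pair$arg_image, tr,
                            out_shape = dim(pair$ihc_positivity))
  out <- summarize_slide(pair$ihc_positivity, arg_aligned, pair$roi_mask,
                         pair$background_mask, tile_sizes_px,
                         scan_delay_h = pair$scan_delay_h,
                         slide_id = slide_id)
  attr(out, "transform") <- tr
  out
}
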