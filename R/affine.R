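#' Affine transform objects
#'
#' A 2x3 parameter matrix mapping destination-frame (IHC) pixel coordinates
#' to source-frame (autoradiography) coordinates:
#' `(x_src, y_src) = M %*% c(x_dst, y_dst, 1)`. Coordinates are 0-based with
#' `x` the column and `y` the row, origin at the top-left pixel.
#'
#' @param m A 2x3 numeric matrix.
#' @return Object of class `cd8_affine`.
#' @export
affine_transform <- function(m) {
  m <- as.matrix(m)
  dimnames(m) <- NULL
  if (!all(dim(m) == c(2L, 3L)) || !all(is.finite(m))) {
    abort("An affine transform is a finite 2x3 matrix.")
  }
  if (abs(det(m[, 1:2])) < 1e-12) {
    abort("Affine transform is singular (|det| < 1e-12).")
  }
  structure(list(m = m), class = "cd8_affine")
}

#' @export
print.cd8_affine <- function(x, ...) {
  cat("Affine transform (destination -> source):\n")
  print(x$m)
  invisible(x)
}

#' Build an affine from rotation, scale and translation
#'
#' @param rotation_deg Rotation angle in degrees (counterclockwise).
#' @param scale Isotropic scale factor.
#' @param translation Length-2 translation `(tx, ty)` in pixels.
#' @return A `cd8_affine`.
#' @export
affine_from_params <- function(rotation_deg = 0, scale = 1,
                               translation = c(0, 0)) {
  th <- rotation_deg * pi / 180
  r <- scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  affine_transform(cbind(r, translation))
}

#' Invert an affine transform
#'
#' @param t A `cd8_affine`.
#' @return The inverse `cd8_affine` (source -> destination becomes
#'   destination -> source of the swapped frames).
#' @export
affine_invert <- function(t) {
  stopifnot(inherits(t, "cd8_affine"))
  a <- t$m[, 1:2]
  ai <- solve(a)
  affine_transform(cbind(ai, -ai %*% t$m[, 3]))
}

#' Apply an affine transform to points
#'
#' @param t A `cd8_affine`.
#' @param xy Two-column matrix (or data frame) of `(x, y)` coordinates.
#' @return Two-column matrix of transformed coordinates.
#' @export
affine_apply <- function(t, xy) {
  stopifnot(inherits(t, "cd8_affine"))
  xy <- as.matrix(xy)
  out <- cbind(xy, 1) %*% t(t$m)
  colnames(out) <- c("x", "y")
  out
}

#' Estimate an affine transform from paired landmarks
#'
#' Least-squares 6-parameter affine mapping IHC-frame control points to
#' autoradiography-frame control points, the registration used to align the
#' two modalities. Reports the root-mean-square landmark residual.
#'
#' @param landmarks Data frame with columns `x_ihc`, `y_ihc`, `x_arg`,
#'   `y_arg`; at least 3 non-collinear pairs.
#' @return A `cd8_affine` with attribute `rmse` (landmark residual RMSE in
#'   source-frame pixels).
#' @export
estimate_affine <- function(landmarks) {
  check_columns(landmarks, c("x_ihc", "y_ihc", "x_arg", "y_arg"), "landmarks")
  n <- nrow(landmarks)
  if (n < 3L) abort("Need at least 3 landmark pairs.")
  X <- cbind(landmarks$x_ihc, landmarks$y_ihc, 1)
  if (qr(X)$rank < 3L) {
    abort("Degenerate landmarks: control points are collinear.")
  }
  B <- cbind(landmarks$x_arg, landmarks$y_arg)
  beta <- qr.solve(X, B)                 # 3x2: columns are x_src, y_src maps
  m <- t(beta)[, c(1, 2, 3)]
  fitted <- X %*% beta
  rmse <- sqrt(mean(rowSums((B - fitted)^2)))
  out <- affine_transform(m)
  attr(out, "rmse") <- rmse
  out
}

#' Warp an image through an affine transform
#'
#' Pull-resampling into the destination (IHC) frame: each output pixel takes
#' the source-image value at its transformed coordinate, with bilinear or
#' nearest-neighbour interpolation. Coordinates mapped outside the source
#' image become `NA` and are excluded from downstream tile means.
#'
#' @param src Numeric matrix (source image, e.g. autoradiography).
#' @param t A `cd8_affine` mapping destination to source coordinates.
#' @param out_shape Integer vector `c(rows, cols)` of the output; defaults
#'   to `dim(src)`.
#' @param interpolation `"bilinear"` (default; intensity images) or
#'   `"nearest"` (masks).
#' @return Numeric matrix of shape `out_shape` with `NA` outside the source.
#' @export
warp_image <- function(src, t, out_shape = dim(src),
                       interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(t, "cd8_affine"), is.matrix(src))
  h <- out_shape[1]; w <- out_shape[2]
  sh <- nrow(src); sw <- ncol(src)
  # 0-based destination pixel coordinates (x = col, y = row)
  xd <- rep(0:(w - 1L), each = h)
  yd <- rep(0:(h - 1L), times = w)
  sxy <- cbind(xd, yd, 1) %*% t(t$m)
  sx <- sxy[, 1]; sy <- sxy[, 2]
  out <- rep(NA_real_, h * w)
  if (interpolation == "nearest") {
    ri <- round(sy); ci <- round(sx)
    ok <- ri >= 0 & ri <= sh - 1 & ci >= 0 & ci <= sw - 1
    out[ok] <- src[cbind(ri[ok] + 1L, ci[ok] + 1L)]
  } else {
    x0 <- floor(sx); y0 <- floor(sy)
    ok <- x0 >= 0 & y0 >= 0 & x0 <= sw - 2 & y0 <= sh - 2
    # allow exact right/bottom edge
    edge_x <- sx == sw - 1; edge_y <- sy == sh - 1
    x0[edge_x] <- sw - 2; y0[edge_y] <- sh - 2
    ok <- ok | (sx >= 0 & sy >= 0 & sx <= sw - 1 & sy <= sh - 1)
    fx <- sx - x0; fy <- sy - y0
    i <- which(ok)
    r0 <- y0[i] + 1L; c0 <- x0[i] + 1L
    v00 <- src[cbind(r0, c0)]
    v01 <- src[cbind(r0, c0 + 1L)]
    v10 <- src[cbind(r0 + 1L, c0)]
    v11 <- src[cbind(r0 + 1L, c0 + 1L)]
    out[i] <- (1 - fy[i]) * ((1 - fx[i]) * v00 + fx[i] * v01) +
      fy[i] * ((1 - fx[i]) * v10 + fx[i] * v11)
  }
  matrix(out, nrow = h, ncol = w)
}
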