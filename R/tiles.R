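#' Tile grid over a tumor ROI
#'
#' Lays a regular grid of square tiles over the image and keeps those with
#' at least 25% overlap with the tumor region of interest. Tiles are
#' half-open pixel ranges `[row0, row0 + size)` in 0-based coordinates and
#' must lie fully inside the image.
#'
#' @param roi_mask Logical or 0/1 matrix marking the tumor ROI.
#' @param tile_size_px Tile side length in pixels.
#' @param stride_px Grid stride in pixels; defaults to `tile_size_px / 2`
#'   (50% overlapping tiles).
#' @param min_overlap Minimum ROI overlap fraction to keep a tile,
#'   default 0.25.
#' @return Tibble with columns `row0`, `col0`, `size_px`,
#'   `roi_overlap_fraction`.
#' @export
compute_tiles <- function(roi_mask, tile_size_px,
                          stride_px = max(1L, tile_size_px %/% 2L),
                          min_overlap = 0.25) {
  stopifnot(is.matrix(roi_mask))
  if (stride_px <= 0) abort("`stride_px` must be > 0.")
  h <- nrow(roi_mask); w <- ncol(roi_mask)
  if (tile_size_px > h || tile_size_px > w) {
    abort("`tile_size_px` exceeds the image dimensions.")
  }
  m <- (roi_mask != 0) * 1
  rows <- seq(0L, h - tile_size_px, by = stride_px)
  cols <- seq(0L, w - tile_size_px, by = stride_px)
  # summed-area table for O(1) tile sums
  sat <- rbind(0, cbind(0, apply(apply(m, 2, cumsum), 1, cumsum) |> t()))
  grid <- expand.grid(row0 = rows, col0 = cols)
  r1 <- grid$row0 + 1L; r2 <- grid$row0 + tile_size_px
  c1 <- grid$col0 + 1L; c2 <- grid$col0 + tile_size_px
  sums <- sat[cbind(r2 + 1L, c2 + 1L)] - sat[cbind(r1, c2 + 1L)] -
    sat[cbind(r2 + 1L, c1)] + sat[cbind(r1, c1)]
  frac <- sums / tile_size_px^2
  keep <- frac >= min_overlap
  tibble::tibble(
    row0 = as.integer(grid$row0[keep]), col0 = as.integer(grid$col0[keep]),
    size_px = as.integer(tile_size_px),
    roi_overlap_fraction = frac[keep]
  )
}

#' Per-tile IHC positivity and autoradiography intensity
#'
#' For each tile: the percentage of CD8-positive IHC pixels among valid
#' pixels, and the decay-corrected, background-subtracted mean
#' autoradiography intensity. The background is the mean autoradiography
#' signal over a non-tissue mask, subtracted per slide; negative values are
#' kept (clamping would bias rank correlations). Decay correction rescales
#' to injection time using the 89Zr half-life. Tiles with zero valid pixels
#' are dropped with a warning.
#'
#' @param ihc_positivity Binary matrix of CD8-positive pixels (IHC frame).
#' @param arg_aligned Autoradiography image warped into the IHC frame
#'   (`NA` allowed where the warp left the source image).
#' @param tiles Tile table from [compute_tiles()].
#' @param background_mask Binary matrix marking non-tissue background.
#' @param scan_delay_h Hours between injection and plate scanning.
#' @return `tiles` with added columns `ihc_pct_positive`, `arg_intensity`.
#' @export
measure_tiles <- function(ihc_positivity, arg_aligned, tiles,
                          background_mask, scan_delay_h = 0) {
  stopifnot(is.matrix(ihc_positivity), is.matrix(arg_aligned))
  if (!all(dim(ihc_positivity) == dim(arg_aligned))) {
    abort("IHC and aligned autoradiography images must have the same shape.")
  }
  bg_vals <- arg_aligned[background_mask != 0]
  bg <- mean(bg_vals, na.rm = TRUE)
  dc <- 2^(scan_delay_h / ZR89_HALF_LIFE_H)
  n <- nrow(tiles)
  ihc_pct <- numeric(n); argm <- numeric(n); ok <- logical(n)
  for (i in seq_len(n)) {
    r <- (tiles$row0[i] + 1L):(tiles$row0[i] + tiles$size_px[i])
    c <- (tiles$col0[i] + 1L):(tiles$col0[i] + tiles$size_px[i])
    a <- arg_aligned[r, c]
    p <- ihc_positivity[r, c]
    valid <- !is.na(a)
    if (!any(valid)) next
    ok[i] <- TRUE
    ihc_pct[i] <- 100 * mean(p[valid] != 0)
    argm[i] <- dc * (mean(a[valid]) - bg)
  }
  if (!all(ok)) {
    warn(sprintf("Dropped %d tile(s) with zero valid pixels.", sum(!ok)))
  }
  dplyr::mutate(tiles[ok, ], ihc_pct_positive = ihc_pct[ok],
                arg_intensity = argm[ok])
}

#' Kendall rank correlation (tau-b)
#'
#' Tau-b with tie correction. The two-sided p-value uses exact permutation
#' enumeration for n <= 8 and the tie-corrected normal approximation
#' otherwise.
#'
#' @param x,y Numeric vectors of equal length (n >= 2), finite.
#' @return One-row tibble with `tau`, `p_value`, `n`, `method`.
#' @export
kendall_tau <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2L) abort("Need at least 2 finite pairs.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation undefined for a constant vector.")
  }
  tau <- stats::cor(x, y, method = "kendall")
  if (n <= 8L) {
    perms <- permutations_of(n)
    obs <- abs(tau)
    taus <- apply(perms, 1, function(p) stats::cor(x, y[p], method = "kendall"))
    p <- mean(abs(taus) >= obs - 1e-12)
    method <- "exact permutation"
  } else {
    p <- kendall_normal_p(x, y)
    method <- "normal approximation"
  }
  tibble::tibble(tau = tau, p_value = p, n = n, method = method)
}

## all permutations of 1..n (n <= 8 -> at most 40320 rows)
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * nrow(sub) + 1L):(i * nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

## tie-corrected normal approximation for the S statistic
kendall_normal_p <- function(x, y) {
  n <- length(x)
  xs <- sign(outer(x, x, "-")); ys <- sign(outer(y, y, "-"))
  s <- sum(xs[upper.tri(xs)] * ys[upper.tri(ys)])
  t_i <- as.numeric(table(x)); u_i <- as.numeric(table(y))
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(t_i * (t_i - 1) * (2 * t_i + 5))
  vu <- sum(u_i * (u_i - 1) * (2 * u_i + 5))
  v1 <- sum(t_i * (t_i - 1)) * sum(u_i * (u_i - 1)) / (2 * n * (n - 1))
  v2 <- sum(t_i * (t_i - 1) * (t_i - 2)) * sum(u_i * (u_i - 1) * (u_i - 2)) /
    (9 * n * (n - 1) * (n - 2))
  vs <- (v0 - vt - vu) / 18 + v1 + v2
  2 * pnorm(-abs(s) / sqrt(vs))
}

#' Summarize one registered slide pair
#'
#' Computes the slide-level (global, all ROI pixels) IHC percent positivity
#' and decay-corrected background-subtracted autoradiography intensity, and
#' per-tile measurements at each requested tile size. Within-slide Kendall
#' correlations are reported per tile size only when the slide has at least
#' 6 tiles at that size (rank-correlation estimates are too unstable below
#' that).
#'
#' @param ihc_positivity,arg_aligned,roi_mask,background_mask Matrices in
#'   the common IHC frame.
#' @param tile_sizes_px Integer vector of tile side lengths; sizes larger
#'   than the image are skipped.
#' @param scan_delay_h Hours from injection to plate scanning.
#' @param slide_id Identifier carried through the outputs.
#' @param min_tiles Minimum tiles for a within-slide correlation, default 6.
#' @return Object of class `cd8_slide_summary`: `global` (one-row tibble),
#'   `tiles` (per-size measurements), `within_tau` (per-size tau or absent
#'   rows where below `min_tiles`).
#' @export
summarize_slide <- function(ihc_positivity, arg_aligned, roi_mask,
                            background_mask, tile_sizes_px,
                            scan_delay_h = 0, slide_id = "slide",
                            min_tiles = 6L) {
  roi <- roi_mask != 0
  valid <- !is.na(arg_aligned) & roi
  dc <- 2^(scan_delay_h / ZR89_HALF_LIFE_H)
  bg <- mean(arg_aligned[background_mask != 0], na.rm = TRUE)
  global <- tibble::tibble(
    slide_id = slide_id,
    global_ihc_pct = 100 * mean(ihc_positivity[valid] != 0),
    global_arg_intensity = dc * (mean(arg_aligned[valid]) - bg)
  )
  tile_sizes_px <- tile_sizes_px[tile_sizes_px <= min(dim(roi_mask))]
  tiles <- purrr::map_dfr(tile_sizes_px, function(sz) {
    tl <- compute_tiles(roi_mask, sz)
    if (nrow(tl) == 0L) return(NULL)
    dplyr::mutate(
      measure_tiles(ihc_positivity, arg_aligned, tl, background_mask,
                    scan_delay_h),
      slide_id = slide_id, .before = 1
    )
  })
  within <- if (nrow(tiles) > 0L) {
    tiles |>
      dplyr::group_by(size_px = .data$size_px) |>
      dplyr::group_modify(function(d, key) {
        if (nrow(d) < min_tiles ||
            sd(d$ihc_pct_positive) == 0 || sd(d$arg_intensity) == 0) {
          return(tibble::tibble())
        }
        kendall_tau(d$ihc_pct_positive, d$arg_intensity)
      }) |>
      dplyr::ungroup() |>
      dplyr::mutate(slide_id = slide_id, .before = 1)
  } else {
    tibble::tibble()
  }
  structure(list(global = global, tiles = tiles, within_tau = within,
                 slide_id = slide_id),
            class = "cd8_slide_summary")
}

#' Correlate autoradiography with IHC across slides
#'
#' Three modes mirroring the tissue analysis: `"slide-level"` correlates the
#' global per-slide values across slides; `"tile-within"` reports the
#' within-slide tile correlations (slides with fewer than 6 tiles at a size
#' are excluded at that size); `"tile-pooled"` pools tiles across slides per
#' tile size (slides with few tiles are retained here).
#'
#' @param summaries List of [summarize_slide()] results.
#' @param mode One of `"slide-level"`, `"tile-within"`, `"tile-pooled"`.
#' @return Tibble of Kendall correlations for the requested mode.
#' @export
correlate_slides <- function(summaries,
                             mode = c("slide-level", "tile-within",
                                      "tile-pooled")) {
  mode <- match.arg(mode)
  stopifnot(all(vapply(summaries, inherits, logical(1), "cd8_slide_summary")))
  if (length(summaries) == 0L) abort("No slides supplied.")
  if (mode == "slide-level") {
    g <- purrr::map_dfr(summaries, "global")
    if (nrow(g) < 3L) abort("Slide-level correlation needs >= 3 slides.")
    return(kendall_tau(g$global_ihc_pct, g$global_arg_intensity))
  }
  tiles <- purrr::map_dfr(summaries, "tiles")
  if (nrow(tiles) == 0L) abort("No eligible tiles across the slides.")
  if (mode == "tile-within") {
    out <- purrr::map_dfr(summaries, "within_tau")
    if (nrow(out) == 0L) abort("No slide reaches the minimum tile count.")
    return(out)
  }
  tiles |>
    dplyr::group_by(size_px = .data$size_px) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 2L || sd(d$ihc_pct_positive) == 0 ||
          sd(d$arg_intensity) == 0) {
        return(tibble::tibble())   # degenerate pool at this tile size
      }
      kendall_tau(d$ihc_pct_positive, d$arg_intensity) |>
        dplyr::mutate(n_slides = length(unique(d$slide_id)))
    }) |>
    dplyr::ungroup()
}
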