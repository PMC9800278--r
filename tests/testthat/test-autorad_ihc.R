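test_that("affine estimation recovers known transforms exactly", {
  # identity
  pts <- tibble::tibble(x_ihc = c(0, 10, 0, 10), y_ihc = c(0, 0, 10, 10))
  id <- estimate_affine(dplyr::mutate(pts, x_arg = x_ihc, y_arg = y_ihc))
  expect_equal(id$m, cbind(diag(2), c(0, 0)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(id, "rmse"), 0, tolerance = 1e-12)

  # known rotation 30 deg, scale 2, translation (5, -3)
  tr <- affine_from_params(30, 2, c(5, -3))
  mapped <- affine_apply(tr, as.matrix(pts))
  est <- estimate_affine(dplyr::bind_cols(pts, x_arg = mapped[, 1],
                                          y_arg = mapped[, 2]))
  expect_equal(est$m, tr$m, tolerance = 1e-10)

  # collinear landmarks fail
  col <- tibble::tibble(x_ihc = c(0, 1, 2), y_ihc = c(0, 1, 2),
                        x_arg = c(0, 1, 2), y_arg = c(0, 1, 2))
  expect_error(estimate_affine(col), "collinear")
})

test_that("random affines recover under noiseless and noisy landmarks", {
  withr::local_seed(53)
  for (i in 1:20) {
    tr <- affine_from_params(runif(1, -45, 45), runif(1, 0.5, 2),
                             runif(2, -20, 20))
    pts <- cbind(x = runif(6, 0, 200), y = runif(6, 0, 200))
    mp <- affine_apply(tr, pts)
    est <- estimate_affine(tibble::tibble(
      x_ihc = pts[, 1], y_ihc = pts[, 2], x_arg = mp[, 1], y_arg = mp[, 2]))
    expect_equal(est$m, tr$m, tolerance = 1e-8)
  }
  # 1 px landmark noise: mapped-point RMSE below 2 px
  rmses <- replicate(30, {
    tr <- affine_from_params(runif(1, -45, 45), runif(1, 0.5, 2),
                             runif(2, -20, 20))
    pts <- cbind(x = runif(8, 0, 200), y = runif(8, 0, 200))
    mp <- affine_apply(tr, pts) + rnorm(16, 0, 1)
    est <- estimate_affine(tibble::tibble(
      x_ihc = pts[, 1], y_ihc = pts[, 2], x_arg = mp[, 1], y_arg = mp[, 2]))
    test_pts <- cbind(runif(50, 0, 200), runif(50, 0, 200))
    sqrt(mean(rowSums((affine_apply(est, test_pts) -
                         affine_apply(tr, test_pts))^2)))
  })
  expect_lt(mean(rmses), 2)
})

test_that("warping matches index arithmetic and round-trips", {
  img <- matrix(as.numeric(1:64), 8, 8)
  # identity leaves the image unchanged
  expect_equal(warp_image(img, affine_from_params()), img)
  # integer translation with nearest interpolation is an exact shift
  tr <- affine_transform(cbind(diag(2), c(2, 1)))  # dst(x,y) <- src(x+2,y+1)
  out <- warp_image(img, tr, interpolation = "nearest")
  expect_equal(out[1:7, 1:6], img[2:8, 3:8])
  expect_true(all(is.na(out[8, ])))
  # warp then inverse-warp on a smooth image: < 1% of dynamic range
  withr::local_seed(59)
  smooth <- cd8pet:::gaussian_blur(matrix(runif(128 * 128), 128, 128), 6)
  tr2 <- affine_from_params(15, 1.2, c(4, -2))
  fwd <- warp_image(smooth, tr2)
  back <- warp_image(fwd, affine_invert(tr2))
  inner <- !is.na(back)
  inner[c(1:10, 119:128), ] <- FALSE; inner[, c(1:10, 119:128)] <- FALSE
  rmse <- sqrt(mean((back[inner] - smooth[inner])^2))
  expect_lt(rmse, 0.01 * diff(range(smooth)))
})

test_that("tile grids count and filter by ROI overlap", {
  roi <- matrix(1, 64, 64)
  tiles <- compute_tiles(roi, 16, stride_px = 8)
  expect_equal(nrow(tiles), (floor((64 - 16) / 8) + 1)^2)
  expect_true(all(tiles$roi_overlap_fraction == 1))
  # a tile with 20% overlap is excluded, 25% retained
  roi2 <- matrix(0, 32, 32)
  roi2[1:8, 1:13] <- 1    # overlap with the 16x16 tile at (0,0): 8*13/256
  t20 <- compute_tiles(roi2, 16, stride_px = 16)
  expect_false(any(t20$row0 == 0 & t20$col0 == 0 &
                     t20$roi_overlap_fraction < 0.25))
  expect_equal(nrow(compute_tiles(roi2 * 0, 16, stride_px = 16)), 0)
  roi2[1:8, 1:8] <- 1; roi2[9:16, 1:8] <- 1  # 50% overlap tile kept
  expect_true(any(compute_tiles(roi2, 16, 16)$roi_overlap_fraction >= 0.25))
  expect_error(compute_tiles(roi, 16, stride_px = 0), "stride")
})

test_that("tile measurements equal brute-force pixel loops", {
  withr::local_seed(61)
  pair <- generate_slide_pair(shape = c(128, 128), phenotype = "inflamed",
                              noise_sd = 0, scan_delay_h = 12, seed = 9)
  tiles <- compute_tiles(pair$roi_mask, 32)
  meas <- measure_tiles(pair$ihc_positivity, pair$arg_image, tiles,
                        pair$background_mask, scan_delay_h = 12)
  bg <- mean(pair$arg_image[pair$background_mask == 1])
  dc <- 2^(12 / 78.4)
  for (i in seq_len(nrow(meas))) {
    pos <- 0; tot <- 0; s <- 0
    for (r in seq(meas$row0[i] + 1, meas$row0[i] + meas$size_px[i])) {
      for (c in seq(meas$col0[i] + 1, meas$col0[i] + meas$size_px[i])) {
        tot <- tot + 1
        pos <- pos + (pair$ihc_positivity[r, c] != 0)
        s <- s + pair$arg_image[r, c]
      }
    }
    expect_equal(meas$ihc_pct_positive[i], 100 * pos / tot, tolerance = 1e-12)
    expect_equal(meas$arg_intensity[i], dc * (s / tot - bg), tolerance = 1e-12)
  }
  # uniform ARG equal to background reads zero everywhere
  flat <- matrix(1.5, 128, 128)
  m0 <- measure_tiles(pair$ihc_positivity, flat, tiles,
                      pair$background_mask, 0)
  expect_equal(m0$arg_intensity, rep(0, nrow(m0)), tolerance = 1e-12)
  # an all-positive IHC tile reads 100%
  m1 <- measure_tiles(matrix(1, 128, 128), flat, tiles,
                      pair$background_mask, 0)
  expect_equal(m1$ihc_pct_positive, rep(100, nrow(m1)))
})

test_that("Kendall tau-b matches enumeration and stays rank-invariant", {
  r1 <- kendall_tau(1:5, (1:5)^3)
  expect_equal(r1$tau, 1)
  expect_equal(kendall_tau(1:5, 5:1)$tau, -1)
  r2 <- kendall_tau(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r2$tau, 2 / 3, tolerance = 1e-12)
  # exact small-n p equals cor.test's exact null distribution (no ties)
  ct <- suppressWarnings(stats::cor.test(c(1, 2, 3, 4), c(1, 3, 2, 4),
                                         method = "kendall", exact = TRUE))
  expect_equal(r2$p_value, ct$p.value, tolerance = 1e-12)
  # invariance under strictly monotone transforms
  withr::local_seed(67)
  x <- rnorm(30); y <- x + rnorm(30)
  expect_equal(kendall_tau(exp(x), y)$tau, kendall_tau(x, y)$tau)
  expect_equal(kendall_tau(x, qlogis(plogis(y)))$tau, kendall_tau(x, y)$tau)
  expect_error(kendall_tau(rep(1, 5), 1:5), "constant")
})

test_that("slide generation honors decay, phenotype, and monotonicity", {
  # one half-life of scan delay halves the pre-noise signal pixelwise
  p0 <- generate_slide_pair(shape = c(96, 96), scan_delay_h = 0,
                            noise_sd = 0, background = 0.02, seed = 21)
  p1 <- generate_slide_pair(shape = c(96, 96), scan_delay_h = 78.4,
                            noise_sd = 0, background = 0.02, seed = 21)
  expect_equal(p1$arg_image - 0.02, (p0$arg_image - 0.02) / 2,
               tolerance = 1e-9)

  # no PSF, no noise, identity affine: tile ARG is monotone in density
  pm <- generate_slide_pair(shape = c(96, 96), phenotype = "inflamed",
                            noise_sd = 0, psf_sigma = 0, seed = 22)
  tiles <- compute_tiles(pm$roi_mask, 24)
  meas <- measure_tiles(pm$ihc_positivity, pm$arg_image, tiles,
                        pm$background_mask, 0)
  dens <- vapply(seq_len(nrow(meas)), function(i) {
    r <- (meas$row0[i] + 1):(meas$row0[i] + 24)
    c <- (meas$col0[i] + 1):(meas$col0[i] + 24)
    mean(pm$true_density_field[r, c])
  }, numeric(1))
  expect_gte(nrow(meas), 6)
  expect_equal(kendall_tau(dens, meas$arg_intensity)$tau, 1)

  # desert slides have fewer positive pixels inside the ROI than stromal
  fracs <- sapply(1:10, function(s) {
    de <- generate_slide_pair(shape = c(96, 96), phenotype = "desert",
                              seed = 1000 + s)
    st <- generate_slide_pair(shape = c(96, 96), phenotype = "stromal",
                              seed = 1000 + s)
    c(mean(de$ihc_positivity[de$roi_mask == 1]),
      mean(st$ihc_positivity[st$roi_mask == 1]))
  })
  expect_true(all(fracs[1, ] < fracs[2, ]))
  expect_error(
    generate_slide_pair(affine = affine_transform(cbind(diag(2) * 0, c(0, 0)))),
    "singular|finite")
})

test_that("slide correlation modes respect the 6-tile rule", {
  withr::local_seed(71)
  sums <- lapply(1:4, function(i) {
    pair <- generate_slide_pair(shape = c(128, 128), phenotype = "inflamed",
                                noise_sd = 0.01, seed = 30 + i)
    summarize_slide(pair$ihc_positivity, pair$arg_image, pair$roi_mask,
                    pair$background_mask, tile_sizes_px = c(32, 96),
                    slide_id = paste0("S", i))
  })
  # at 96 px these slides have < 6 tiles: absent within, present pooled
  for (s in sums) {
    n96 <- sum(s$tiles$size_px == 96)
    expect_lt(n96, 6)
    expect_false(96 %in% s$within_tau$size_px)
  }
  pooled <- correlate_slides(sums, mode = "tile-pooled")
  expect_true(96 %in% pooled$size_px)
  within <- correlate_slides(sums, mode = "tile-within")
  expect_true(all(within$size_px == 32))
  expect_error(correlate_slides(sums[1:2], mode = "slide-level"), "3 slides")
})
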