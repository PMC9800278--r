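test_that("oblate spheroid volume from orthogonal diameters", {
  expect_equal(oblate_volume(2, 2), 4 * pi / 3)
  expect_equal(oblate_volume(2, 1), pi / 6 * 4)
  expect_equal(oblate_volume(3, 0), 0)
  expect_equal(oblate_volume(2, 1, convention = "prolate"), pi / 6 * 2)
  expect_error(oblate_volume(1, 2), "argument order")
})

test_that("volume interpolation to PET time is linear with clamping", {
  expect_equal(interpolate_volume(10, 6, 0, 42, 30), 10 - 4 * 30 / 42)
  expect_equal(interpolate_volume(10, 6, 0, 42, 0), 10)
  expect_equal(interpolate_volume(10, 6, 0, 42, 42), 6)
  expect_equal(interpolate_volume(10, 6, 0, 42, 60), 6)  # clamped
  expect_error(interpolate_volume(-1, 6, 0, 42, 10), ">= 0")
  expect_error(interpolate_volume(10, 6, 42, 42, 50), "t_followup_d")
})

test_that("restricted cubic spline basis is linear beyond boundary knots", {
  knots <- c(-1, 0, 0.7, 1.5, 3)
  below <- seq(-5, -1.2, length.out = 20)
  above <- seq(3.2, 8, length.out = 20)
  for (x in list(below, above)) {
    B <- rcs_basis(x, knots)
    # every basis column is affine in x outside the boundary knots
    for (j in seq_len(ncol(B))) {
      fit <- lm(B[, j] ~ x)
      expect_lt(max(abs(residuals(fit))), 1e-10)
    }
  }
  expect_error(rcs_basis(1:5, c(1, 1, 2)), "strictly increasing")
})

test_that("pretreatment spline discovers the partial-volume knee", {
  withr::local_seed(5)
  co <- generate_cohort(generator_params(seed = 205, n_patients = 300))
  pre <- co$lesions[co$lesions$timepoint == 0 & !co$lesions$irradiated, ]
  pre$volume_cm3 <- oblate_volume(pre$diam_long_cm, pre$diam_short_cm)
  sp <- quiet_lmer(fit_volume_uptake_spline(pre))
  # attenuated region: expectation increases with volume below 2 cm^3
  v_small <- c(0.6, 0.9, 1.3, 1.8)
  expect_true(all(diff(predict(sp, v_small)) > 0))
  # flat region between the knee and the 95th percentile
  v_flat <- seq(3, quantile(pre$volume_cm3, 0.95), length.out = 10)
  slopes <- diff(predict(sp, v_flat)) / diff(log(v_flat))
  expect_lt(max(abs(slopes)), 0.08)
  # consistency of the stored anchor expectation
  expect_equal(sp$expected_at_anchor, predict(sp, 5))
})

test_that("volume-independent uptake yields a flat spline", {
  withr::local_seed(9)
  n <- 400
  d <- tibble::tibble(
    volume_cm3 = exp(rnorm(n, log(4), 1.1)),
    suv_max = rlnorm(n, log(5.6), 0.3)
  )
  sp <- fit_volume_uptake_spline(d)
  grid <- exp(seq(log(0.5), log(40), length.out = 30))
  pred <- predict(sp, grid)
  # flat within a couple of residual standard errors everywhere
  expect_lt(diff(range(pred)), 2 * sp$sigma / sqrt(n) * 6 + 0.1)
})

test_that("adjustment is anchored, identity for flat splines, and monotone", {
  withr::local_seed(13)
  co <- generate_cohort(generator_params(seed = 301, n_patients = 150))
  pre <- co$lesions[co$lesions$timepoint == 0, ]
  pre$volume_cm3 <- oblate_volume(pre$diam_long_cm, pre$diam_short_cm)
  sp <- quiet_lmer(fit_volume_uptake_spline(pre))

  # anchor identity: a lesion at 5 cm^3 is unchanged
  at5 <- adjust_uptake(
    tibble::tibble(suv_max = 7.7, volume_at_pet_cm3 = 5), sp)
  expect_equal(at5$suv_max_adjusted, 7.7)

  # constant spline: adjustment is the identity map
  flat <- sp
  flat$coefficients <- c(1.5, rep(0, length(sp$coefficients) - 1))
  flat$expected_at_anchor <- predict(flat, flat$anchor_volume_cm3)
  d <- tibble::tibble(suv_max = c(2, 5, 11),
                      volume_at_pet_cm3 = c(0.7, 5, 30))
  expect_equal(adjust_uptake(d, flat)$suv_max_adjusted, d$suv_max)

  # equal observed SUV: the smaller lesion below the knee adjusts higher
  two <- adjust_uptake(
    tibble::tibble(suv_max = c(5, 5), volume_at_pet_cm3 = c(0.7, 1.8)), sp)
  expect_gt(two$suv_max_adjusted[1], two$suv_max_adjusted[2])

  # linear-scale mode agrees at the anchor
  lin <- adjust_uptake(
    tibble::tibble(suv_max = 7.7, volume_at_pet_cm3 = 5), sp,
    scale = "linear")
  expect_equal(lin$suv_max_adjusted, 7.7)

  expect_error(adjust_uptake(d, list()), "cd8_spline")
  expect_error(
    fit_volume_uptake_spline(
      tibble::tibble(volume_cm3 = rep(2, 30), suv_max = rlnorm(30))),
    "Degenerate")
})

test_that("adjustment removes the shrinkage-induced slope bias on average", {
  # equal true slopes with responder shrinkage: the raw estimate is biased
  # away from the truth, the adjusted estimate is close to it
  withr::local_seed(17)
  est <- sapply(1:12, function(s) {
    co <- generate_cohort(generator_params(seed = 400 + s))
    adj <- quiet_lmer(prepare_volume_adjusted(co$lesions))
    raw <- quiet_lmer(treatment_change_model(adj$lesions, adjusted = FALSE))
    a <- quiet_lmer(treatment_change_model(adj$lesions, adjusted = TRUE))
    c(raw = raw$overall$percent, adj = a$overall$percent)
  })
  truth <- -4.6
  expect_lt(abs(mean(est["adj", ]) - truth), 0.5)
  expect_gt(abs(mean(est["raw", ]) - truth), abs(mean(est["adj", ]) - truth))
})
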