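test_that("RECIST categorization applies the threshold rules", {
  expect_equal(as.character(recist_categorize(100, 70, 70)), "PR")
  expect_equal(as.character(recist_categorize(100, 50, 61)), "PD")
  expect_equal(as.character(recist_categorize(100, 85, 85)), "SD")
  expect_equal(as.character(recist_categorize(100, 0, 0)), "CR")
  # 20% rise over nadir but < 5 mm absolute is not PD
  expect_equal(as.character(recist_categorize(14, 10, 12.4)), "SD")
  expect_equal(as.character(recist_categorize(100, 80, 80, new_lesions = TRUE)),
               "PD")
  expect_error(recist_categorize(50, 60, 55), "nadir")
})

test_that("Kaplan-Meier equals the hand product-limit computation", {
  km <- km_estimate(tibble::tibble(time = c(1, 2, 3), event = c(1, 1, 1)))
  s2 <- km$steps$survival[km$steps$time == 2]
  expect_equal(s2, (2 / 3) * (1 / 2))
  # all censored
  kmc <- km_estimate(tibble::tibble(time = c(2, 4), event = c(0, 0)))
  expect_true(all(kmc$steps$survival == 1))
  # one event of two
  km2 <- km_estimate(tibble::tibble(time = c(1, 2), event = c(1, 0)))
  expect_equal(km2$steps$survival[km2$steps$time == 1], 0.5)
  # no censoring: equals the empirical survival function
  tt <- c(1, 2, 4, 5, 9)
  kme <- km_estimate(tibble::tibble(time = tt, event = 1))
  expect_equal(kme$steps$survival[kme$steps$n_event == 1],
               1 - seq_along(tt) / 5)
  expect_error(km_estimate(tibble::tibble(time = c(0, 1), event = c(1, 1))),
               "> 0")
})

test_that("log-rank matches the Cox score test and is label-invariant", {
  d <- toy_survival()
  lr <- logrank_test(d)
  # score test of an unpenalized Cox fit with the binary group covariate
  cox <- survival::coxph(survival::Surv(time, event) ~ I(group == "b"),
                         data = d, ties = "breslow")
  expect_equal(lr$statistic, unname(cox$score), tolerance = 1e-8)
  # label permutation invariance
  d2 <- dplyr::mutate(d, group = ifelse(group == "a", "b", "a"))
  expect_equal(logrank_test(d2)$statistic, lr$statistic, tolerance = 1e-12)
  # identical groups: statistic 0
  same <- tibble::tibble(time = rep(c(1, 2, 3), 2), event = 1,
                         group = rep(c("a", "b"), each = 3))
  lr0 <- logrank_test(same)
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1, tolerance = 1e-12)
  expect_error(
    logrank_test(tibble::tibble(time = 1:4, event = 0,
                                group = rep(c("a", "b"), 2))),
    "censored")
})

test_that("Firth-penalized Cox matches a brute-force grid on tiny data", {
  d4 <- tibble::tibble(time = c(1, 2, 3, 4), event = c(1, 1, 1, 0),
                       x = c(0.5, -0.2, 1.1, 0.3))
  fit <- firth_cox(d4, "x")
  # independent 1e-4 grid search of the penalized objective
  ll <- cd8pet:::cox_penalized_loglik_factory(d4$time, d4$event, d4$x)
  grid <- seq(-10, 10, by = 1e-4)
  vals <- vapply(grid, ll$pll, numeric(1))
  expect_equal(fit$log_hr, grid[which.max(vals)], tolerance = 2e-4)
})

test_that("Firth-penalized Cox agrees with coxph away from separation", {
  withr::local_seed(41)
  n <- 400
  x <- rnorm(n)
  t_raw <- rexp(n, 0.1 * exp(0.5 * x))
  d <- tibble::tibble(time = pmin(t_raw, 20),
                      event = as.integer(t_raw <= 20), x = x)
  fit <- firth_cox(d, "x")
  ref <- survival::coxph(survival::Surv(time, event) ~ x, data = d,
                         ties = "breslow")
  expect_lt(abs(fit$log_hr - unname(coef(ref))) / abs(coef(ref)), 0.02)
})

test_that("Firth penalization keeps separated data finite", {
  # all events in one arm: unpenalized likelihood is monotone
  d <- tibble::tibble(time = c(1, 2, 3, 4, 5, 6, 7, 8),
                      event = c(1, 1, 1, 1, 0, 0, 0, 0),
                      x = c(1, 1, 1, 1, 0, 0, 0, 0))
  fit <- firth_cox(d, "x")
  expect_true(is.finite(fit$log_hr))
  expect_true(is.finite(fit$ci_low) || is.finite(fit$ci_high))
  expect_error(firth_cox(dplyr::mutate(d, x = 1), "x"), "zero variance")
})

test_that("median split and standardization follow the predefined rules", {
  co <- generate_cohort(generator_params(seed = 603))
  expo <- patient_uptake_exposure(co$lesions)
  med <- median(expo$geomean_suv)
  expect_true(all(expo$uptake_group[expo$geomean_suv <= med] == "low"))
  expect_true(all(expo$uptake_group[expo$geomean_suv > med] == "high"))
  expect_equal(sd(expo$suv_z), 1)
  expect_equal(mean(expo$suv_z), 0, tolerance = 1e-12)
})

test_that("estimated hazard direction tracks the generator's uptake effect", {
  withr::local_seed(47)
  signs <- sapply(1:40, function(s) {
    co <- generate_cohort(generator_params(seed = 700 + s))
    expo <- patient_uptake_exposure(co$lesions)
    d <- dplyr::inner_join(co$patients, expo, by = "patient_id")
    fit <- firth_cox(
      tibble::tibble(time = d$os_months, event = d$os_event,
                     geomean = d$geomean_suv),
      "geomean", standardize = TRUE, direction = "decrease")
    sign(fit$log_hr)
  })
  # generator: higher uptake, lower hazard, so HR per SD decrease > 1
  expect_gte(mean(signs > 0), 0.9)
})
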