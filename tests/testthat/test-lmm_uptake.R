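test_that("REML components equal ANOVA method-of-moments on balanced data", {
  d <- balanced_oneway(g = 8, m = 5)
  fit <- fit_lmm(d, ~1, random = "patient")
  mom <- mom_components(log(d$suv_max), d$patient_id)
  expect_equal(fit$sigma2_patient, unname(mom["between"]), tolerance = 1e-8)
  expect_equal(fit$sigma2_resid, unname(mom["within"]), tolerance = 1e-8)
})

test_that("intercept-only fit back-transforms to the geometric mean", {
  d <- balanced_oneway(g = 5, m = 3, seed = 8)
  fit <- fit_lmm(d, ~1, random = "patient")
  # grand mean of a balanced layout is the overall log mean
  expect_equal(exp(unname(fit$beta[1])),
               summarize_uptake(d$suv_max)$geometric_mean, tolerance = 1e-6)
})

test_that("zero-noise data reduce to the OLS solution", {
  d <- tibble::tibble(
    patient_id = rep(c("a", "b", "c", "d"), each = 3),
    x = rep(c(0, 1, 2), 4)
  )
  d$suv_max <- exp(1 + 0.5 * d$x)
  fit <- quiet_lmer(fit_lmm(d, ~x, random = "patient"))
  expect_equal(unname(fit$beta), c(1, 0.5), tolerance = 1e-6)
})

test_that("percent effects back-transform exactly and symmetrically", {
  d <- balanced_oneway(g = 6, m = 4, seed = 30)
  d$x <- rep(rep(c(0, 1), 2), 6)
  fit <- fit_lmm(d, ~x, random = "patient")
  p0 <- percent_effect(fit, c(x = 0))
  expect_equal(p0$percent, 0, tolerance = 1e-12)
  # formula identities on the estimate itself
  est <- percent_effect(fit, c(x = 1))
  expect_equal(est$percent, 100 * (exp(sum(c(0, 1) * fit$beta)) - 1),
               tolerance = 1e-12)
  # reciprocal symmetry between +c and -c
  pos <- percent_effect(fit, c(x = 1))$percent
  neg <- percent_effect(fit, c(x = -1))$percent
  expect_equal(neg, 100 * (1 / (1 + pos / 100) - 1), tolerance = 1e-9)
  # published-style magnitudes are pure formula inversions
  expect_equal(100 * (exp(log(1.62)) - 1), 62, tolerance = 1e-12)
  expect_equal(100 * (exp(-0.04718) - 1), -4.608, tolerance = 1e-3)
  expect_error(percent_effect(fit, c(bogus = 1)), "Unknown coefficient")
})

test_that("likelihood-ratio test demands ML and handles identical models", {
  d <- balanced_oneway(g = 6, m = 4, seed = 31)
  d$x <- rnorm(nrow(d))
  full_ml <- fit_lmm(d, ~x, random = "patient", method = "ML")
  red_ml <- fit_lmm(d, ~1, random = "patient", method = "ML")
  same <- lrt(full_ml, full_ml)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  out <- lrt(full_ml, red_ml)
  expect_gte(out$statistic, 0)
  expect_equal(out$df, 1)
  full_reml <- fit_lmm(d, ~x, random = "patient")
  expect_error(lrt(full_reml, red_ml), "ML")
})

test_that("strong effects give tiny LRT p, null effects are calibrated", {
  withr::local_seed(77)
  # strong two-level factor
  d <- tibble::tibble(
    patient_id = rep(sprintf("P%02d", 1:16), each = 4),
    g = rep(rep(c(0, 1), each = 2), 16)
  )
  d$suv_max <- exp(1 + 3 * d$g + rnorm(64, 0, 0.1) +
                     rep(rnorm(16, 0, 0.1), each = 4))
  full <- quiet_lmer(fit_lmm(d, ~g, random = "patient", method = "ML"))
  red <- quiet_lmer(fit_lmm(d, ~1, random = "patient", method = "ML"))
  expect_lt(lrt(full, red)$p_value, 1e-6)

  # null two-level factor: rejection rate near nominal 5%
  rej <- replicate(300, {
    d$suv_max <- exp(1 + rnorm(64, 0, 0.3) + rep(rnorm(16, 0, 0.4), each = 4))
    f <- quiet_lmer(fit_lmm(d, ~g, random = "patient", method = "ML"))
    r <- quiet_lmer(fit_lmm(d, ~1, random = "patient", method = "ML"))
    lrt(f, r)$p_value < 0.05
  })
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
})

test_that("nested variance components are recovered from synthetic cohorts", {
  withr::local_seed(19)
  comps <- sapply(1:25, function(s) {
    co <- generate_cohort(generator_params(
      seed = 500 + s, pv_gamma = 0,
      slope_per_week_by_bor = c(PD = 0, SD = 0, PR = 0, CR = 0),
      lesion_slope_sd = 0))
    fit <- quiet_lmer(fit_lmm(co$lesions[!co$lesions$irradiated, ], ~1,
                              random = c("patient", "lesion")))
    c(fit$sigma2_patient, fit$sigma2_lesion, fit$sigma2_resid)
  })
  p <- generator_params()
  truth <- c(p$sd_patient^2, p$sd_lesion^2, p$sd_residual^2)
  expect_equal(unname(rowMeans(comps)), unname(truth), tolerance = 0.12)
})

test_that("ICC partitions the patient share of total variance", {
  mkfit <- function(sp, sl, se) {
    structure(list(sigma2_patient = sp, sigma2_lesion = sl,
                   sigma2_resid = se), class = "cd8_lmm")
  }
  expect_equal(compute_icc(mkfit(0.2, 0.19, 0.01)), 0.5)
  expect_equal(compute_icc(mkfit(0, 0.3, 0.1)), 0)
  expect_equal(compute_icc(mkfit(0.3, NA, 0.3)), 0.5)
  expect_error(compute_icc(mkfit(0, 0, 0)), "undefined")
})

test_that("trend coding equals a Wald test on the numeric response score", {
  withr::local_seed(23)
  co <- generate_cohort(generator_params(seed = 601))
  base <- co$lesions[co$lesions$timepoint == 0 & !co$lesions$irradiated, ]
  base$bor_num <- c(PD = 0, SD = 1, PR = 2, CR = 3)[as.character(base$bor)]
  fit <- quiet_lmer(fit_lmm(base, ~bor_num, random = "patient"))
  trend <- percent_effect(fit, c(bor_num = 1))
  row <- tidy(fit)
  row <- row[row$term == "bor_num", ]
  expect_equal(trend$p_value, row$p_value, tolerance = 1e-9)
})

test_that("degenerate designs are refused with clear errors", {
  d <- balanced_oneway(g = 4, m = 3)
  d$x1 <- rnorm(nrow(d)); d$x2 <- 2 * d$x1
  expect_error(fit_lmm(d, ~x1 + x2, random = "patient"), "rank deficient")
  expect_error(fit_lmm(d[d$patient_id == "P01", ], ~1, random = "patient"),
               "2 patients")
  d$lesion_id <- seq_len(nrow(d))  # no repeats
  expect_error(fit_lmm(d, ~1, random = c("patient", "lesion")), "repeated")
})

test_that("treatment-change projection is arithmetically consistent", {
  withr::local_seed(29)
  co <- generate_cohort(generator_params(seed = 602, pv_gamma = 0))
  rep_ <- quiet_lmer(treatment_change_model(co$lesions))
  r <- rep_$overall$percent / 100
  expect_equal(rep_$overall$projection_percent,
               100 * ((1 + r)^(30 / 7) - 1), tolerance = 1e-12)
  # with no attenuation and equal slopes, estimate is near the -4.6%/week truth
  expect_lt(abs(rep_$overall$percent - -4.6), 1.5)
  no_tx <- co$lesions[co$lesions$timepoint == 0, ]
  expect_error(treatment_change_model(no_tx), "on-treatment")
})
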