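## shared fixtures, built in code

# small survival dataset with distinct event times in two groups
toy_survival <- function() {
  tibble::tibble(
    time = c(1, 3, 5, 7, 9, 2, 4, 6, 8, 10),
    event = c(1, 1, 1, 0, 1, 1, 1, 0, 1, 1),
    group = rep(c("a", "b"), each = 5)
  )
}

# balanced one-way layout: g groups x m replicates with known effects
balanced_oneway <- function(g = 6, m = 4, sd_g = 0.7, sd_e = 0.3, seed = 42) {
  withr::local_seed(seed)
  u <- rnorm(g, 0, sd_g)
  tibble::tibble(
    patient_id = rep(sprintf("P%02d", seq_len(g)), each = m),
    suv_max = exp(rep(u, each = m) + rnorm(g * m, 0, sd_e) + 1.5)
  )
}

# ANOVA method-of-moments variance components for a balanced one-way layout
mom_components <- function(y, group) {
  m <- length(y) / length(unique(group))
  means <- tapply(y, group, mean)
  msb <- m * var(as.numeric(means))
  msw <- mean(tapply(y, group, var))
  c(between = (msb - msw) / m, within = msw)
}

quiet_lmer <- function(expr) {
  withCallingHandlers(expr,
    message = function(m) invokeRestart("muffleMessage"),
    warning = function(w) {
      if (grepl("singular|converge", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}
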