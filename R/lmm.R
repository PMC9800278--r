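#' Fit a log-scale linear mixed model with patient (and nested lesion)
#' random intercepts
#'
#' The workhorse model of the uptake analyses: log SUVmax regressed on fixed
#' covariates, with a random intercept per patient to account for repeated
#' measurements within patients and, when lesions are measured repeatedly,
#' an additional random intercept per lesion nested within patient. Fitted
#' by REML (for estimates, Wald CIs and Satterthwaite degrees of freedom) or
#' ML (for likelihood-ratio comparisons).
#'
#' @param data Data frame with a `patient_id` column (and `lesion_id` when
#'   `random` includes `"lesion"`), the response column, and all fixed-effect
#'   covariates.
#' @param fixed One-sided formula of fixed effects, e.g. `~ weeks * group`;
#'   default intercept only.
#' @param response Name of the response column, default `"suv_max"`.
#' @param log_response Log-transform the response (default `TRUE`; SUVmax is
#'   right-skewed and analyzed geometrically). Set `FALSE` for normal-tissue
#'   SUVmean analyzed untransformed.
#' @param random `"patient"` or `c("patient", "lesion")` for lesion-within-
#'   patient nesting. Nesting requires at least one lesion with repeated
#'   measurements.
#' @param method `"REML"` (default) or `"ML"`.
#' @return An object of class `cd8_lmm`: the underlying `lmerModLmerTest`
#'   fit plus extracted fixed effects (`beta`, `vcov_beta`), variance
#'   components (`sigma2_patient`, `sigma2_lesion`, `sigma2_resid`),
#'   `loglik` and `method`.
#' @export
fit_lmm <- function(data, fixed = ~1, response = "suv_max",
                    log_response = TRUE,
                    random = c("patient", "lesion"),
                    method = c("REML", "ML")) {
  method <- match.arg(method)
  random <- match.arg(random, c("patient", "lesion"), several.ok = TRUE)
  check_columns(data, c("patient_id", response), "data")
  data <- tibble::as_tibble(data)
  if (length(unique(data$patient_id)) < 2L) {
    abort("Need at least 2 patients (single grouping level is degenerate).")
  }
  y <- data[[response]]
  if (log_response) {
    if (any(y <= 0, na.rm = TRUE)) abort("Response must be > 0 to log-transform.")
    data$.y <- log(y)
  } else {
    data$.y <- y
  }
  use_lesion <- "lesion" %in% random
  if (use_lesion) {
    check_columns(data, "lesion_id", "data")
    data$.lesion <- interaction(data$patient_id, data$lesion_id, drop = TRUE)
    if (!any(table(data$.lesion) > 1L)) {
      abort(paste("Nested lesion intercepts require repeated measures per",
                  "lesion; no lesion has more than one row."))
    }
  }
  fixed_rhs <- paste(deparse(fixed[[2]]), collapse = " ")
  rand_rhs <- if (use_lesion) "(1 | patient_id) + (1 | .lesion)" else
    "(1 | patient_id)"
  form <- stats::as.formula(paste(".y ~", fixed_rhs, "+", rand_rhs))
  # full-rank check on the fixed design
  mm <- stats::model.matrix(stats::as.formula(paste("~", fixed_rhs)), data)
  if (qr(mm)$rank < ncol(mm)) {
    abort("Fixed-effect design matrix is rank deficient.")
  }
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE,
                            optCtrl = list(xtol_abs = 1e-12,
                                           ftol_abs = 1e-12))
  # modular fit with a gradient-based polish of the profiled deviance:
  # derivative-free optimizers stall ~sqrt(ftol) from the optimum, which is
  # visible against closed-form oracles on balanced designs
  fit <- suppressWarnings(fit_polished_lmer(form, data, method, ctrl))
  # Satterthwaite machinery can fail on boundary/zero-variance fits;
  # downstream code falls back to a normal approximation there
  fit_lt <- tryCatch(
    suppressWarnings(lmerTest::lmer(form, data = data,
                                    REML = (method == "REML"),
                                    start = lme4::getME(fit, "theta"),
                                    control = ctrl)),
    error = function(e) NULL)
  vcov_beta <- tryCatch(
    suppressWarnings(as.matrix(stats::vcov(fit))),
    error = function(e) {
      p <- length(lme4::fixef(fit))
      matrix(NA_real_, p, p)
    })
  vc <- as.data.frame(lme4::VarCorr(fit))
  getvc <- function(grp) {
    i <- vc$grp == grp & vc$var1 == "(Intercept)" & is.na(vc$var2)
    if (any(i, na.rm = TRUE)) vc$vcov[which(i)] else 0
  }
  out <- structure(
    list(
      fit = fit,
      fit_lt = fit_lt,
      beta = lme4::fixef(fit),
      vcov_beta = vcov_beta,
      sigma2_patient = getvc("patient_id"),
      sigma2_lesion = if (use_lesion) getvc(".lesion") else NA_real_,
      sigma2_resid = vc$vcov[vc$grp == "Residual"],
      loglik = as.numeric(logLik(fit)),
      method = method,
      log_response = log_response,
      n_obs = nrow(data),
      formula = form
    ),
    class = "cd8_lmm"
  )
  if (!use_lesion) {
    # single random intercept: solve the analytic score equation, which
    # locates the optimum to machine precision (the profiled deviance
    # itself is too flat for derivative-free optimizers)
    exact <- tryCatch(
      one_way_mixed_exact(data$.y,
                          stats::model.matrix(
                            stats::as.formula(paste("~", fixed_rhs)), data),
                          data$patient_id, method,
                          lambda0 = sum(lme4::getME(fit, "theta"))^2),
      error = function(e) NULL)
    if (!is.null(exact)) {
      out$beta <- setNames(exact$beta, names(out$beta))
      out$vcov_beta <- exact$vcov_beta
      out$sigma2_patient <- exact$sigma2_patient
      out$sigma2_resid <- exact$sigma2_resid
    }
  }
  out
}

## Exact REML/ML for y = X beta + u_group + e via the profiled score in
## lambda = sigma2_group / sigma2_resid. All pieces reduce to group sums, so
## the analytic derivative can be root-found to machine precision.
one_way_mixed_exact <- function(y, X, group, method, lambda0 = 1) {
  group <- as.factor(group)
  n_i <- as.numeric(table(group))
  p <- ncol(X)
  N <- length(y)
  Xs <- rowsum(X, group)                       # group sums of columns of X
  ys <- as.numeric(rowsum(y, group))
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y^2)
  denom_df <- if (method == "REML") N - p else N

  pieces <- function(lambda) {
    ci <- lambda / (1 + n_i * lambda)
    XtWX <- XtX - crossprod(Xs * sqrt(ci))
    XtWy <- Xty - crossprod(Xs, ci * ys)
    beta <- solve(XtWX, XtWy)
    s_i <- ys - as.numeric(Xs %*% beta)        # group residual sums
    rss <- yty - 2 * sum(beta * Xty) + sum(beta * (XtX %*% beta))
    Q <- rss - sum(ci * s_i^2)
    sigma2e <- Q / denom_df
    list(beta = beta, XtWX = XtWX, s_i = s_i, sigma2e = sigma2e)
  }
  score <- function(lambda) {
    pc <- pieces(lambda)
    d <- (1 + n_i * lambda)^2
    g <- sum(n_i / (1 + n_i * lambda)) -
      sum(pc$s_i^2 / d) / pc$sigma2e
    if (method == "REML") {
      M <- crossprod(Xs / sqrt(d))
      g <- g - sum(diag(solve(pc$XtWX, M)))
    }
    g   # = -2 d(loglik)/d(lambda); root is the optimum
  }
  if (score(0) >= 0) {
    lambda <- 0                                # boundary: no group variance
  } else {
    lo <- max(lambda0 / 4, 1e-10); hi <- max(4 * lambda0, 1e-6)
    for (i in 1:60) {
      if (score(hi) > 0) break
      hi <- hi * 2
    }
    while (score(lo) > 0) lo <- lo / 4
    lambda <- uniroot(score, c(lo, hi), tol = 1e-14)$root
  }
  pc <- pieces(lambda)
  list(beta = as.numeric(pc$beta),
       vcov_beta = pc$sigma2e * solve(pc$XtWX),
       sigma2_patient = lambda * pc$sigma2e,
       sigma2_resid = pc$sigma2e)
}

## modular lme4 fit followed by an L-BFGS-B polish of the profiled deviance
fit_polished_lmer <- function(form, data, method, ctrl) {
  lmod <- lme4::lFormula(form, data = data, REML = (method == "REML"),
                         control = ctrl)
  devfun <- do.call(lme4::mkLmerDevfun, lmod)
  opt <- lme4::optimizeLmer(devfun, optimizer = "nloptwrap",
                            control = ctrl$optCtrl)
  best <- list(par = opt$par, fval = opt$fval, conv = 0L,
               feval = NA_integer_, message = "polished")
  polish <- tryCatch(
    polish_quadratic(devfun, opt$par, lmod$reTrms$lower),
    error = function(e) NULL)
  if (!is.null(polish) && is.finite(polish$fval) &&
      polish$fval <= opt$fval) {
    best$par <- polish$par
    best$fval <- polish$fval
  }
  devfun(best$par)   # leave the deviance environment at the optimum
  lme4::mkMerMod(environment(devfun), best, lmod$reTrms, fr = lmod$fr)
}

## coordinate-wise parabolic-vertex refinement; one step is essentially exact
## on the locally quadratic profiled deviance
polish_quadratic <- function(f, par, lower, h = 1e-5, iters = 3L) {
  f0 <- f(par)
  for (it in seq_len(iters)) {
    for (j in seq_along(par)) {
      hp <- h * (1 + abs(par[j]))
      up <- par; up[j] <- par[j] + hp
      dn <- par; dn[j] <- max(lower[j], par[j] - hp)
      fu <- f(up); fd <- f(dn)
      curv <- fu - 2 * f0 + fd
      if (!is.finite(curv) || curv <= 0) next
      cand <- par
      cand[j] <- max(lower[j], par[j] - hp * (fu - fd) / (2 * curv))
      fc <- f(cand)
      if (is.finite(fc) && fc <= f0) {
        par <- cand
        f0 <- fc
      }
    }
  }
  list(par = par, fval = f0)
}

#' @export
print.cd8_lmm <- function(x, ...) {
  cat(sprintf("Linear mixed model (%s), %d observations\n", x$method, x$n_obs))
  cat("  variance components: patient", signif(x$sigma2_patient, 4))
  if (!is.na(x$sigma2_lesion)) cat(", lesion", signif(x$sigma2_lesion, 4))
  cat(", residual", signif(x$sigma2_resid, 4), "\n")
  print(x$beta)
  invisible(x)
}

#' @export
tidy.cd8_lmm <- function(x, ...) {
  sm <- if (is.null(x$fit_lt)) NULL else {
    tryCatch(as.data.frame(suppressWarnings(summary(x$fit_lt))$coefficients),
             error = function(e) NULL)
  }
  if (is.null(sm) || ncol(sm) < 5L) {
    se <- sqrt(diag(x$vcov_beta))
    return(tibble::tibble(
      term = names(x$beta), estimate = unname(x$beta), std_error = se,
      df = NA_real_, statistic = unname(x$beta) / se,
      p_value = 2 * pnorm(-abs(unname(x$beta) / se))
    ))
  }
  tibble::tibble(
    term = rownames(sm), estimate = sm[["Estimate"]],
    std_error = sm[["Std. Error"]], df = sm[["df"]],
    statistic = sm[["t value"]], p_value = sm[["Pr(>|t|)"]]
  )
}

#' @export
glance.cd8_lmm <- function(x, ...) {
  tibble::tibble(
    sigma2_patient = x$sigma2_patient, sigma2_lesion = x$sigma2_lesion,
    sigma2_resid = x$sigma2_resid, logLik = x$loglik,
    method = x$method, nobs = x$n_obs
  )
}

#' Back-transformed percent effect for a fixed-effect contrast
#'
#' Computes `100 * (exp(c'beta) - 1)` with a confidence interval
#' back-transformed from the log-scale Wald interval using Satterthwaite
#' degrees of freedom (falling back to a normal approximation, with a
#' warning, when the Satterthwaite computation fails near a variance
#' boundary).
#'
#' @param fit A [fit_lmm()] result on a log-transformed response.
#' @param contrast Numeric contrast vector, either full length (in the order
#'   of `fit$beta`) or named by coefficient (unnamed coefficients get 0).
#' @param conf_level Confidence level, default 0.95.
#' @return One-row tibble: `percent`, `ci_low`, `ci_high`, `log_estimate`,
#'   `std_error`, `df`, `p_value`.
#' @export
percent_effect <- function(fit, contrast, conf_level = 0.95) {
  stopifnot(inherits(fit, "cd8_lmm"))
  cf <- expand_contrast(contrast, names(fit$beta))
  est <- sum(cf * fit$beta)
  if (all(cf == 0)) {
    return(tibble::tibble(percent = 0, ci_low = 0, ci_high = 0,
                          log_estimate = 0, std_error = 0, df = NA_real_,
                          p_value = NA_real_))
  }
  se <- sqrt(drop(t(cf) %*% fit$vcov_beta %*% cf))
  res <- if (is.null(fit$fit_lt)) NULL else tryCatch({
    ct <- lmerTest::contest1D(fit$fit_lt, cf, confint = TRUE,
                              level = conf_level)
    list(df = ct$df, p = ct[["Pr(>|t|)"]], lo = ct$lower, hi = ct$upper)
  }, error = function(e) NULL)
  if (is.null(res) || !is.finite(res$df)) {
    warn("Satterthwaite df unavailable; using a normal approximation.")
    z <- qnorm(1 - (1 - conf_level) / 2)
    res <- list(df = Inf, p = 2 * pnorm(-abs(est / se)),
                lo = est - z * se, hi = est + z * se)
  }
  tibble::tibble(
    percent = 100 * (exp(est) - 1),
    ci_low = 100 * (exp(res$lo) - 1),
    ci_high = 100 * (exp(res$hi) - 1),
    log_estimate = est, std_error = se, df = res$df, p_value = res$p
  )
}

expand_contrast <- function(contrast, coef_names) {
  p <- length(coef_names)
  if (!is.null(names(contrast)) && any(names(contrast) != "")) {
    bad <- setdiff(names(contrast), coef_names)
    if (length(bad)) {
      abort(sprintf("Unknown coefficient(s) in contrast: %s.",
                    paste(bad, collapse = ", ")))
    }
    cf <- setNames(numeric(p), coef_names)
    cf[names(contrast)] <- contrast
    return(cf)
  }
  if (length(contrast) != p) {
    abort(sprintf("Contrast length %d does not match %d coefficients.",
                  length(contrast), p))
  }
  as.numeric(contrast)
}

#' Likelihood-ratio test between nested mixed models
#'
#' Both models must be fitted under maximum likelihood (REML log-likelihoods
#' are not comparable across fixed-effect structures).
#'
#' @param fit_full,fit_reduced [fit_lmm()] results with `method = "ML"`,
#'   reduced nested in full.
#' @return One-row tibble with `statistic`, `df`, `p_value`.
#' @export
lrt <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "cd8_lmm"), inherits(fit_reduced, "cd8_lmm"))
  if (fit_full$method != "ML" || fit_reduced$method != "ML") {
    abort("Both fits must use method = 'ML' for a likelihood-ratio test.")
  }
  df <- length(fit_full$beta) - length(fit_reduced$beta)
  if (df < 0) abort("`fit_reduced` has more fixed effects than `fit_full`.")
  stat <- max(0, 2 * (fit_full$loglik - fit_reduced$loglik))
  p <- if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE)
  tibble::tibble(statistic = stat, df = df, p_value = p)
}

#' Intraclass correlation of log uptake
#'
#' Fraction of total log-uptake variance attributable to the patient level:
#' `sigma2_patient / (sigma2_patient + sigma2_lesion + sigma2_resid)`. In
#' the baseline model with a single scan per lesion there is no nested
#' lesion intercept and the residual variance plays the between-lesion role.
#'
#' @param fit A [fit_lmm()] result.
#' @return ICC in `[0, 1]`.
#' @export
compute_icc <- function(fit) {
  stopifnot(inherits(fit, "cd8_lmm"))
  comps <- c(fit$sigma2_patient,
             if (!is.na(fit$sigma2_lesion)) fit$sigma2_lesion,
             fit$sigma2_resid)
  total <- sum(comps)
  if (total <= 0) abort("All variance components are zero; ICC undefined.")
  fit$sigma2_patient / total
}
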