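#' Fit a mono-exponential time-activity curve
#'
#' Fits `C(t) = c0 * exp(-lambda_eff * t)` to activity-concentration
#' samples of a single organ (or blood) within one treatment cycle.
#' With exactly two samples the fit is the exact algebraic solution
#' through both points, matching the blood curve which is sampled only
#' at 18 h and 25 h. With three or more samples the curve is fitted by
#' nonlinear least squares in linear concentration space
#' (Levenberg-Marquardt via [minpack.lm::nlsLM]), initialized from the
#' log-linear ordinary-least-squares solution; fitting only in log space
#' would bias the estimates under multiplicative noise, but the log
#' solution is a robust starting point.
#'
#' A fitted effective decay constant below the 177Lu physical constant
#' ([LU177_LAMBDA_H]) is physically impossible but can arise from
#' measurement noise; it triggers a warning, not an error. A
#' non-positive decay constant (a rising curve) is rejected.
#'
#' @param samples A [timed_samples] data frame (or any data frame with
#'   `time_h` and `conc` columns) for one organ and one cycle;
#'   at least two rows with distinct times and strictly positive
#'   concentrations.
#' @return An object of class `monoexp_fit`: a list with `c0`
#'   (extrapolated concentration at t = 0, MBq/kg), `lambda_eff` (1/h),
#'   `half_life_h`, `n_points`, `rss` (residual sum of squares in
#'   concentration space), and the `organ`/`cycle` labels when present.
#' @examples
#' s <- timed_samples("blood", c(18, 25), c(30, 25))
#' f <- fit_monoexp(s)
#' f$half_life_h
#' @export
fit_monoexp <- function(samples) {
  t <- as.numeric(samples$time_h)
  y <- as.numeric(samples$conc)
  if (length(t) < 2L) {
    abort_prrt("mono-exponential fit needs at least 2 samples",
               "prrtdose_insufficient_data")
  }
  if (any(y <= 0)) {
    abort_prrt("all concentrations must be > 0 for fitting",
               "prrtdose_domain_error")
  }
  if (anyDuplicated(t)) {
    abort_prrt("sample times must be distinct", "prrtdose_domain_error")
  }
  if ("organ" %in% names(samples) && length(unique(samples$organ)) > 1L) {
    abort_prrt("samples mix more than one organ", "prrtdose_domain_error")
  }

  if (length(t) == 2L) {
    o <- order(t)
    t <- t[o]; y <- y[o]
    lam <- log(y[1] / y[2]) / (t[2] - t[1])
    if (!is.finite(lam) || lam <= 0) {
      abort_prrt("two-point curve is non-decaying (lambda <= 0)",
                 "prrtdose_nonphysical_fit")
    }
    c0 <- y[1] * exp(lam * t[1])
    rss <- 0
  } else {
    # log-linear OLS initializer
    ll <- stats::lm.fit(cbind(1, t), log(y))
    lam0 <- max(-ll$coefficients[2], 1e-8)
    c00 <- exp(ll$coefficients[1])
    df <- data.frame(t = t, y = y)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ c0 * exp(-lam * t), data = df,
                        start = list(c0 = c00, lam = lam0),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) {
      warn_prrt("nonlinear fit failed to converge; using log-linear estimates",
                "prrtdose_fit_fallback")
      c0 <- c00; lam <- -ll$coefficients[2]
    } else {
      cf <- stats::coef(fit)
      c0 <- unname(cf["c0"]); lam <- unname(cf["lam"])
    }
    if (!is.finite(lam) || lam <= 0) {
      abort_prrt("fitted decay constant is non-positive (rising curve)",
                 "prrtdose_nonphysical_fit")
    }
    rss <- sum((y - c0 * exp(-lam * t))^2)
  }

  if (lam < LU177_LAMBDA_H) {
    warn_prrt(sprintf(
      "fitted lambda_eff (%.3g 1/h) is below the 177Lu physical decay constant (%.3g 1/h)",
      lam, LU177_LAMBDA_H), "prrtdose_subphysical_lambda")
  }

  structure(list(
    c0 = unname(c0),
    lambda_eff = unname(lam),
    half_life_h = log(2) / unname(lam),
    n_points = length(t),
    rss = rss,
    organ = if ("organ" %in% names(samples)) samples$organ[1] else NA_character_,
    cycle = if ("cycle" %in% names(samples)) samples$cycle[1] else NA_integer_
  ), class = "monoexp_fit")
}

#' @export
print.monoexp_fit <- function(x, ...) {
  cat(sprintf("Mono-exponential fit%s: c0 = %.4g MBq/kg, lambda_eff = %.4g 1/h (T1/2 = %.3g h), n = %d\n",
              if (is.na(x$organ)) "" else paste0(" [", x$organ, "]"),
              x$c0, x$lambda_eff, x$half_life_h, x$n_points))
  invisible(x)
}

#' Propagate a cycle-1 fit to a later cycle from a single sample
#'
#' Later treatment cycles are imaged at a single time point (~20 h
#' post-injection). Assuming the effective half-life of the organ is
#' unchanged between cycles, the full time-activity curve of the later
#' cycle is recovered by anchoring the reference decay constant to the
#' single measured concentration: `c0 = conc * exp(lambda_eff * time_h)`.
#'
#' @param reference A `monoexp_fit` from the fully sampled cycle
#'   (normally cycle 1).
#' @param sample A single measurement: a one-row [timed_samples] data
#'   frame or a list with `time_h` and `conc` (and optionally `cycle`).
#' @return A `monoexp_fit` for the later cycle (`n_points = 1`).
#' @examples
#' ref <- structure(list(c0 = 100, lambda_eff = 0.02), class = "monoexp_fit")
#' rescale_to_cycle(ref, list(time_h = 20, conc = 40))$c0  # 40 * exp(0.4)
#' @export
rescale_to_cycle <- function(reference, sample) {
  time_h <- as.numeric(sample$time_h[1])
  conc <- as.numeric(sample$conc[1])
  if (!is.finite(conc) || conc <= 0) {
    abort_prrt("sample concentration must be > 0", "prrtdose_domain_error")
  }
  if (!is.finite(time_h) || time_h <= 0) {
    abort_prrt("sample time must be > 0", "prrtdose_domain_error")
  }
  lam <- reference$lambda_eff
  if (!is.finite(lam) || lam <= 0) {
    abort_prrt("reference fit has non-positive lambda_eff", "prrtdose_domain_error")
  }
  structure(list(
    c0 = conc * exp(lam * time_h),
    lambda_eff = lam,
    half_life_h = log(2) / lam,
    n_points = 1L,
    rss = NA_real_,
    organ = if (!is.null(sample$organ)) as.character(sample$organ[1]) else reference$organ,
    cycle = if (!is.null(sample$cycle)) as.integer(sample$cycle[1]) else NA_integer_
  ), class = "monoexp_fit")
}

#' Residence time of the activity concentration
#'
#' Integrates the fitted curve to infinity and normalizes by the
#' administered activity:
#' `t_r = integral(c0 * exp(-lambda * t) dt, 0, Inf) / A_adm
#'      = c0 * 3600 / (lambda_eff * A_adm)`,
#' in (MBq.s)/(MBq.kg). Times are carried in hours everywhere else; the
#' factor 3600 converts the integral to seconds only here.
#'
#' @param fit A `monoexp_fit`.
#' @param a_adm Administered activity for the cycle, MBq; > 0.
#' @return An object of class `residence_time`: list with `organ`,
#'   `value` ((MBq.s)/(MBq.kg)), `cycle`.
#' @examples
#' f <- structure(list(c0 = 100, lambda_eff = 0.03, organ = "kidneys",
#'                     cycle = 1L), class = "monoexp_fit")
#' residence_time(f, 7400)$value  # ~1621.6
#' @export
residence_time <- function(fit, a_adm) {
  stopifnot_scalar_number(a_adm, "a_adm")
  if (a_adm <= 0) {
    abort_prrt("administered activity must be > 0", "prrtdose_domain_error")
  }
  structure(list(
    organ = fit$organ,
    value = fit$c0 * 3600 / (fit$lambda_eff * a_adm),
    cycle = fit$cycle
  ), class = "residence_time")
}
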