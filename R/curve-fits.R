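#' Fit the Hill function to a titration series
#'
#' Least-squares fit of F = Fmin + (Fmax - Fmin) c^n / (EC50^n + c^n).
#' The Hill coefficient is free within `hill_bounds` (initialized at 1).
#' The maximal fractional response (Fmax - Fmin)/Fmin is reported
#' alongside a bootstrap confidence interval for EC50 obtained by residual
#' resampling. The fit is flagged unreliable when a parameter lands on a
#' bound or when the response range is small relative to the residual
#' noise.
#'
#' @param series A [titration_series()], or concentrations when `response`
#'   is given.
#' @param response Optional response vector (with `series` a concentration
#'   vector).
#' @param hill_bounds Bounds on the Hill coefficient.
#' @param n_bootstrap Bootstrap replicates for the EC50 CI (0 disables).
#' @param conf Confidence level.
#' @param seed Optional seed for the bootstrap.
#' @return Object of class `hill_fit`: `estimates` (ec50, hill_n, fmin,
#'   fmax), `max_dff`, `ec50_ci`, `residuals`, `fitted`, `flags`.
#' @export
fit_hill <- function(series, response = NULL, hill_bounds = c(0.5, 4),
                     n_bootstrap = 200L, conf = 0.95, seed = NULL) {
  if (inherits(series, "titration_series")) {
    conc <- series$concentration
    resp <- series$response
  } else {
    conc <- as.numeric(series)
    resp <- as.numeric(response)
  }
  stopifnot(length(conc) == length(resp))
  if (length(unique(conc)) < 5L) {
    stop_ss("need at least 5 distinct concentrations for a constrained fit")
  }
  if (any(conc < 0)) stop_ss("concentrations must be >= 0")

  pos <- conc[conc > 0]
  lo <- resp[conc == min(conc)]
  hi <- resp[conc == max(conc)]
  half <- (mean(lo) + mean(hi)) / 2
  ec50_0 <- pos[which.min(abs(resp[conc > 0] - half))]
  init <- list(fmin = mean(lo), fmax = mean(hi),
               ec50 = ec50_0, n = 1)
  lower <- c(fmin = -Inf, fmax = -Inf, ec50 = min(pos) / 100,
             n = hill_bounds[1])
  upper <- c(fmin = Inf, fmax = Inf, ec50 = max(pos) * 100,
             n = hill_bounds[2])
  do_fit <- function(y) {
    minpack.lm::nlsLM(
      y ~ fmin + (fmax - fmin) * conc^n / (ec50^n + conc^n),
      start = init, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 300))
  }
  fit <- do_fit(resp)
  cf <- stats::coef(fit)
  fitted <- stats::fitted(fit)
  res <- resp - fitted

  flags <- character(0)
  at_bound <- function(v, b) abs(v - b) <= 1e-6 * max(abs(b), 1)
  if (at_bound(cf[["n"]], hill_bounds[1]) || at_bound(cf[["n"]], hill_bounds[2])) {
    flags <- c(flags, "hill coefficient at bound")
  }
  if (at_bound(cf[["ec50"]], lower[["ec50"]]) ||
      at_bound(cf[["ec50"]], upper[["ec50"]])) {
    flags <- c(flags, "ec50 at bound")
  }
  if (abs(cf[["fmax"]] - cf[["fmin"]]) < 3 * stats::sd(res)) {
    flags <- c(flags, "response range within noise")
  }
  if (cf[["ec50"]] <= min(pos) || cf[["ec50"]] >= max(pos)) {
    flags <- c(flags, "ec50 outside sampled concentration range")
  }

  ci <- c(NA_real_, NA_real_)
  if (n_bootstrap > 0L) {
    boot <- function() {
      vapply(seq_len(n_bootstrap), function(i) {
        yb <- fitted + sample(res, length(res), replace = TRUE)
        fb <- tryCatch(do_fit(yb), error = function(e) NULL)
        if (is.null(fb)) NA_real_ else stats::coef(fb)[["ec50"]]
      }, numeric(1))
    }
    bs <- if (is.null(seed)) boot() else with_seed(seed, boot())
    ci <- stats::quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          na.rm = TRUE, names = FALSE)
  }
  structure(
    list(estimates = list(ec50 = cf[["ec50"]], hill_n = cf[["n"]],
                          fmin = cf[["fmin"]], fmax = cf[["fmax"]]),
         max_dff = (cf[["fmax"]] - cf[["fmin"]]) / cf[["fmin"]],
         ec50_ci = ci, conf = conf, residuals = res, fitted = fitted,
         concentration = conc, response = resp, flags = flags),
    class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  e <- x$estimates
  cat(sprintf("Hill fit: EC50 = %.4g, n = %.3g, Fmin = %.4g, Fmax = %.4g\n",
              e$ec50, e$hill_n, e$fmin, e$fmax))
  cat(sprintf("max dF/F0 = %.3g; EC50 %d%% CI [%.4g, %.4g]\n",
              x$max_dff, round(100 * x$conf), x$ec50_ci[1], x$ec50_ci[2]))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Extract step amplitudes from an on-cell perfusion trace
#'
#' For a protocol of ligand applications (each concentration perfused for
#' `duration` seconds, followed by wash), computes the response amplitude
#' per step as the mean dF/F0 over the final `response_avg` seconds of the
#' application minus the mean over the `baseline_avg` seconds preceding its
#' onset. The result can be passed straight to [fit_hill()].
#'
#' @param time,dff Trace samples (seconds, dF/F0).
#' @param schedule Data frame with columns `concentration` and `onset`
#'   (seconds), one row per application step.
#' @param duration Application duration in seconds.
#' @param response_avg,baseline_avg Averaging windows in seconds.
#' @return A [titration_series()] of step amplitudes.
#' @export
extract_step_amplitudes <- function(time, dff, schedule, duration = 5,
                                    response_avg = 2, baseline_avg = 2) {
  stopifnot(all(c("concentration", "onset") %in% names(schedule)))
  sch <- schedule[order(schedule$onset), ]
  if (nrow(sch) > 1L) {
    gaps <- sch$onset[-1L] - (sch$onset[-nrow(sch)] + duration)
    if (any(gaps < 0)) stop_ss("overlapping application steps in schedule")
  }
  amp <- vapply(seq_len(nrow(sch)), function(i) {
    on <- sch$onset[i]
    # half-open windows: application samples are [onset, onset + duration)
    resp_win <- time >= (on + duration - response_avg) & time < (on + duration)
    base_win <- time >= (on - baseline_avg) & time < on
    if (!any(resp_win) || !any(base_win)) {
      stop_ss(sprintf("step %d windows contain no samples", i))
    }
    mean(dff[resp_win]) - mean(dff[base_win])
  }, numeric(1))
  titration_series(sch$concentration, amp)
}

#' Fit the pH sigmoid
#'
#' Least-squares fit of F = Fmin + (Fmax - Fmin) / (1 + 10^(pKa - pH)),
#' the standard single-site protonation model for fluorophore brightness,
#' giving the apparent pKa and the limiting brightnesses.
#'
#' @param ph pH values (at least 5, spanning the transition).
#' @param brightness Fluorescence at each pH.
#' @return Object of class `ph_fit`: `pka`, `fmin`, `fmax`, `residuals`,
#'   `fitted`, `flags`.
#' @export
fit_ph <- function(ph, brightness) {
  stopifnot(length(ph) == length(brightness))
  if (length(unique(ph)) < 5L) stop_ss("need at least 5 pH points")
  ord <- order(ph)
  ph <- ph[ord]
  f <- brightness[ord]
  half <- (min(f) + max(f)) / 2
  pka0 <- ph[which.min(abs(f - half))]
  fit <- minpack.lm::nlsLM(
    f ~ fmin + (fmax - fmin) / (1 + 10^(pka - ph)),
    start = list(fmin = min(f), fmax = max(f), pka = pka0),
    control = minpack.lm::nls.lm.control(maxiter = 300))
  cf <- stats::coef(fit)
  res <- f - stats::fitted(fit)
  flags <- character(0)
  if (cf[["pka"]] <= min(ph) || cf[["pka"]] >= max(ph)) {
    flags <- c(flags, "no transition within sampled pH range")
  }
  if (abs(cf[["fmax"]] - cf[["fmin"]]) < 3 * stats::sd(res)) {
    flags <- c(flags, "transition within noise")
  }
  structure(
    list(pka = cf[["pka"]], fmin = cf[["fmin"]], fmax = cf[["fmax"]],
         residuals = res, fitted = stats::fitted(fit), ph = ph,
         flags = flags),
    class = "ph_fit")
}

#' Fit a monoexponential to a stopped-flow trace
#'
#' Fits F(t) = f_inf + (f0 - f_inf) exp(-k_obs t) for t >= `dead_time`
#' (the instrument dead time is excluded). The lag-1 autocorrelation of the
#' residuals is reported as a biphasicity diagnostic: a genuinely
#' monoexponential trace leaves near-white residuals, while a biphasic one
#' leaves structured (positively autocorrelated) residuals.
#'
#' @param trace A `kinetic_trace`, or a time vector when `fluorescence` is
#'   given.
#' @param fluorescence Optional fluorescence vector.
#' @param dead_time Seconds excluded from the start of the trace.
#' @return Object of class `monoexp_fit`: `k_obs`, `f0`, `f_inf`,
#'   `residual_autocorr`, `rmse`, `flags` (with `k_obs = NA` and flag
#'   `"unidentifiable"` on a constant trace).
#' @export
fit_monoexp <- function(trace, fluorescence = NULL, dead_time = 0.002) {
  if (inherits(trace, "kinetic_trace")) {
    t <- trace$time
    f <- trace$fluorescence
  } else {
    t <- as.numeric(trace)
    f <- as.numeric(fluorescence)
  }
  stopifnot(length(t) == length(f))
  keep <- t >= dead_time
  if (sum(keep) < 10L) stop_ss("need at least 10 samples after the dead time")
  t <- t[keep]
  f <- f[keep]
  if (diff(range(f)) == 0) {
    return(structure(
      list(k_obs = NA_real_, f0 = f[1], f_inf = f[1],
           residual_autocorr = NA_real_, rmse = 0,
           flags = "unidentifiable: constant trace"),
      class = "monoexp_fit"))
  }
  n_tail <- max(3L, ceiling(length(f) / 10))
  finf0 <- mean(utils::tail(f, n_tail))
  amp0 <- f[1] - finf0
  dev <- abs(f - finf0)
  use <- dev > max(dev) * 0.05
  k0 <- if (sum(use) >= 3L) {
    sl <- stats::coef(stats::lm(log(dev[use]) ~ t[use]))[[2]]
    if (is.finite(sl) && sl < 0) -sl else 1 / diff(range(t))
  } else {
    1 / diff(range(t))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      f ~ f_inf + (f0 - f_inf) * exp(-k * t),
      start = list(f0 = finf0 + amp0, f_inf = finf0, k = k0),
      lower = c(f0 = -Inf, f_inf = -Inf, k = 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) {
      stop_ss(sprintf(
        "monoexponential fit did not converge (init f0=%.4g, f_inf=%.4g, k=%.4g): %s",
        finf0 + amp0, finf0, k0, conditionMessage(e)))
    })
  cf <- stats::coef(fit)
  res <- f - stats::fitted(fit)
  ac <- if (stats::sd(res) > 0) {
    stats::cor(res[-length(res)], res[-1L])
  } else {
    NA_real_
  }
  structure(
    list(k_obs = cf[["k"]], f0 = cf[["f0"]], f_inf = cf[["f_inf"]],
         residual_autocorr = ac, rmse = sqrt(mean(res^2)),
         flags = character(0)),
    class = "monoexp_fit")
}

#' @export
print.monoexp_fit <- function(x, ...) {
  cat(sprintf("monoexponential fit: k_obs = %.4g /s, f0 = %.4g, f_inf = %.4g\n",
              x$k_obs, x$f0, x$f_inf))
  cat(sprintf("residual lag-1 autocorrelation = %.3g, rmse = %.3g\n",
              x$residual_autocorr, x$rmse))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Pseudo-first-order analysis of observed rate constants
#'
#' Linear fit of k_obs against ligand concentration; under a one-step
#' binding model the slope estimates the association rate constant k_on
#' and the intercept the dissociation rate constant k_off. This is an
#' extension beyond the per-trace observed rate constants.
#'
#' @param k_obs Observed rate constants (1/s).
#' @param concentration Ligand concentrations.
#' @return List with `k_on`, `k_off` and the underlying `lm` fit.
#' @export
kobs_vs_concentration <- function(k_obs, concentration) {
  stopifnot(length(k_obs) == length(concentration), length(k_obs) >= 3L)
  fit <- stats::lm(k_obs ~ concentration)
  list(k_on = stats::coef(fit)[[2]], k_off = stats::coef(fit)[[1]], fit = fit)
}
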