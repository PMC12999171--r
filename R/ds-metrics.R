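#' Response amplitude index
#'
#' RAI = (r_s - r_b) / (r_s + r_b), where r_s is the peak dF/F0 during
#' stimulation (of the trial-averaged trace) and r_b the mean dF/F0 before
#' stimulation. Lies in \[-1, 1\] for non-negative inputs.
#'
#' @param r_s Peak dF/F0 during the stimulus window.
#' @param r_b Mean dF/F0 during the baseline window.
#' @return RAI, or `NA` (with a warning) when r_s + r_b = 0.
#' @export
response_amplitude_index <- function(r_s, r_b) {
  if (r_s + r_b == 0) {
    warning("RAI undefined: r_s + r_b = 0")
    return(NA_real_)
  }
  (r_s - r_b) / (r_s + r_b)
}

#' Trial-to-trial response reliability
#'
#' Ratio of the variance over time of the across-trial mean trace to the
#' across-trial mean of the per-trial temporal variance:
#' Var\[<C>_r\]_t / <Var\[C\]_t>_r. Equals 1 when all trials are identical,
#' and approaches 1/R for R trials of pure independent noise.
#'
#' @param C A [trial_matrix()] or a numeric matrix (time x trials).
#' @param window Optional frame indices restricting the computation (for a
#'   `trial_matrix` the stimulus window is used by default when present).
#' @return Reliability, or `NA` (with a warning) when every trial is
#'   constant in time.
#' @export
response_reliability <- function(C, window = NULL) {
  if (inherits(C, "trial_matrix")) {
    window <- window %||% C$stim_window
    C <- C$C
  }
  C <- as.matrix(C)
  if (!is.null(window)) C <- C[window, , drop = FALSE]
  if (ncol(C) < 2L || nrow(C) < 2L) {
    stop_ss("need at least 2 trials and 2 time points")
  }
  denom <- mean(apply(C, 2L, stats::var))
  if (denom == 0) {
    warning("reliability undefined: all trials constant in time")
    return(NA_real_)
  }
  stats::var(rowMeans(C)) / denom
}

#' Motion-response signal-to-noise ratio
#'
#' SNR = (R_p - SD_b) / (R_p + SD_b): response amplitude in the preferred
#' direction relative to the standard deviation of the signal before
#' stimulation.
#'
#' @param r_p Response amplitude in the preferred direction.
#' @param sd_b Baseline standard deviation.
#' @return SNR, or `NA` (with a warning) when r_p + sd_b = 0.
#' @export
motion_snr <- function(r_p, sd_b) {
  if (r_p + sd_b == 0) {
    warning("SNR undefined: r_p + sd_b = 0")
    return(NA_real_)
  }
  (r_p - sd_b) / (r_p + sd_b)
}

#' Circular variance of direction tuning
#'
#' CV = | sum_d R_d exp(i 2 theta_d) / sum_d R_d |, the modulus of the
#' response-weighted doubled-angle phasor mean over motion directions.
#' With the doubled angle (the default) this measures axis tuning: a
#' single responsive direction gives 1, responses balanced over
#' directions whose doubled angles cancel give 0. `double_angle = FALSE`
#' gives the single-angle (direction rather than axis) variant.
#'
#' Negative responses (possible with noisy dF/F) are clamped to 0 so the
#' statistic stays in \[0, 1\]; callers keep the raw values.
#'
#' @param r_d Response per direction.
#' @param theta_d Direction angles.
#' @param unit `"degrees"` (default) or `"radians"`.
#' @param double_angle Use 2 theta_d (default) or theta_d.
#' @return CV in \[0, 1\], or `NA` (with a warning) when all responses are
#'   0 after clamping.
#' @export
circular_variance <- function(r_d, theta_d, unit = c("degrees", "radians"),
                              double_angle = TRUE) {
  unit <- match.arg(unit)
  stopifnot(length(r_d) == length(theta_d))
  r <- pmax(r_d, 0)
  if (sum(r) == 0) {
    warning("circular variance undefined: all responses are 0")
    return(NA_real_)
  }
  th <- if (unit == "degrees") theta_d * pi / 180 else theta_d
  k <- if (double_angle) 2 else 1
  Mod(sum(r * exp(1i * k * th)) / sum(r))
}

#' Preferred motion direction
#'
#' The direction with the largest mean response. Ties (within a relative
#' tolerance) are flagged ambiguous and resolved by the angle of the
#' response-weighted vector sum.
#'
#' @param r_d Response per direction.
#' @param theta_d Direction angles in degrees (at least 2).
#' @param tol Relative tolerance for calling a tie.
#' @return List with `angle` (degrees), `ambiguous` (logical) and
#'   `vector_sum_angle`.
#' @export
preferred_direction <- function(r_d, theta_d, tol = 1e-8) {
  stopifnot(length(r_d) == length(theta_d))
  if (length(theta_d) < 2L) stop_ss("need at least 2 directions")
  r <- pmax(r_d, 0)
  th <- theta_d * pi / 180
  z <- sum(r * exp(1i * th))
  vs <- (Arg(z) * 180 / pi) %% 360
  mx <- max(r_d)
  near <- which(r_d >= mx - tol * max(abs(mx), 1))
  ambiguous <- length(near) > 1L
  list(angle = if (ambiguous) vs else theta_d[which.max(r_d)],
       ambiguous = ambiguous, vector_sum_angle = vs)
}

#' Direction-selectivity statistics for one ROI
#'
#' Computes, from per-direction trial matrices, the per-direction mean
#' responses and the four summary statistics: response amplitude index
#' (RAI), trial-to-trial reliability, motion SNR and circular variance,
#' plus the preferred direction. Per direction, r_s is the peak dF/F0 of
#' the trial-averaged trace within the stimulus window and r_b the mean
#' over the baseline window; the tuning response R_d is r_s - r_b (set
#' `baseline_subtract = FALSE` to use r_s directly), clamped at 0 for the
#' circular statistics with raw values preserved in the output. RAI,
#' reliability and SNR are evaluated at the preferred direction, with the
#' reliability restricted to the stimulus window.
#'
#' @param trials Named list mapping direction (degrees) to
#'   [trial_matrix()] objects, e.g. from [simulate_direction_trials()].
#' @param baseline_subtract Subtract r_b from r_s before tuning analysis.
#' @param double_angle Passed to [circular_variance()].
#' @return Object of class `direction_tuning`: `directions`, `r_d` (raw),
#'   `r_d_clamped`, `r_s`, `r_b`, `rai`, `reliability`, `snr`, `cv`,
#'   `preferred` (list), `sd_b`.
#' @export
direction_tuning <- function(trials, baseline_subtract = TRUE,
                             double_angle = TRUE) {
  stopifnot(length(trials) >= 2L)
  dirs <- as.numeric(names(trials))
  if (anyNA(dirs)) stop_ss("`trials` must be named by direction in degrees")
  per_dir <- lapply(trials, function(tm) {
    stopifnot(inherits(tm, "trial_matrix"))
    avg <- rowMeans(tm$C)
    sw <- tm$stim_window %||% seq_len(nrow(tm$C))
    bw <- tm$baseline_window %||% integer(0)
    r_s <- max(avg[sw])
    r_b <- if (length(bw)) mean(avg[bw]) else 0
    sd_b <- if (length(bw) > 1L) stats::sd(avg[bw]) else NA_real_
    list(r_s = r_s, r_b = r_b, sd_b = sd_b)
  })
  r_s <- vapply(per_dir, `[[`, numeric(1), "r_s")
  r_b <- vapply(per_dir, `[[`, numeric(1), "r_b")
  r_d <- if (baseline_subtract) r_s - r_b else r_s
  r_cl <- pmax(r_d, 0)
  pref <- preferred_direction(r_d, dirs)
  pi_ <- if (pref$ambiguous) {
    which.min(abs((dirs - pref$angle + 180) %% 360 - 180))
  } else {
    which.max(r_d)
  }
  rel <- response_reliability(trials[[pi_]])
  structure(
    list(directions = dirs, r_d = unname(r_d), r_d_clamped = unname(r_cl),
         r_s = unname(r_s), r_b = unname(r_b),
         rai = response_amplitude_index(r_s[[pi_]], r_b[[pi_]]),
         reliability = rel,
         snr = motion_snr(r_cl[[pi_]], per_dir[[pi_]]$sd_b),
         cv = circular_variance(r_d, dirs, double_angle = double_angle),
         preferred = pref, sd_b = per_dir[[pi_]]$sd_b),
    class = "direction_tuning")
}

#' @export
print.direction_tuning <- function(x, ...) {
  cat(sprintf("direction tuning over %d directions\n", length(x$directions)))
  cat(sprintf("preferred %g deg%s | RAI %.3g | reliability %.3g | SNR %.3g | CV %.3g\n",
              x$preferred$angle, if (x$preferred$ambiguous) " (ambiguous)" else "",
              x$rai, x$reliability, x$snr, x$cv))
  invisible(x)
}
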