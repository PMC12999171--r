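#' Peak dF/F0 of an epoch trace
#'
#' Extremum of the 3-frame median-smoothed trace within the post-stimulus
#' window. The signed peak keeps the sensor polarity (negative for
#' negative-going sensors); the magnitude is its absolute value. With
#' `polarity = "auto"` the polarity is inferred from whichever extremum of
#' the smoothed trace is larger in magnitude.
#'
#' @param dff Numeric dF/F0 trace.
#' @param post_idx Integer indices of the post-stimulus window within
#'   `dff`.
#' @param polarity `"auto"`, `"positive"`/`1` or `"negative"`/`-1`.
#' @param smooth Odd median-filter width in frames (1 disables smoothing).
#' @return List with `signed`, `magnitude`, `index` (position of the peak
#'   in `dff`), `polarity` and `raw_signed` (peak of the unsmoothed trace).
#' @export
peak_response <- function(dff, post_idx, polarity = "auto", smooth = 3L) {
  if (any(post_idx < 1L) || any(post_idx > length(dff))) {
    stop_ss("`post_idx` lies outside the trace")
  }
  pol <- parse_polarity(polarity)
  sm <- if (smooth > 1L) stats::runmed(dff, smooth, endrule = "median") else dff
  seg <- sm[post_idx]
  if (is.na(pol)) pol <- if (max(seg) >= -min(seg)) 1 else -1
  i <- if (pol > 0) which.max(seg) else which.min(seg)
  idx <- post_idx[i]
  raw_seg <- dff[post_idx]
  raw <- if (pol > 0) max(raw_seg) else min(raw_seg)
  list(signed = seg[i], magnitude = abs(seg[i]), index = idx,
       polarity = pol, raw_signed = raw)
}

parse_polarity <- function(polarity) {
  if (is.character(polarity)) {
    switch(polarity,
           auto = NA_real_, positive = 1, negative = -1,
           stop_ss("`polarity` must be 'auto', 'positive' or 'negative'"))
  } else if (polarity %in% c(-1, 1)) {
    as.numeric(polarity)
  } else {
    stop_ss("`polarity` must be +1 or -1")
  }
}

#' Rise and decay time constants of an evoked transient
#'
#' Fits the rising phase with A (1 - exp(-(t - t0)/tau_on)) from the epoch
#' onset to the peak, and the decaying phase with
#' A exp(-(t - t_peak)/tau_off) from the peak to at most 1 s later
#' (avoiding the next epoch). Fits are nonlinear least squares with
#' log-linear initialization and time constants bounded to \[1 ms, 10 s\].
#' A phase with fewer than 4 samples or a non-converging fit is flagged
#' and reports no time constant.
#'
#' @param dff dF/F0 trace for one epoch.
#' @param frame_rate Sampling rate in Hz.
#' @param onset_index Index of the stimulus onset frame within `dff`.
#' @param polarity As in [peak_response()].
#' @param max_decay_s Decay-fit window cap in seconds past the peak.
#' @param tau_bounds Lower/upper bounds on both time constants (seconds).
#' @return List with `tau_on`, `tau_off` (NA when flagged), `amplitude`
#'   (signed), `polarity`, `peak_index`, `rise`/`decay` diagnostic lists
#'   (`ok`, `n_points`, `rmse`, `message`).
#' @export
fit_kinetics <- function(dff, frame_rate, onset_index, polarity = "auto",
                         max_decay_s = 1, tau_bounds = c(1e-3, 10)) {
  n <- length(dff)
  if (onset_index < 1L || onset_index > n) stop_ss("`onset_index` outside trace")
  pk <- peak_response(dff, post_idx = onset_index:n, polarity = polarity)
  pol <- pk$polarity
  y <- pol * dff
  t <- (seq_len(n) - 1) / frame_rate
  peak_i <- pk$index
  peak_y <- y[peak_i]

  flagged <- function(msg, np = 0L) list(ok = FALSE, n_points = np,
                                         rmse = NA_real_, message = msg)
  rise <- decay <- NULL
  tau_on <- tau_off <- NA_real_

  if (peak_y <= 0) {
    rise <- flagged("no positive-going peak after rectification")
    decay <- flagged("no positive-going peak after rectification")
  } else {
    # rising phase: onset..peak
    ri <- onset_index:peak_i
    if (length(ri) < 4L) {
      rise <- flagged("fewer than 4 samples in rising phase", length(ri))
    } else {
      tr <- t[ri] - t[onset_index]
      yr <- y[ri]
      fit <- tryCatch(
        minpack.lm::nlsLM(
          yr ~ A * (1 - exp(-tr / tau)),
          start = list(A = peak_y, tau = max(tr[length(tr)] / 3, tau_bounds[1])),
          lower = c(A = 0, tau = tau_bounds[1]),
          upper = c(A = Inf, tau = tau_bounds[2]),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) {
        rise <- flagged("rise fit did not converge", length(ri))
      } else {
        tau_on <- stats::coef(fit)[["tau"]]
        rise <- list(ok = TRUE, n_points = length(ri),
                     rmse = sqrt(mean(stats::resid(fit)^2)), message = "")
        if (tau_on >= tau_bounds[2] * (1 - 1e-6)) {
          rise$message <- "tau_on at upper bound"
        }
      }
    }
    # decaying phase: first frame after the peak .. min(peak + max_decay_s,
    # end). The peak sample itself straddles rise and decay at finite frame
    # rate and would bias the decay fit, so it anchors the window but is
    # excluded from it.
    di <- min(n, peak_i + 1L):min(n, peak_i + window_frames(max_decay_s, frame_rate))
    if (length(di) < 4L) {
      decay <- flagged("fewer than 4 samples in decaying phase", length(di))
    } else {
      td <- t[di] - t[peak_i]
      yd <- y[di]
      pos <- yd > 0
      k0 <- if (sum(pos) >= 2L) {
        sl <- stats::coef(stats::lm(log(yd[pos]) ~ td[pos]))[[2]]
        if (is.finite(sl) && sl < 0) -1 / sl else td[length(td)] / 3
      } else {
        td[length(td)] / 3
      }
      fit <- tryCatch(
        minpack.lm::nlsLM(
          yd ~ A * exp(-td / tau),
          start = list(A = peak_y,
                       tau = min(max(k0, tau_bounds[1]), tau_bounds[2])),
          lower = c(A = 0, tau = tau_bounds[1]),
          upper = c(A = Inf, tau = tau_bounds[2]),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) {
        decay <- flagged("decay fit did not converge", length(di))
      } else {
        tau_off <- stats::coef(fit)[["tau"]]
        decay <- list(ok = TRUE, n_points = length(di),
                      rmse = sqrt(mean(stats::resid(fit)^2)), message = "")
      }
    }
  }
  list(tau_on = tau_on, tau_off = tau_off,
       amplitude = pol * peak_y, polarity = pol, peak_index = peak_i,
       rise = rise, decay = decay)
}

#' Sensitivity index (d-prime) of an evoked response
#'
#' Standardized separation between the post- and pre-stimulus window
#' distributions of the trace:
#' (mean_post - mean_pre) / sqrt((var_pre + var_post) / 2), with the sign
#' rectified by the sensor polarity so an effective response is positive.
#'
#' @param x Numeric trace.
#' @param pre_idx,post_idx Window indices; each must span at least
#'   `min_frames` frames.
#' @param polarity `+1` or `-1`.
#' @param min_frames Minimum frames per window.
#' @return List with `d_prime` (Inf with `flag = "zero-variance"` when both
#'   windows are constant) and `flag`.
#' @export
d_prime <- function(x, pre_idx, post_idx, polarity = 1, min_frames = 5L) {
  if (length(pre_idx) < min_frames || length(post_idx) < min_frames) {
    stop_ss(sprintf("both windows must span at least %d frames", min_frames))
  }
  if (any(c(pre_idx, post_idx) < 1L) || any(c(pre_idx, post_idx) > length(x))) {
    stop_ss("window indices outside the trace")
  }
  pol <- parse_polarity(polarity)
  if (is.na(pol)) stop_ss("`polarity` must be +1 or -1 for d_prime")
  pre <- x[pre_idx]
  post <- x[post_idx]
  num <- pol * (mean(post) - mean(pre))
  pooled <- (stats::var(pre) + stats::var(post)) / 2
  if (pooled == 0) {
    d <- if (num == 0) 0 else Inf * sign(num)
    return(list(d_prime = d, flag = if (num == 0) "" else "zero-variance"))
  }
  list(d_prime = num / sqrt(pooled), flag = "")
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' Standard one-way analysis of variance across variant groups followed by
#' Tukey's honestly-significant-difference pairwise comparisons with
#' family-wise adjusted p-values.
#'
#' @param values Numeric metric values.
#' @param groups Group labels, same length as `values`; at least 2 groups
#'   with at least 2 values each.
#' @return List of class `group_comparison` with `f_statistic`, `p_value`,
#'   `df`, and `tukey` (data frame: `comparison`, `diff`, `lwr`, `upr`,
#'   `p_adj`).
#' @export
compare_groups <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop_ss("need at least 2 groups")
  if (any(table(groups) < 2L)) stop_ss("every group needs at least 2 values")
  d <- data.frame(value = as.numeric(values), group = groups)
  fit <- stats::aov(value ~ group, data = d)
  s <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  structure(
    list(f_statistic = s[["F value"]][1], p_value = s[["Pr(>F)"]][1],
         df = s[["Df"]],
         tukey = data.frame(comparison = rownames(tk),
                            diff = tk[, "diff"], lwr = tk[, "lwr"],
                            upr = tk[, "upr"], p_adj = tk[, "p adj"],
                            row.names = NULL)),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.3g, p = %.3g\n",
              x$df[1], x$df[2], x$f_statistic, x$p_value))
  print(x$tukey, ...)
  invisible(x)
}

#' Fold change and percent change between group means
#'
#' `ratio` is mean_a / mean_b (e.g. variant over reference). For "x% faster"
#' phrasing of time constants, `percent_change` is 100 (b - a) / b, the
#' percent reduction of `a` relative to `b`.
#'
#' @param mean_a,mean_b Group means; `mean_b` must be nonzero.
#' @return List with `ratio` and `percent_change` (in percent).
#' @examples
#' fold_change(0.77, 0.19)$ratio        # ~4.1-fold
#' fold_change(43, 61)$percent_change   # ~30% faster
#' @export
fold_change <- function(mean_a, mean_b) {
  if (mean_b == 0) stop_ss("`mean_b` must be nonzero")
  list(ratio = mean_a / mean_b,
       percent_change = 100 * (mean_b - mean_a) / mean_b)
}
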