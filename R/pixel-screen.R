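#' Photobleach correction by single-exponential fitting
#'
#' Fits F_b(t) = A exp(-t/tau) + C to the beginning and end of the
#' recording, avoiding all response windows, and divides the data by
#' F_b(t)/F_b(0) so the initial level is preserved while the bleaching
#' trend is flattened. If the exponential fit does not converge the
#' correction falls back to a linear detrend of the same segments and is
#' flagged.
#'
#' For a `well_movie` the exponential is fit to the spatial mean trace and
#' the same multiplicative correction is applied to every pixel (the
#' bleaching time constant is a property of the fluorophore and
#' illumination, shared across the well).
#'
#' @param x Numeric trace or a `well_movie`.
#' @param ... Passed to methods.
#' @return For traces, a list with `corrected`, `fit` (A, tau, C, `method`,
#'   `converged`) and `bleach_curve`. For movies, the corrected `well_movie`
#'   with the fit attached as `$bleach_fit`.
#' @export
correct_photobleach <- function(x, ...) UseMethod("correct_photobleach")

#' @rdname correct_photobleach
#' @param frame_rate Sampling rate in Hz.
#' @param response_windows List of `c(start, end)` times in seconds to
#'   exclude from the fit (see [response_windows()]).
#' @param min_segment Minimum seconds of usable data required before the
#'   first and after the last response window.
#' @export
correct_photobleach.default <- function(x, frame_rate, response_windows,
                                        min_segment = 1, ...) {
  trace <- as.numeric(x)
  n <- length(trace)
  t <- (seq_len(n) - 1) / frame_rate
  starts <- vapply(response_windows, `[`, numeric(1), 1L)
  ends <- vapply(response_windows, `[`, numeric(1), 2L)
  seg <- t < min(starts) | t > max(ends)
  head_s <- sum(t < min(starts)) / frame_rate
  tail_s <- sum(t > max(ends)) / frame_rate
  if (head_s < min_segment || tail_s < min_segment) {
    stop_ss(sprintf(
      "need >= %g s outside response windows at both ends (have %.2f s / %.2f s)",
      min_segment, head_s, tail_s))
  }
  ts <- t[seg]
  ys <- trace[seg]

  # With data only at the two ends of the recording the three-parameter
  # model is weakly conditioned, so initialize from the segment means
  # (two-point tau estimate) and minimize with Levenberg-Marquardt, which
  # tolerates the near-degenerate Jacobian.
  fit <- tryCatch({
    head_seg <- t < min(starts) & seg
    tail_seg <- t > max(ends) & seg
    m1 <- mean(trace[head_seg]); t1 <- mean(t[head_seg])
    m2 <- mean(trace[tail_seg]); t2 <- mean(t[tail_seg])
    tau0 <- if (m1 > 0 && m2 > 0 && m1 != m2 && sign(m1) == sign(m2)) {
      dt <- (t2 - t1) / log(m1 / m2)
      if (is.finite(dt) && dt > 0) dt else 2 * max(t)
    } else {
      2 * max(t)
    }
    a0 <- m1 / exp(-t1 / tau0)
    m <- minpack.lm::nls.lm(
      par = c(A = a0, tau = tau0, C = 0),
      fn = function(p) ys - (p[1] * exp(-ts / p[2]) + p[3]),
      lower = c(-Inf, 1e-6, -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    if (!m$info %in% 1:4) stop("nls.lm did not converge")
    p <- m$par
    list(A = p[[1]], tau = p[[2]], C = p[[3]],
         method = "exponential", converged = TRUE)
  }, error = function(e) NULL)

  if (is.null(fit)) {
    lf <- stats::lm(ys ~ ts)
    fit <- list(A = stats::coef(lf)[[2]], tau = NA_real_,
                C = stats::coef(lf)[[1]], method = "linear",
                converged = FALSE)
    bleach <- fit$C + fit$A * t
  } else {
    bleach <- fit$A * exp(-t / fit$tau) + fit$C
  }
  rel <- bleach / bleach[1]
  if (any(!is.finite(rel)) || any(rel <= 0)) {
    rel <- rep(1, n)  # refuse a correction that would invert or blow up
    fit$method <- "none"
    fit$converged <- FALSE
  }
  list(corrected = trace / rel, fit = fit, bleach_curve = bleach)
}

#' @rdname correct_photobleach
#' @param post_window,pad Seconds after each epoch onset treated as
#'   response window (`post_window + pad`) when `response_windows` is not
#'   given.
#' @export
correct_photobleach.well_movie <- function(x, response_windows = NULL,
                                           post_window = 0.4, pad = 2, ...) {
  response_windows <- response_windows %||%
    response_windows(x$epochs, post_window = post_window, pad = pad)
  d <- dim(x$pixels)
  px <- matrix(x$pixels, nrow = d[1] * d[2])
  mean_trace <- colMeans(px)
  res <- correct_photobleach(mean_trace, x$frame_rate, response_windows, ...)
  rel <- res$bleach_curve / res$bleach_curve[1]
  if (res$fit$method == "none") rel <- rep(1, d[3])
  x$pixels <- array(px / rep(rel, each = nrow(px)), dim = d)
  x$bleach_fit <- res$fit
  x
}

#' Response windows around stimulation epochs
#'
#' @param epochs Data frame with an `onset` column (seconds).
#' @param post_window Seconds of evoked response after onset.
#' @param pad Extra seconds to skip after the response before data are
#'   again considered baseline (decay tail).
#' @return List of `c(start, end)` windows in seconds.
#' @export
response_windows <- function(epochs, post_window = 0.4, pad = 2) {
  lapply(epochs$onset, function(o) c(o, o + post_window + pad))
}

#' Detect responsive pixels
#'
#' For every pixel and every stimulation epoch, compares the intensity
#' samples from the 1.5 s preceding the stimulus onset against the 0.4 s
#' following it with a two-sided Mann-Whitney U test. A pixel is
#' responsive when its p-value falls below `alpha` for any epoch; the
#' number of responsive pixels serves as a proxy for sensor expression.
#' The movie should be photobleach-corrected first
#' ([correct_photobleach()]).
#'
#' @param movie A `well_movie`.
#' @param pre_window Seconds before onset used as the baseline sample.
#' @param post_window Seconds from onset used as the response sample (the
#'   onset frame belongs to the post window).
#' @param alpha Per-test threshold; responsive means p < alpha (strict).
#' @return Object of class `responsive_pixel_result`: `p_values` (pixel x
#'   epoch matrix), `mask` (height x width logical), `n_responsive`,
#'   `fraction_responsive` and `alpha`.
#' @export
responsive_pixels <- function(movie, pre_window = 1.5, post_window = 0.4,
                              alpha = 0.01) {
  stopifnot(inherits(movie, "well_movie"))
  d <- dim(movie$pixels)
  n_t <- d[3]
  rate <- movie$frame_rate
  npre <- window_frames(pre_window, rate)
  npost <- window_frames(post_window, rate)
  if (npre < 1L || npost < 1L) stop_ss("windows are empty at this frame rate")
  ep <- movie$epochs
  for (i in seq_len(nrow(ep))) {
    first <- ep$onset_frame[i] - npre
    last <- ep$onset_frame[i] + npost - 1L
    if (first < 1L || last > n_t) {
      stop_ss(sprintf("windows of epoch %d (%g pulses) fall outside the recording",
                      i, ep$pulses[i]))
    }
    if (i > 1L && first <= ep$onset_frame[i - 1L] + npost - 1L) {
      stop_ss(sprintf("pre-window of epoch %d (%g pulses) overlaps the post-window of epoch %d (%g pulses)",
                      i, ep$pulses[i], i - 1L, ep$pulses[i - 1L]))
    }
  }
  px <- matrix(movie$pixels, nrow = d[1] * d[2])
  p <- vapply(seq_len(nrow(ep)), function(i) {
    pre_idx <- (ep$onset_frame[i] - npre):(ep$onset_frame[i] - 1L)
    post_idx <- ep$onset_frame[i]:(ep$onset_frame[i] + npost - 1L)
    mw_p_rows(px[, c(pre_idx, post_idx), drop = FALSE], npre)
  }, numeric(nrow(px)))
  p_min <- do.call(pmin, as.data.frame(p))
  mask <- matrix(p_min < alpha, d[1], d[2])
  structure(
    list(p_values = p, mask = mask, n_responsive = sum(mask),
         fraction_responsive = mean(mask), alpha = alpha),
    class = "responsive_pixel_result")
}

#' @export
print.responsive_pixel_result <- function(x, ...) {
  cat(sprintf("responsive pixels: %d (%.2f%%) at alpha = %g over %d epoch(s)\n",
              x$n_responsive, 100 * x$fraction_responsive, x$alpha,
              ncol(x$p_values)))
  invisible(x)
}

#' Pool the well response over responsive pixels
#'
#' Averages the (bleach-corrected) intensity over all responsive pixels and
#' converts the pooled trace to dF/F0 per stimulation epoch, with F0 the
#' mean over the pre-window of that epoch.
#'
#' @param movie Bleach-corrected `well_movie`.
#' @param mask Logical matrix of responsive pixels (e.g. from
#'   [responsive_pixels()]).
#' @param pre_window Seconds of baseline before each onset.
#' @param trace_window Seconds of trace kept after each onset.
#' @return Object of class `well_trace`: per-epoch list of `time` (seconds
#'   relative to onset), `dff`, `onset_index`, `pulses` and `f0`, plus the
#'   pooled raw trace. If the mask is empty the well is marked
#'   `no_response = TRUE` and no trace is emitted.
#' @export
pool_well_trace <- function(movie, mask, pre_window = 1.5, trace_window = 2.5) {
  stopifnot(inherits(movie, "well_movie"))
  d <- dim(movie$pixels)
  if (!is.logical(mask) || length(mask) != d[1] * d[2]) {
    stop_ss("`mask` must be a logical matrix matching the frame shape")
  }
  if (sum(mask) == 0L) {
    return(structure(list(no_response = TRUE, epochs = list()),
                     class = "well_trace"))
  }
  px <- matrix(movie$pixels, nrow = d[1] * d[2])
  pooled <- colMeans(px[as.vector(mask), , drop = FALSE])
  rate <- movie$frame_rate
  npre <- window_frames(pre_window, rate)
  ntr <- window_frames(trace_window, rate)
  eps <- lapply(seq_len(nrow(movie$epochs)), function(i) {
    onset <- movie$epochs$onset_frame[i]
    pre_idx <- max(1L, onset - npre):(onset - 1L)
    f0 <- mean(pooled[pre_idx])
    idx <- max(1L, onset - npre):min(length(pooled), onset + ntr - 1L)
    list(time = (idx - onset) / rate,
         dff = (pooled[idx] - f0) / f0,
         onset_index = which(idx == onset),
         pulses = movie$epochs$pulses[i],
         f0 = f0)
  })
  structure(
    list(no_response = FALSE, epochs = eps, pooled = pooled,
         frame_rate = rate, n_pixels = sum(mask)),
    class = "well_trace")
}
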