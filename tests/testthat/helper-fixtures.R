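# Shared fixtures: small, fast synthetic inputs built in code.

# Ground truth parameterized like the improved positive-going sensor.
gt_improved <- function(...) {
  variant_ground_truth("improved",
                       amplitude_by_pulses = c(`1` = 0.2, `10` = 0.77, `40` = 1.0),
                       tau_on = 0.043, tau_off = 0.073, ...)
}

# Ground truth like the first-generation reference sensor.
gt_reference <- function(...) {
  variant_ground_truth("control",
                       amplitude_by_pulses = c(`1` = 0.05, `10` = 0.19, `40` = 0.30),
                       tau_on = 0.061, tau_off = 0.062, ...)
}

# Null ground truth: no evoked signal at all.
gt_null <- function(...) {
  variant_ground_truth("null",
                       amplitude_by_pulses = c(`1` = 0, `10` = 0, `40` = 0),
                       ...)
}

# Small plate spec for fast movie tests.
small_spec <- function(frame = 16L, seed = 1L, ...) {
  plate_spec(frame_shape = c(frame, frame), seed = seed, ...)
}

noiseless <- function(spec) {
  spec$noise <- list(read_sd = 0, shot_sd = 0)
  spec$pixel_gain_sd <- 0
  spec
}

# Directly construct a pooled dF/F0 epoch trace from the transient kernel.
make_epoch_trace <- function(peak, tau_on, tau_off, rate = 200,
                             pre = 1.5, post = 2.5, noise_sd = 0,
                             polarity = 1, shape = "piecewise",
                             seed = NULL) {
  npre <- floor(pre * rate)
  npost <- floor(post * rate)
  t <- seq(-npre, npost - 1) / rate
  dff <- polarity * transient_kernel(t, peak, tau_on, tau_off, shape)
  if (noise_sd > 0) {
    add <- function() dff + rnorm(length(dff), 0, noise_sd)
    dff <- if (is.null(seed)) add() else withr_seed(seed, add())
  }
  list(dff = dff, onset_index = npre + 1L, rate = rate,
       pre_idx = seq_len(npre), post_idx = npre + seq_len(floor(0.4 * rate)))
}

tmp_file <- function(ext = "") tempfile(fileext = ext)

tmp_dir <- function() {
  d <- tempfile()
  dir.create(d)
  d
}

# Minimal local stand-in for deterministic seeding in helpers.
withr_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  force(code)
}

# Independent brute-force Mann-Whitney oracle: U by pairwise counting and
# the permutation null by enumerating value assignments (not rank sums).
mw_oracle_p <- function(a, b, alternative = "two.sided") {
  pooled <- c(a, b)
  n1 <- length(a)
  count_u <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- count_u(a, b)
  idx <- utils::combn(length(pooled), n1)
  us <- apply(idx, 2, function(i) count_u(pooled[i], pooled[-i]))
  eps <- 1e-9
  p_le <- mean(us <= u_obs + eps)
  p_ge <- mean(us >= u_obs - eps)
  switch(alternative,
         two.sided = min(1, 2 * min(p_le, p_ge)),
         greater = p_ge,
         less = p_le)
}

# Per-variant wells/epochs tables for rank-module tests (no movies).
make_screen_tables <- function(variant_peaks, control_peak = 0.19,
                               n_reps = 4L, n_ctrl = 8L, pixels = 400L,
                               control_pixels = 400L, jitter = 0,
                               seed = 1L) {
  withr_seed(seed, {
    rows <- list()
    eps <- list()
    add_well <- function(wid, vid, is_ctrl, peak, npx) {
      rows[[length(rows) + 1L]] <<- data.frame(
        plate_id = "P01", well_id = wid, variant_id = vid,
        is_control = is_ctrl, n_responsive = npx,
        fraction_responsive = npx / 1024, no_response = FALSE,
        polarity = sign(peak), f0 = 1000, bleach_tau = 60,
        bleach_method = "exponential", stringsAsFactors = FALSE)
      for (p in c(1, 10, 40)) {
        pk <- peak * c(`1` = 0.26, `10` = 1, `40` = 1.3)[[as.character(p)]] +
          if (jitter > 0) rnorm(1, 0, jitter) else 0
        eps[[length(eps) + 1L]] <<- data.frame(
          plate_id = "P01", well_id = wid, variant_id = vid,
          is_control = is_ctrl, pulses = p, peak_signed = pk,
          peak_abs = abs(pk), tau_on = 0.05, tau_off = 0.07,
          d_prime = 1.5, polarity = sign(peak), f0 = 1000,
          stringsAsFactors = FALSE)
      }
    }
    k <- 0L
    for (i in seq_len(n_ctrl)) {
      k <- k + 1L
      add_well(sprintf("W%02d", k), "control", TRUE, control_peak,
               control_pixels)
    }
    for (v in names(variant_peaks)) {
      for (r in seq_len(n_reps)) {
        k <- k + 1L
        add_well(sprintf("W%02d", k), v, FALSE, variant_peaks[[v]], pixels)
      }
    }
    list(wells = do.call(rbind, rows), epochs = do.call(rbind, eps))
  })
}
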