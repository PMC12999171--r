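#' Ground truth for one sensor variant
#'
#' Bundles the parameters from which synthetic well movies are generated:
#' response polarity, peak dF/F0 per pulse-count epoch, rise and decay time
#' constants, the fraction of pixels expressing the sensor, baseline
#' brightness and the photobleaching time constant.
#'
#' @param variant_id Character label.
#' @param polarity `+1` (fluorescence increases on release) or `-1`
#'   (negative-going sensor).
#' @param amplitude_by_pulses Named numeric vector mapping pulse count to
#'   peak |dF/F0|; non-negative and non-decreasing with pulse count.
#' @param tau_on,tau_off Rise and decay time constants in seconds (> 0).
#' @param expressing_fraction Fraction of pixels expressing the sensor, in
#'   \[0, 1\].
#' @param baseline_brightness Baseline fluorescence of expressing pixels, in
#'   camera counts.
#' @param bleach_tau Photobleaching time constant in seconds.
#' @return An object of class `variant_ground_truth`.
#' @examples
#' variant_ground_truth("ctrl", amplitude_by_pulses = c(`1` = 0.05, `10` = 0.19, `40` = 0.30))
#' @export
variant_ground_truth <- function(variant_id,
                                 polarity = 1,
                                 amplitude_by_pulses = c(`1` = 0.05, `10` = 0.19, `40` = 0.30),
                                 tau_on = 0.061,
                                 tau_off = 0.062,
                                 expressing_fraction = 0.3,
                                 baseline_brightness = 1000,
                                 bleach_tau = 60) {
  if (!polarity %in% c(-1, 1)) stop_ss("`polarity` must be +1 or -1")
  amp <- amplitude_by_pulses
  if (is.null(names(amp)) || anyNA(suppressWarnings(as.numeric(names(amp))))) {
    stop_ss("`amplitude_by_pulses` must be named by pulse count")
  }
  pulses <- as.numeric(names(amp))
  amp <- amp[order(pulses)]
  if (any(amp < 0)) stop_ss("amplitudes must be >= 0")
  if (is.unsorted(amp)) stop_ss("amplitudes must be non-decreasing with pulse count")
  if (tau_on <= 0 || tau_off <= 0) stop_ss("time constants must be > 0")
  if (expressing_fraction < 0 || expressing_fraction > 1) {
    stop_ss("`expressing_fraction` must lie in [0, 1]")
  }
  if (baseline_brightness <= 0) stop_ss("`baseline_brightness` must be > 0")
  if (bleach_tau <= 0) stop_ss("`bleach_tau` must be > 0")
  structure(
    list(variant_id = as.character(variant_id), polarity = polarity,
         amplitude_by_pulses = amp, tau_on = tau_on, tau_off = tau_off,
         expressing_fraction = expressing_fraction,
         baseline_brightness = baseline_brightness, bleach_tau = bleach_tau),
    class = "variant_ground_truth")
}

#' Default screen variant panel
#'
#' A deterministic panel of `n_variants` ground-truth variants spanning a
#' range of response amplitudes (0.5-2x the reference), expression levels
#' and both polarities, used to populate a default plate.
#'
#' @param n_variants Number of variants (default 18, matching an 80-well
#'   plate layout of 8 controls + 18 variants x 4 replicates).
#' @return List of [variant_ground_truth()] objects.
#' @export
default_screen_variants <- function(n_variants = 18) {
  mult <- rep(c(0.5, 0.8, 1, 1.2, 1.5, 2), length.out = n_variants)
  expr <- rep(c(0.2, 0.3, 0.4), length.out = n_variants)
  pol <- rep(c(1, 1, 1, 1, 1, -1), length.out = n_variants)
  lapply(seq_len(n_variants), function(i) {
    variant_ground_truth(
      variant_id = sprintf("V%02d", i),
      polarity = pol[i],
      amplitude_by_pulses = c(`1` = 0.05, `10` = 0.19, `40` = 0.30) * mult[i],
      expressing_fraction = expr[i])
  })
}

#' Specification of a synthetic screening plate
#'
#' Describes the acquisition and layout conditions of one 96-well screening
#' plate: by default 8 control wells plus 18 variants at 4 replicate wells
#' each (80 populated wells; the first and last plate columns are left
#' empty), movies of 256 x 256 pixels at 50 Hz, and three stimulation
#' epochs of 1, 10 and 40 pulses delivered at 83 Hz.
#'
#' @param control VariantGroundTruth used for the in-plate control wells.
#' @param variants List of [variant_ground_truth()] objects, or a list of
#'   `list(gt = , n_replicates = )` pairs.
#' @param n_control_wells Number of control replicate wells (default 8).
#' @param n_replicates Replicate wells per variant when `variants` is a
#'   plain list of ground truths (default 4).
#' @param frame_shape Movie height and width in pixels.
#' @param frame_rate Acquisition rate in Hz (> 0).
#' @param duration Recording duration in seconds.
#' @param pulse_epochs Data frame with columns `pulses` and `onset` (s).
#' @param pulse_hz Within-epoch pulse delivery rate (Hz).
#' @param noise List with `read_sd` and `shot_sd`: additive Gaussian noise
#'   with SD = read_sd + shot_sd * sqrt(F) in counts.
#' @param background_frac Brightness of non-expressing pixels as a fraction
#'   of the control baseline.
#' @param pixel_gain_sd SD of the log-normal pixel-to-pixel brightness
#'   variation among expressing pixels (0 disables it).
#' @param seed Integer seed from which per-well seeds are derived.
#' @return An object of class `plate_spec`.
#' @export
plate_spec <- function(control = variant_ground_truth("control"),
                       variants = default_screen_variants(),
                       n_control_wells = 8L,
                       n_replicates = 4L,
                       frame_shape = c(256L, 256L),
                       frame_rate = 50,
                       duration = 14,
                       pulse_epochs = data.frame(pulses = c(1, 10, 40),
                                                 onset = c(2, 6, 10)),
                       pulse_hz = pulse_rate(0.012),
                       noise = list(read_sd = 2, shot_sd = 1),
                       background_frac = 0.1,
                       pixel_gain_sd = 0.2,
                       seed = 1L) {
  if (!is.numeric(frame_rate) || frame_rate <= 0) {
    stop_ss("invalid plate spec: `frame_rate` must be > 0")
  }
  if (is.null(pulse_epochs) || nrow(pulse_epochs) == 0L) {
    stop_ss("invalid plate spec: `pulse_epochs` must contain at least one epoch")
  }
  if (!all(c("pulses", "onset") %in% names(pulse_epochs))) {
    stop_ss("`pulse_epochs` needs columns `pulses` and `onset`")
  }
  if (is.unsorted(pulse_epochs$onset, strictly = TRUE)) {
    stop_ss("epoch onsets must be strictly increasing")
  }
  if (duration <= max(pulse_epochs$onset)) {
    stop_ss("`duration` must extend past the last epoch onset")
  }
  variants <- lapply(variants, function(v) {
    if (inherits(v, "variant_ground_truth")) {
      list(gt = v, n_replicates = as.integer(n_replicates))
    } else {
      stopifnot(inherits(v$gt, "variant_ground_truth"))
      list(gt = v$gt, n_replicates = as.integer(v$n_replicates %||% n_replicates))
    }
  })
  structure(
    list(control = control, variants = variants,
         n_control_wells = as.integer(n_control_wells),
         frame_shape = as.integer(frame_shape), frame_rate = frame_rate,
         duration = duration, pulse_epochs = pulse_epochs,
         pulse_hz = pulse_hz, noise = noise,
         background_frac = background_frac, pixel_gain_sd = pixel_gain_sd,
         seed = as.integer(seed)),
    class = "plate_spec")
}

#' Evoked-transient kernel
#'
#' Shape of the pooled fluorescence transient for one stimulation epoch,
#' normalized so that its maximum equals `peak`. The default `"piecewise"`
#' kernel rises as 1 - exp(-t/tau_on) until 3 tau_on (95% saturation) and
#' then decays as exp(-(t - t_peak)/tau_off); this makes the rising and
#' decaying phases exactly the exponential models that the kinetics fits
#' assume, so generator and analyzer close on each other. The alternative
#' `"dexp"` kernel is the classic difference-of-exponentials
#' (1 - exp(-t/tau_on)) * exp(-t/tau_off), under which a rise-only fit is
#' systematically biased.
#'
#' @param t Time since epoch onset in seconds (values < 0 give 0).
#' @param peak Kernel maximum (|dF/F0| at the transient peak).
#' @param tau_on,tau_off Time constants in seconds.
#' @param shape `"piecewise"` or `"dexp"`.
#' @return Numeric vector, the kernel evaluated at `t`.
#' @export
transient_kernel <- function(t, peak, tau_on, tau_off,
                             shape = c("piecewise", "dexp")) {
  shape <- match.arg(shape)
  out <- numeric(length(t))
  pos <- t >= 0
  tp <- t[pos]
  if (shape == "piecewise") {
    t_peak <- 3 * tau_on
    rise <- (1 - exp(-tp / tau_on)) / (1 - exp(-3))
    out[pos] <- peak * ifelse(tp <= t_peak, rise, exp(-(tp - t_peak) / tau_off))
  } else {
    t_star <- tau_on * log(1 + tau_off / tau_on)
    a_max <- (1 - exp(-t_star / tau_on)) * exp(-t_star / tau_off)
    out[pos] <- peak * (1 - exp(-tp / tau_on)) * exp(-tp / tau_off) / a_max
  }
  out
}

#' Simulate one well movie
#'
#' Generates a fluorescence image stack for one well. Expressing pixels
#' follow baseline x exp(-t/bleach_tau) x (1 + polarity * a(t)), where a(t)
#' sums the [transient_kernel()] of every stimulation epoch; non-expressing
#' pixels sit at a constant background offset. Signal-dependent Gaussian
#' noise (SD = read_sd + shot_sd * sqrt(F)) is added throughout. The
#' generating ground truth travels with the movie for closed-loop tests.
#'
#' @param gt A [variant_ground_truth()]. Epochs whose pulse count is missing
#'   from `amplitude_by_pulses` are interpolated between the nearest counts.
#' @param spec A [plate_spec()].
#' @param well_seed Integer seed; identical seeds give bit-identical movies.
#' @param well_id,plate_id Labels carried into the movie metadata.
#' @param kernel_shape Passed to [transient_kernel()].
#' @return An object of class `well_movie`: list with `pixels`
#'   (height x width x frames array, counts), `frame_rate`, `epochs`
#'   (data frame with `pulses`, `onset`, `onset_frame`), ids,
#'   `expressing_mask` and `ground_truth`.
#' @export
simulate_well <- function(gt, spec, well_seed,
                          well_id = "W01", plate_id = "P01",
                          kernel_shape = c("piecewise", "dexp")) {
  stopifnot(inherits(gt, "variant_ground_truth"), inherits(spec, "plate_spec"))
  kernel_shape <- match.arg(kernel_shape)
  h <- spec$frame_shape[1]
  w <- spec$frame_shape[2]
  n_px <- h * w
  n_t <- window_frames(spec$duration, spec$frame_rate)
  t <- (seq_len(n_t) - 1) / spec$frame_rate

  amp_known <- gt$amplitude_by_pulses
  amp_for <- function(pulses) {
    stats::approx(as.numeric(names(amp_known)), amp_known, xout = pulses,
                  rule = 2)$y
  }
  a_t <- numeric(n_t)
  for (i in seq_len(nrow(spec$pulse_epochs))) {
    ep <- spec$pulse_epochs[i, ]
    a_t <- a_t + transient_kernel(t - ep$onset, amp_for(ep$pulses),
                                  gt$tau_on, gt$tau_off, kernel_shape)
  }
  bleach <- exp(-t / gt$bleach_tau)
  signal <- gt$baseline_brightness * bleach * (1 + gt$polarity * a_t)
  # background autofluorescence bleaches with the same time constant
  background <- spec$background_frac * gt$baseline_brightness * bleach

  with_seed(well_seed, {
    n_expr <- round(gt$expressing_fraction * n_px)
    expr_idx <- sample.int(n_px, n_expr)
    gains <- if (spec$pixel_gain_sd > 0 && n_expr > 0) {
      exp(stats::rnorm(n_expr, -spec$pixel_gain_sd^2 / 2, spec$pixel_gain_sd))
    } else {
      rep(1, n_expr)
    }
    mean_f <- matrix(background, nrow = n_px, ncol = n_t, byrow = TRUE)
    if (n_expr > 0) mean_f[expr_idx, ] <- outer(gains, signal)
    read_sd <- spec$noise$read_sd %||% 0
    shot_sd <- spec$noise$shot_sd %||% 0
    if (read_sd < 0 || shot_sd < 0) stop_ss("noise SDs must be >= 0")
    px <- if (read_sd > 0 || shot_sd > 0) {
      mean_f + stats::rnorm(length(mean_f)) * (read_sd + shot_sd * sqrt(mean_f))
    } else {
      mean_f
    }
    mask <- logical(n_px)
    mask[expr_idx] <- TRUE
    structure(
      list(pixels = array(px, dim = c(h, w, n_t)),
           frame_rate = spec$frame_rate,
           epochs = data.frame(
             pulses = spec$pulse_epochs$pulses,
             onset = spec$pulse_epochs$onset,
             onset_frame = window_frames(spec$pulse_epochs$onset,
                                         spec$frame_rate) + 1L),
           well_id = well_id, plate_id = plate_id,
           variant_id = gt$variant_id,
           expressing_mask = matrix(mask, h, w),
           ground_truth = gt),
      class = "well_movie")
  })
}

#' @export
print.well_movie <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("well_movie %s/%s (%s): %dx%d px, %d frames @ %g Hz, %d epochs\n",
              x$plate_id, x$well_id, x$variant_id, d[1], d[2], d[3],
              x$frame_rate, nrow(x$epochs)))
  invisible(x)
}

#' Simulate an equilibrium titration series
#'
#' Draws fluorescence readings from a Hill curve
#' F = fmin + (fmax - fmin) c^n / (EC50^n + c^n) with additive Gaussian
#' noise. The generating parameters are attached as `ground_truth`.
#'
#' @param ec50 Half-maximal concentration (> 0), same units as
#'   `concentrations`.
#' @param hill_n Hill coefficient.
#' @param fmin,fmax Fluorescence at zero and saturating ligand.
#' @param concentrations Non-negative ligand concentrations.
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param seed Optional integer seed.
#' @param n_replicates Independent readings per concentration.
#' @return Object of class `titration_series`: data-frame-like list with
#'   `concentration` and `response`.
#' @export
simulate_titration <- function(ec50, hill_n = 1, fmin = 1, fmax = 2,
                               concentrations, noise_sd = 0, seed = NULL,
                               n_replicates = 1L) {
  if (ec50 <= 0) stop_ss("`ec50` must be > 0")
  if (any(concentrations < 0)) stop_ss("concentrations must be >= 0")
  if (noise_sd < 0) stop_ss("`noise_sd` must be >= 0")
  conc <- rep(sort(concentrations), each = n_replicates)
  mu <- hill_curve(conc, ec50, hill_n, fmin, fmax)
  draw <- function() mu + if (noise_sd > 0) stats::rnorm(length(mu), 0, noise_sd) else 0
  resp <- if (is.null(seed)) draw() else with_seed(seed, draw())
  titration_series(conc, resp,
                   ground_truth = list(ec50 = ec50, hill_n = hill_n,
                                       fmin = fmin, fmax = fmax))
}

#' Hill curve
#'
#' @param conc Concentrations (>= 0).
#' @param ec50 Half-maximal concentration.
#' @param hill_n Hill coefficient.
#' @param fmin,fmax Asymptotes at zero and saturating ligand.
#' @return Fluorescence values.
#' @export
hill_curve <- function(conc, ec50, hill_n, fmin, fmax) {
  fmin + (fmax - fmin) * conc^hill_n / (ec50^hill_n + conc^hill_n)
}

#' Construct a titration series
#'
#' @param concentration,response Equal-length numeric vectors.
#' @param ground_truth Optional list of generating parameters.
#' @return Object of class `titration_series`.
#' @export
titration_series <- function(concentration, response, ground_truth = NULL) {
  stopifnot(length(concentration) == length(response))
  if (any(concentration < 0)) stop_ss("concentrations must be >= 0")
  ord <- order(concentration)
  structure(
    list(concentration = concentration[ord], response = response[ord],
         ground_truth = ground_truth),
    class = "titration_series")
}

#' Simulate a stopped-flow kinetic trace
#'
#' Monoexponential relaxation F(t) = f_inf + (f0 - f_inf) exp(-k_obs t)
#' after a concentration step, plus optional Gaussian noise. A biphasic
#' option splits the amplitude over two rate constants, emulating sensors
#' whose fluorescence change has a fast and a slow component.
#'
#' @param k_obs Observed rate constant in 1/s (> 0).
#' @param f0,f_inf Initial and asymptotic fluorescence.
#' @param duration Trace duration in seconds (> 0).
#' @param rate Sampling rate in Hz.
#' @param noise_sd Gaussian noise SD.
#' @param seed Optional integer seed.
#' @param biphasic Optional `list(fraction = , k2 = )`: `fraction` of the
#'   amplitude relaxes at `k_obs`, the rest at `k2`.
#' @return Object of class `kinetic_trace` with `time`, `fluorescence` and
#'   `ground_truth`.
#' @export
simulate_stopped_flow <- function(k_obs, f0 = 1, f_inf = 2, duration = 0.5,
                                  rate = 1000, noise_sd = 0, seed = NULL,
                                  biphasic = NULL) {
  if (k_obs <= 0) stop_ss("`k_obs` must be > 0")
  if (duration <= 0) stop_ss("`duration` must be > 0")
  if (noise_sd < 0) stop_ss("`noise_sd` must be >= 0")
  t <- seq(0, duration, by = 1 / rate)
  amp <- f0 - f_inf
  mu <- if (is.null(biphasic)) {
    f_inf + amp * exp(-k_obs * t)
  } else {
    f_inf + amp * (biphasic$fraction * exp(-k_obs * t) +
                     (1 - biphasic$fraction) * exp(-biphasic$k2 * t))
  }
  draw <- function() mu + if (noise_sd > 0) stats::rnorm(length(mu), 0, noise_sd) else 0
  fl <- if (is.null(seed)) draw() else with_seed(seed, draw())
  structure(
    list(time = t, fluorescence = fl,
         ground_truth = list(k_obs = k_obs, f0 = f0, f_inf = f_inf,
                             biphasic = biphasic)),
    class = "kinetic_trace")
}

#' Simulate direction-tuned trial matrices
#'
#' Generates, for each motion direction, a time x trial matrix of dF/F
#' traces made of a baseline period followed by a stimulus period whose
#' response amplitude depends on direction (a half-sine envelope peaking at
#' the per-direction tuning value), plus i.i.d. Gaussian noise.
#'
#' @param directions Motion directions in degrees (at least 2).
#' @param tuning Mean peak response per direction (same length).
#' @param n_trials Trials per direction (>= 1).
#' @param trace_noise_sd I.i.d. noise SD added to every sample.
#' @param frame_rate Sampling rate in Hz.
#' @param baseline_s,stim_s Baseline and stimulus durations in seconds.
#' @param seed Optional integer seed.
#' @return Named list (one [trial_matrix()] per direction) with the
#'   generating tuning attached as attribute `ground_truth`.
#' @export
simulate_direction_trials <- function(directions = seq(0, 315, by = 45),
                                      tuning = NULL,
                                      n_trials = 5L, trace_noise_sd = 0,
                                      frame_rate = 10, baseline_s = 1,
                                      stim_s = 2, seed = NULL) {
  if (length(directions) < 2L) stop_ss("need at least 2 directions")
  if (n_trials < 1L) stop_ss("`n_trials` must be >= 1")
  tuning <- tuning %||% vonmises_tuning(directions)
  stopifnot(length(tuning) == length(directions))
  nb <- window_frames(baseline_s, frame_rate)
  ns <- window_frames(stim_s, frame_rate)
  envelope <- sin(pi * seq_len(ns) / (ns + 1))
  envelope <- envelope / max(envelope)
  make <- function() {
    out <- lapply(seq_along(directions), function(d) {
      mu <- c(rep(0, nb), tuning[d] * envelope)
      noise <- if (trace_noise_sd > 0) {
        matrix(stats::rnorm(length(mu) * n_trials, 0, trace_noise_sd),
               nrow = length(mu))
      } else {
        0
      }
      trial_matrix(matrix(mu, nrow = length(mu), ncol = n_trials) + noise,
                   frame_rate = frame_rate,
                   baseline_window = seq_len(nb),
                   stim_window = nb + seq_len(ns))
    })
    names(out) <- as.character(directions)
    attr(out, "ground_truth") <- list(directions = directions, tuning = tuning)
    out
  }
  if (is.null(seed)) make() else with_seed(seed, make())
}

#' Von Mises direction tuning profile
#'
#' @param directions Directions in degrees.
#' @param preferred Preferred direction in degrees.
#' @param kappa Concentration (larger = sharper tuning).
#' @param amplitude Peak response at the preferred direction.
#' @return Mean response per direction.
#' @export
vonmises_tuning <- function(directions, preferred = 90, kappa = 2,
                            amplitude = 1) {
  th <- (directions - preferred) * pi / 180
  amplitude * exp(kappa * (cos(th) - 1))
}

#' Construct a trial matrix
#'
#' @param C Numeric matrix, time points x trials, of dF/F values.
#' @param frame_rate Sampling rate in Hz.
#' @param baseline_window,stim_window Integer frame indices of the baseline
#'   and stimulus periods (within the trace).
#' @return Object of class `trial_matrix`.
#' @export
trial_matrix <- function(C, frame_rate = NULL,
                         baseline_window = NULL, stim_window = NULL) {
  C <- as.matrix(C)
  win_ok <- function(w) is.null(w) || (all(w >= 1) && all(w <= nrow(C)))
  if (!win_ok(baseline_window) || !win_ok(stim_window)) {
    stop_ss("windows must lie within the trace")
  }
  structure(
    list(C = C, frame_rate = frame_rate,
         baseline_window = baseline_window, stim_window = stim_window),
    class = "trial_matrix")
}
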