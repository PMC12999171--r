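# Per-well analysis pipeline: bleach correction -> responsive pixels ->
# pooled trace -> scalar metrics. Produces the tables consumed by the
# plate-level QC/ranking functions.

#' Default analysis parameters for the field-stimulation screen
#'
#' The thresholds of the screening protocol: 1.5 s pre / 0.4 s post
#' Mann-Whitney windows, per-pixel alpha 0.01, wells with fewer than 4
#' responsive pixels discarded, variants with fewer than 3 surviving
#' replicates retested, variants with fewer than 1800 responsive pixels
#' per plate eliminated, selection test alpha 0.05, ranking at the
#' 40-pulse epoch. Every value is overridable.
#'
#' @param ... Overrides of the defaults.
#' @return Named list of parameters.
#' @export
screen_params <- function(...) {
  p <- list(pre_window = 1.5, post_window = 0.4, alpha = 0.01,
            trace_window = 2.5, min_responsive = 4L, min_replicates = 3L,
            min_pixels_per_plate = 1800, selection_alpha = 0.05,
            ranking_pulses = 40, bleach_pad = 2)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) {
    stop_ss("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  p[names(dots)] <- dots
  p
}

#' Analyze a single well movie
#'
#' Runs the full per-well pipeline: photobleach correction on the spatial
#' mean trace, per-pixel Mann-Whitney responsive-pixel detection, pooling
#' of the dF/F0 trace over responsive pixels, and per-epoch peak,
#' kinetics and d-prime metrics.
#'
#' @param movie A `well_movie`.
#' @param params A [screen_params()] list.
#' @param is_control Is this an in-plate control well?
#' @return List with `well` (one-row data frame of well-level results) and
#'   `epochs` (per-epoch metric rows), plus the intermediate `pixels`
#'   ([responsive_pixels()] result) and `trace` ([pool_well_trace()]).
#' @export
analyze_well <- function(movie, params = screen_params(), is_control = FALSE) {
  stopifnot(inherits(movie, "well_movie"))
  corrected <- correct_photobleach(movie, post_window = params$post_window,
                                   pad = params$bleach_pad)
  rp <- responsive_pixels(corrected, pre_window = params$pre_window,
                          post_window = params$post_window,
                          alpha = params$alpha)
  tr <- pool_well_trace(corrected, rp$mask, pre_window = params$pre_window,
                        trace_window = params$trace_window)
  rate <- movie$frame_rate
  npost <- window_frames(params$post_window, rate)

  if (tr$no_response) {
    epochs <- data.frame()
    polarity <- NA_real_
    f0 <- NA_real_
  } else {
    rows <- lapply(tr$epochs, function(ep) {
      post_idx <- ep$onset_index:min(length(ep$dff), ep$onset_index + npost - 1L)
      pk <- peak_response(ep$dff, post_idx = post_idx, polarity = "auto")
      kin <- fit_kinetics(ep$dff, rate, ep$onset_index,
                          polarity = pk$polarity)
      pre_idx <- 1:(ep$onset_index - 1L)
      dp <- d_prime(ep$dff, pre_idx, post_idx, polarity = pk$polarity)
      data.frame(pulses = ep$pulses, peak_signed = pk$signed,
                 peak_abs = pk$magnitude, tau_on = kin$tau_on,
                 tau_off = kin$tau_off, d_prime = dp$d_prime,
                 polarity = pk$polarity, f0 = ep$f0)
    })
    epochs <- do.call(rbind, rows)
    # well polarity: from the strongest epoch (consistent across epochs of
    # one sensor; noise can flip near-zero epochs)
    polarity <- epochs$polarity[which.max(epochs$peak_abs)]
    f0 <- mean(epochs$f0)
  }
  well <- data.frame(
    plate_id = movie$plate_id, well_id = movie$well_id,
    variant_id = movie$variant_id, is_control = is_control,
    n_responsive = rp$n_responsive,
    fraction_responsive = rp$fraction_responsive,
    no_response = tr$no_response, polarity = polarity, f0 = f0,
    bleach_tau = corrected$bleach_fit$tau %||% NA_real_,
    bleach_method = corrected$bleach_fit$method,
    stringsAsFactors = FALSE)
  if (nrow(epochs)) {
    epochs <- cbind(data.frame(plate_id = movie$plate_id,
                               well_id = movie$well_id,
                               variant_id = movie$variant_id,
                               is_control = is_control,
                               stringsAsFactors = FALSE),
                    epochs)
  }
  list(well = well, epochs = epochs, pixels = rp, trace = tr)
}

#' Analyze a list of well movies
#'
#' @param movies List of `well_movie` objects.
#' @param params A [screen_params()] list.
#' @param control_variant Variant id of the in-plate control wells.
#' @return List with stacked `wells` and `epochs` data frames.
#' @export
analyze_wells <- function(movies, params = screen_params(),
                          control_variant = "control") {
  res <- lapply(movies, function(m) {
    analyze_well(m, params, is_control = identical(m$variant_id,
                                                   control_variant))
  })
  list(wells = do.call(rbind, lapply(res, `[[`, "well")),
       epochs = do.call(rbind, lapply(res, function(r) {
         if (nrow(r$epochs)) r$epochs else NULL
       })))
}
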