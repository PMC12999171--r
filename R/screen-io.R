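# Plate-directory I/O: multi-page TIFF well movies with CSV layout and
# JSON ground-truth/config sidecars, plus the end-to-end simulate/analyze
# entry points.

TIFF_SCALE <- 65535  # counts are stored as 16-bit intensities / TIFF_SCALE

#' Plate layout for a plate specification
#'
#' Populated wells occupy rows A-H of columns 2-11 (the first and last
#' columns of the 96-well plate are left empty). Control wells fill
#' column 2; variants follow column-major, `n_replicates` consecutive
#' wells each.
#'
#' @param spec A [plate_spec()].
#' @return Data frame: `well_id`, `row`, `col`, `variant_id`,
#'   `is_control`, `well_seed`.
#' @export
plate_layout <- function(spec) {
  stopifnot(inherits(spec, "plate_spec"))
  ids <- c(rep(spec$control$variant_id, spec$n_control_wells),
           unlist(lapply(spec$variants, function(v) {
             rep(v$gt$variant_id, v$n_replicates)
           })))
  n <- length(ids)
  rows <- LETTERS[1:8]
  cols <- 2:11
  if (n > length(rows) * length(cols)) {
    stop_ss(sprintf("layout needs %d wells but only %d positions are usable",
                    n, length(rows) * length(cols)))
  }
  pos <- expand.grid(row = rows, col = cols, stringsAsFactors = FALSE)[seq_len(n), ]
  data.frame(
    well_id = sprintf("%s%02d", pos$row, pos$col),
    row = pos$row, col = pos$col,
    variant_id = ids,
    is_control = ids == spec$control$variant_id,
    well_seed = derive_seeds(spec$seed, n),
    stringsAsFactors = FALSE)
}

ground_truth_list <- function(spec) {
  gts <- c(list(spec$control), lapply(spec$variants, `[[`, "gt"))
  stats::setNames(lapply(gts, function(g) {
    list(variant_id = g$variant_id, polarity = g$polarity,
         amplitude_by_pulses = as.list(g$amplitude_by_pulses),
         tau_on = g$tau_on, tau_off = g$tau_off,
         expressing_fraction = g$expressing_fraction,
         baseline_brightness = g$baseline_brightness,
         bleach_tau = g$bleach_tau)
  }), vapply(gts, `[[`, character(1), "variant_id"))
}

#' Write a well movie as a multi-page TIFF
#'
#' Frames are stored as 16-bit pages; counts are divided by 65535 on
#' write and multiplied back on read, so intensities round-trip to within
#' half a count.
#'
#' @param movie A `well_movie`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_well_tiff <- function(movie, path) {
  d <- dim(movie$pixels)
  pages <- lapply(seq_len(d[3]), function(k) {
    pmin(pmax(movie$pixels[, , k] / TIFF_SCALE, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a well movie from a multi-page TIFF
#'
#' @param path TIFF written by [write_well_tiff()].
#' @param frame_rate Acquisition rate in Hz.
#' @param epochs Data frame with `pulses` and `onset` (seconds).
#' @param well_id,plate_id,variant_id Metadata labels.
#' @return A `well_movie`.
#' @export
read_well_tiff <- function(path, frame_rate, epochs,
                           well_id = "W01", plate_id = "P01",
                           variant_id = NA_character_) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  px <- array(unlist(pages, use.names = FALSE) * TIFF_SCALE,
              dim = c(d[1], d[2], length(pages)))
  structure(
    list(pixels = px, frame_rate = frame_rate,
         epochs = data.frame(
           pulses = epochs$pulses, onset = epochs$onset,
           onset_frame = window_frames(epochs$onset, frame_rate) + 1L),
         well_id = well_id, plate_id = plate_id, variant_id = variant_id,
         expressing_mask = NULL, ground_truth = NULL),
    class = "well_movie")
}

#' Simulate a complete screening plate to disk
#'
#' Writes one synthetic plate: a multi-page TIFF per well under `wells/`,
#' the plate layout as CSV, the generating ground truth as a JSON
#' sidecar, and the resolved configuration (acquisition parameters,
#' stimulus protocol, seed) as JSON. Deterministic for a given spec seed.
#'
#' @param spec A [plate_spec()].
#' @param out_dir Output directory (created; must be empty or absent
#'   unless `overwrite`).
#' @param plate_id Plate label.
#' @param overwrite Allow writing into an existing directory.
#' @return The layout data frame, invisibly.
#' @export
simulate_screen <- function(spec, out_dir, plate_id = "P01",
                            overwrite = FALSE) {
  stopifnot(inherits(spec, "plate_spec"))
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !overwrite) {
    stop_ss("`out_dir` exists and is not empty; use overwrite = TRUE")
  }
  dir.create(file.path(out_dir, "wells"), recursive = TRUE,
             showWarnings = FALSE)
  layout <- plate_layout(spec)
  gts <- ground_truth_list(spec)
  for (i in seq_len(nrow(layout))) {
    gt_fields <- gts[[layout$variant_id[i]]]
    gt <- variant_ground_truth(
      variant_id = gt_fields$variant_id, polarity = gt_fields$polarity,
      amplitude_by_pulses = unlist(gt_fields$amplitude_by_pulses),
      tau_on = gt_fields$tau_on, tau_off = gt_fields$tau_off,
      expressing_fraction = gt_fields$expressing_fraction,
      baseline_brightness = gt_fields$baseline_brightness,
      bleach_tau = gt_fields$bleach_tau)
    movie <- simulate_well(gt, spec, layout$well_seed[i],
                           well_id = layout$well_id[i], plate_id = plate_id)
    write_well_tiff(movie, file.path(out_dir, "wells",
                                     paste0(layout$well_id[i], ".tif")))
  }
  utils::write.csv(layout, file.path(out_dir, "layout.csv"),
                   row.names = FALSE)
  jsonlite::write_json(gts, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  config <- list(plate_id = plate_id, frame_shape = spec$frame_shape,
                 frame_rate = spec$frame_rate, duration = spec$duration,
                 pulse_epochs = spec$pulse_epochs, pulse_hz = spec$pulse_hz,
                 noise = spec$noise, background_frac = spec$background_frac,
                 pixel_gain_sd = spec$pixel_gain_sd, seed = spec$seed,
                 control_variant = spec$control$variant_id,
                 tiff_scale = TIFF_SCALE)
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(layout)
}

#' Analyze a plate directory or in-memory movie list
#'
#' Chains the per-well pipeline (photobleach correction, responsive-pixel
#' detection, pooled dF/F0 metrics) with plate-level QC, in-plate control
#' normalization, responsive-pixel elimination and joint winner
#' selection. For a plate directory, per-well metrics, the variant
#' summary, a JSON screen report and a log of every QC decision are
#' written next to the inputs (or to `out_dir`). A well whose TIFF cannot
#' be read is flagged and the run continues.
#'
#' @param plate Either a plate directory written by [simulate_screen()]
#'   or a list of `well_movie` objects.
#' @param params A [screen_params()] list.
#' @param control_variant Variant id of the control wells (for in-memory
#'   input; directories carry it in their config).
#' @param out_dir Where to write results (directory input only); default
#'   `<plate>/results`.
#' @return List of class `screen_analysis`: `wells`, `epochs`,
#'   `summaries`, `winners`, `report`, `qc`.
#' @export
analyze_screen <- function(plate, params = screen_params(),
                           control_variant = "control", out_dir = NULL) {
  log <- character(0)
  if (is.character(plate)) {
    cfg_path <- file.path(plate, "config.json")
    layout_path <- file.path(plate, "layout.csv")
    if (!file.exists(layout_path)) {
      stop_ss("no layout.csv in plate directory: ", plate)
    }
    config <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
    layout <- utils::read.csv(layout_path, stringsAsFactors = FALSE)
    control_variant <- config$control_variant %||% control_variant
    epochs_cfg <- as.data.frame(config$pulse_epochs)
    results <- vector("list", nrow(layout))
    for (i in seq_len(nrow(layout))) {
      path <- file.path(plate, "wells", paste0(layout$well_id[i], ".tif"))
      movie <- tryCatch(
        read_well_tiff(path, config$frame_rate, epochs_cfg,
                       well_id = layout$well_id[i],
                       plate_id = config$plate_id %||% "P01",
                       variant_id = layout$variant_id[i]),
        error = function(e) NULL)
      if (is.null(movie)) {
        log <- c(log, sprintf("well %s: unreadable movie (%s); well flagged",
                              layout$well_id[i], basename(path)))
        results[[i]] <- list(
          well = data.frame(plate_id = config$plate_id %||% "P01",
                            well_id = layout$well_id[i],
                            variant_id = layout$variant_id[i],
                            is_control = layout$is_control[i],
                            n_responsive = 0L, fraction_responsive = 0,
                            no_response = TRUE, polarity = NA_real_,
                            f0 = NA_real_, bleach_tau = NA_real_,
                            bleach_method = "none",
                            stringsAsFactors = FALSE),
          epochs = data.frame())
        next
      }
      results[[i]] <- analyze_well(movie, params,
                                   is_control = layout$is_control[i])
    }
    wells <- do.call(rbind, lapply(results, `[[`, "well"))
    epochs <- do.call(rbind, lapply(results, function(r) {
      if (nrow(r$epochs)) r$epochs else NULL
    }))
  } else {
    res <- analyze_wells(plate, params, control_variant = control_variant)
    wells <- res$wells
    epochs <- res$epochs
  }

  qc <- qc_wells_and_plate(wells, min_responsive = params$min_responsive,
                           min_replicates = params$min_replicates)
  summaries <- summarize_variants(qc, epochs,
                                  ranking_pulses = params$ranking_pulses)
  summaries <- filter_variants(summaries,
                               min_pixels_per_plate = params$min_pixels_per_plate)
  winners <- select_joint_winners(summaries, alpha = params$selection_alpha)
  report <- screen_report(qc, summaries, winners)
  report$qc_log <- c(log, report$qc_log)

  out <- structure(
    list(wells = wells, epochs = epochs, summaries = summaries,
         winners = winners, report = report, qc = qc),
    class = "screen_analysis")

  if (is.character(plate)) {
    out_dir <- out_dir %||% file.path(plate, "results")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ord <- order(wells$well_id)
    utils::write.csv(wells[ord, ], file.path(out_dir, "well_metrics.csv"),
                     row.names = FALSE)
    if (!is.null(epochs)) {
      utils::write.csv(epochs[order(epochs$well_id, epochs$pulses), ],
                       file.path(out_dir, "epoch_metrics.csv"),
                       row.names = FALSE)
    }
    s <- summaries[order(summaries$variant_id), ]
    utils::write.csv(s, file.path(out_dir, "variant_summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "screen_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(report$qc_log, file.path(out_dir, "analysis.log"))
    jsonlite::write_json(params, file.path(out_dir, "params.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.screen_analysis <- function(x, ...) {
  r <- x$report
  cat(sprintf("screen analysis: %d wells (%d discarded), %d variants\n",
              r$n_wells, r$n_wells_discarded, r$n_variants))
  if (r$plate_rejected) cat("PLATE REJECTED (control well failed QC)\n")
  cat(sprintf("retest %d | eliminated %d | stage-1 %d | winners %d\n",
              r$n_retest, r$n_eliminated, r$n_stage1, r$n_winners))
  if (length(r$winners)) {
    cat("winners:", paste(r$winners, collapse = ", "), "\n")
  }
  invisible(x)
}
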