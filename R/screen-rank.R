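# Plate-level QC, in-plate control normalization, variant aggregation and
# joint sensitivity/expression winner selection.

#' Well- and plate-level quality control
#'
#' Applies the screen's QC rules: wells with fewer than `min_responsive`
#' responsive pixels (or no pooled response) are discarded; variants with
#' fewer than `min_replicates` surviving replicate wells are flagged for
#' retesting; if any control well is discarded the entire plate is
#' rejected and every variant set to retest.
#'
#' @param wells Data frame of well-level results (from [analyze_wells()]);
#'   must contain `well_id`, `variant_id`, `is_control`, `n_responsive`
#'   and `no_response`.
#' @param min_responsive Minimum responsive pixels per well (discard below).
#' @param min_replicates Minimum surviving replicates per variant.
#' @return List of class `plate_qc`: `wells` (with `qc_pass`), `variants`
#'   (`variant_id`, `n_replicates`, `n_passing`, `qc_status`),
#'   `plate_rejected` and a `log` of QC decisions.
#' @export
qc_wells_and_plate <- function(wells, min_responsive = 4L,
                               min_replicates = 3L) {
  req <- c("well_id", "variant_id", "is_control", "n_responsive", "no_response")
  if (!all(req %in% names(wells))) {
    stop_ss("`wells` must contain columns: ", paste(req, collapse = ", "))
  }
  if (!any(wells$is_control)) {
    stop_ss("plate layout identifies no control wells")
  }
  log <- character(0)
  wells$qc_pass <- !wells$no_response & wells$n_responsive >= min_responsive
  for (i in which(!wells$qc_pass)) {
    log <- c(log, sprintf(
      "well %s (%s) discarded: %d responsive pixels < %d%s",
      wells$well_id[i], wells$variant_id[i], wells$n_responsive[i],
      min_responsive, if (wells$no_response[i]) " (no pooled response)" else ""))
  }
  plate_rejected <- any(!wells$qc_pass & wells$is_control)
  if (plate_rejected) {
    log <- c(log, "control well(s) discarded: entire plate rejected, all variants flagged for retesting")
  }
  vtab <- wells[!wells$is_control, ]
  ids <- unique(vtab$variant_id)
  variants <- data.frame(
    variant_id = ids,
    n_replicates = vapply(ids, function(v) sum(vtab$variant_id == v), integer(1)),
    n_passing = vapply(ids, function(v) {
      sum(vtab$variant_id == v & vtab$qc_pass)
    }, integer(1)),
    stringsAsFactors = FALSE)
  variants$qc_status <- ifelse(
    plate_rejected | variants$n_passing < min_replicates, "retest", "pass")
  for (i in which(variants$qc_status == "retest" & !plate_rejected)) {
    log <- c(log, sprintf(
      "variant %s flagged for retesting: %d passing replicates < %d",
      variants$variant_id[i], variants$n_passing[i], min_replicates))
  }
  structure(list(wells = wells, variants = variants,
                 plate_rejected = plate_rejected, log = log),
            class = "plate_qc")
}

#' Normalize a metric to the in-plate control
#'
#' Variant replicate mean divided by the control replicate mean, the
#' screen's batch-variability correction. The control normalized against
#' itself is 1 by construction; a negative-going variant against a
#' positive control gives a signed negative ratio.
#'
#' @param variant_values Metric values over the variant's replicate wells.
#' @param control_values Metric values over the control wells.
#' @return Normalized value (scalar).
#' @export
normalize_to_control <- function(variant_values, control_values) {
  cm <- mean(control_values)
  if (cm == 0) stop_ss("control mean is zero; cannot normalize")
  mean(variant_values) / cm
}

#' Aggregate replicate wells into per-variant summaries
#'
#' For each variant on a plate, averages the metrics over its passing
#' replicate wells and normalizes them to the in-plate control wells:
#' signed dF/F0 peak per epoch (control = 1; negative for inverted
#' sensors), responsive-pixel count, baseline fluorescence F0 and time
#' constants. Also totals the responsive pixels over the variant's passing
#' wells and computes the one-sided Mann-Whitney p-value for the variant's
#' |dF/F0| at the ranking epoch exceeding the control wells'.
#'
#' @param qc A `plate_qc` from [qc_wells_and_plate()].
#' @param epochs Per-epoch metric data frame (from [analyze_wells()]).
#' @param ranking_pulses Epoch (pulse count) used for ranking and the
#'   significance test.
#' @return Data frame of class `variant_summary`, one row per variant:
#'   normalized metrics (`norm_peak_signed`, `norm_peak_abs`,
#'   `norm_pixels`, `norm_f0`, `norm_tau_on`, `norm_tau_off`),
#'   `total_responsive`, `p_vs_control`, `qc_status`.
#' @export
summarize_variants <- function(qc, epochs, ranking_pulses = 40) {
  stopifnot(inherits(qc, "plate_qc"))
  wells <- qc$wells
  ctrl_wells <- wells[wells$is_control & wells$qc_pass, ]
  if (nrow(ctrl_wells) == 0L) ctrl_wells <- wells[wells$is_control, ]
  ep_rank <- epochs[epochs$pulses == ranking_pulses, ]
  if (nrow(ep_rank) == 0L) {
    stop_ss(sprintf("no epoch with %g pulses in `epochs`", ranking_pulses))
  }
  ctrl_ep <- ep_rank[ep_rank$well_id %in% ctrl_wells$well_id, ]
  ctrl_tau <- epochs[epochs$well_id %in% ctrl_wells$well_id, ]

  mean_or_na <- function(x) if (length(x) && any(is.finite(x))) {
    mean(x[is.finite(x)])
  } else {
    NA_real_
  }
  safe_norm <- function(v, c) {
    cm <- mean_or_na(c)
    vm <- mean_or_na(v)
    if (!is.finite(cm) || cm == 0 || !is.finite(vm)) NA_real_ else vm / cm
  }

  if (nrow(qc$variants) == 0L) {
    out <- data.frame(variant_id = character(0),
                      n_passing_replicates = integer(0),
                      qc_status = character(0), norm_peak_signed = numeric(0),
                      norm_peak_abs = numeric(0), norm_pixels = numeric(0),
                      norm_f0 = numeric(0), norm_tau_on = numeric(0),
                      norm_tau_off = numeric(0), total_responsive = numeric(0),
                      p_vs_control = numeric(0), stringsAsFactors = FALSE)
    class(out) <- c("variant_summary", class(out))
    return(out)
  }
  rows <- lapply(seq_len(nrow(qc$variants)), function(i) {
    vid <- qc$variants$variant_id[i]
    vw <- wells[wells$variant_id == vid & wells$qc_pass & !wells$is_control, ]
    vep <- ep_rank[ep_rank$well_id %in% vw$well_id, ]
    vtau <- epochs[epochs$well_id %in% vw$well_id, ]
    p_vs <- if (nrow(vep) >= 1L && nrow(ctrl_ep) >= 1L) {
      mann_whitney_u(vep$peak_abs, ctrl_ep$peak_abs,
                     alternative = "greater")$p.value
    } else {
      NA_real_
    }
    data.frame(
      variant_id = vid,
      n_passing_replicates = qc$variants$n_passing[i],
      qc_status = qc$variants$qc_status[i],
      norm_peak_signed = safe_norm(vep$peak_signed, ctrl_ep$peak_signed),
      norm_peak_abs = safe_norm(vep$peak_abs, ctrl_ep$peak_abs),
      norm_pixels = safe_norm(vw$n_responsive, ctrl_wells$n_responsive),
      norm_f0 = safe_norm(vw$f0, ctrl_wells$f0),
      norm_tau_on = safe_norm(vtau$tau_on, ctrl_tau$tau_on),
      norm_tau_off = safe_norm(vtau$tau_off, ctrl_tau$tau_off),
      total_responsive = sum(vw$n_responsive),
      p_vs_control = p_vs,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("variant_summary", class(out))
  out
}

#' Eliminate variants with too few responsive pixels per plate
#'
#' Variants whose responsive pixels, summed over their passing replicate
#' wells on the plate, fall below `min_pixels_per_plate` (strict `<`) are
#' set to `qc_status = "eliminated"`. With the default full-frame layout
#' the threshold is 1800 pixels (about 0.6% of four replicate wells'
#' pixels); for scaled-down plates pass the equivalent fraction of the
#' plate's variant-well pixels.
#'
#' @param summaries A `variant_summary` data frame.
#' @param min_pixels_per_plate Elimination threshold.
#' @return The summaries with updated `qc_status`; warns when every
#'   variant is eliminated.
#' @export
filter_variants <- function(summaries, min_pixels_per_plate = 1800) {
  low <- summaries$total_responsive < min_pixels_per_plate
  summaries$qc_status[low] <- "eliminated"
  if (all(summaries$qc_status == "eliminated")) {
    warning("all variants eliminated by the responsive-pixel threshold; empty ranking")
  }
  summaries
}

#' Jointly select winning variants on sensitivity and expression
#'
#' Two-stage selection over the QC-passing variants: stage 1 keeps
#' variants whose |dF/F0| exceeds the in-plate control with a one-sided
#' rank-test p below `alpha` across replicate wells; stage 2 keeps, of
#' those, variants with normalized responsive pixels above 1 (better
#' expression than control). Winners are ranked by normalized |dF/F0| at
#' the ranking epoch, so negative-going sensors compete on magnitude.
#'
#' @param summaries A `variant_summary` data frame (after
#'   [filter_variants()]).
#' @param alpha Stage-1 significance threshold.
#' @return Winners subset of `summaries`, ranked by `norm_peak_abs`
#'   (decreasing), with columns `stage1_pass`/`stage2_pass` added to the
#'   full table attached as attribute `"staged"`.
#' @export
select_joint_winners <- function(summaries, alpha = 0.05) {
  s <- summaries
  eligible <- s$qc_status == "pass"
  s$stage1_pass <- eligible & !is.na(s$p_vs_control) & s$p_vs_control < alpha &
    !is.na(s$norm_peak_abs) & s$norm_peak_abs > 1
  s$stage2_pass <- s$stage1_pass & !is.na(s$norm_pixels) & s$norm_pixels > 1
  winners <- s[s$stage2_pass, , drop = FALSE]
  winners <- winners[order(-winners$norm_peak_abs), , drop = FALSE]
  attr(winners, "staged") <- s
  winners
}

#' Summary report of one screened plate
#'
#' @param qc A `plate_qc`.
#' @param summaries A `variant_summary` (after elimination filtering).
#' @param winners Output of [select_joint_winners()].
#' @return List with QC/selection counts and the winner ranking, suitable
#'   for JSON serialization.
#' @export
screen_report <- function(qc, summaries, winners) {
  staged <- attr(winners, "staged") %||% summaries
  list(
    plate_rejected = qc$plate_rejected,
    n_wells = nrow(qc$wells),
    n_wells_discarded = sum(!qc$wells$qc_pass),
    n_variants = nrow(summaries),
    n_retest = sum(summaries$qc_status == "retest"),
    n_eliminated = sum(summaries$qc_status == "eliminated"),
    n_stage1 = sum(staged$stage1_pass, na.rm = TRUE),
    n_winners = nrow(winners),
    winners = winners$variant_id,
    qc_log = qc$log)
}
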