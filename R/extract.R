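# Full extraction pipeline: raw recording -> conditioned signals -> gait
# events -> paretic-referenced stride table with spatial and kinetic
# parameters and epoch labels.

#' Extract the stride table from a trial recording
#'
#' Runs the complete per-session analysis: rotates markers and forces into
#' the treadmill-surface frame, fills marker gaps, median-filters the
#' normal forces (offline 10 N heel-strike detection), low-pass filters and
#' body-weight-normalises the AP forces, detects gait events per belt,
#' segments paretic-referenced strides, assigns epochs from the belt-speed
#' schedule, and computes step lengths, step length asymmetry, leading and
#' trailing leg orientations and peak propulsion per stride.
#'
#' @param trial A [trial_recording()] (lab or surface frame).
#' @param threshold_mode `"offline"` (10 N on median-filtered force, the
#'   analysis default) or `"online"` (30 N on raw force, emulating the
#'   real-time stride counter).
#' @return A stride table tibble (one row per paretic-referenced stride)
#'   with columns `stride_idx`, `epoch`, `lead_leg`, `sl_paretic_mm`,
#'   `sl_nonparetic_mm`, `sla`, `alpha_paretic_mm`, `alpha_nonparetic_mm`,
#'   `x_paretic_mm`, `x_nonparetic_mm`, `prop_paretic_nkg`,
#'   `prop_nonparetic_nkg` plus timing/diagnostic columns.
#' @export
extract_strides <- function(trial, threshold_mode = c("offline", "online")) {
  threshold_mode <- match.arg(threshold_mode)
  cfg <- trial$config
  pp <- cfg$processing

  markers <- lapply(trial$markers, function(m) {
    if (m$frame == "lab") m <- rotate_to_surface(m, cfg$slope_deg)
    fill_gaps(m)
  })
  forces <- lapply(trial$forces, function(f) {
    if (f$frame == "lab") f <- rotate_to_surface(f, cfg$slope_deg)
    f <- lowpass_ap(f, pp$lowpass_cutoff_hz)
    f
  })

  events <- lapply(forces, function(f) {
    if (threshold_mode == "offline") {
      detect_stance(median_filter_normal(f, pp$median_window_ms),
                    threshold_n = pp$hs_threshold_offline_n,
                    min_stance_ms = pp$min_stance_ms,
                    min_swing_ms = pp$min_swing_ms)
    } else {
      detect_stance(f, threshold_n = pp$hs_threshold_online_n,
                    min_stance_ms = pp$min_stance_ms,
                    min_swing_ms = pp$min_swing_ms)
    }
  })
  paretic_events <- events[[cfg$paretic_side]]
  other_side <- setdiff(c("left", "right"), cfg$paretic_side)
  strides <- segment_strides(paretic_events, events[[other_side]])
  if (!is.null(trial$epoch_schedule)) {
    strides <- assign_epochs(strides, trial$epoch_schedule)
  } else {
    strides$epoch <- NA_character_
  }
  if (nrow(strides) == 0L) return(strides)

  spatial <- stride_spatial(strides, markers, cfg$paretic_side)
  kinetics <- stride_kinetics(strides, forces, cfg$paretic_side,
                              cfg$mass_kg)
  out <- dplyr::bind_cols(strides, spatial, kinetics)
  out$stride_idx <- seq_len(nrow(out))
  per_epoch <- table(out$epoch)
  sb_log("info", "extract_strides: %d strides (%s)", nrow(out),
         paste(names(per_epoch), per_epoch, sep = "=", collapse = ", "))
  out[, c("stride_idx", "epoch", "lead_leg", "t_start", "t_contra",
          "t_end", "sl_paretic_mm", "sl_nonparetic_mm", "sla",
          "alpha_paretic_mm", "alpha_nonparetic_mm", "x_paretic_mm",
          "x_nonparetic_mm", "prop_paretic_nkg", "prop_nonparetic_nkg",
          "prop_paretic_atypical", "prop_nonparetic_atypical")]
}

#' Event detection agreement between online and offline thresholds
#'
#' Compares heel-strike times between the real-time emulation (30 N, raw
#' normal force) and the offline rule (10 N, median-filtered) for one belt.
#'
#' @param force A [force_series()] in the surface frame.
#' @param processing [processing_params()].
#' @return Tibble of matched heel strikes with `dt_s` differences.
#' @export
compare_threshold_modes <- function(force, processing = processing_params()) {
  on <- detect_stance(force, processing$hs_threshold_online_n,
                      processing$min_stance_ms, processing$min_swing_ms)
  off <- detect_stance(median_filter_normal(force,
                                            processing$median_window_ms),
                       processing$hs_threshold_offline_n,
                       processing$min_stance_ms, processing$min_swing_ms)
  hs_on <- on$time_s[on$kind == "heel_strike"]
  hs_off <- off$time_s[off$kind == "heel_strike"]
  n <- min(length(hs_on), length(hs_off))
  tibble(t_online = hs_on[seq_len(n)], t_offline = hs_off[seq_len(n)],
         dt_s = hs_on[seq_len(n)] - hs_off[seq_len(n)])
}
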