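#' Derive split-belt speeds from the mid walking speed
#'
#' The split-belt protocol sets the slow belt to 66.6% and the fast belt to
#' 133.3% of the subject's self-selected mid speed, rounded half away from
#' zero to two decimals (treadmill speed resolution, 0.01 m/s). This gives a
#' 2:1 fast:slow ratio and keeps the average belt speed equal to the mid
#' speed across all epochs.
#'
#' @param mid_speed Self-selected treadmill speed in m/s (positive scalar).
#' @return Named numeric vector with elements `slow` and `fast` (m/s).
#' @examples
#' derive_belt_speeds(0.70)  # c(slow = 0.47, fast = 0.93)
#' @export
derive_belt_speeds <- function(mid_speed) {
  stopif_not_scalar_pos(mid_speed, "mid_speed")
  c(slow = round_half_away(0.666 * mid_speed, 2),
    fast = round_half_away(1.333 * mid_speed, 2))
}

#' Processing constants for the analysis pipeline
#'
#' All signal-conditioning and windowing constants used downstream, with the
#' study defaults: 20 Hz low-pass cutoff for anterior-posterior forces, 30 N
#' heel-strike threshold on raw normal force (real-time emulation), 10 N on
#' median-filtered force (offline), 5 ms median window, 40-stride late
#' windows, 5-stride early windows and 5-stride bins.
#'
#' @param lowpass_cutoff_hz Low-pass cutoff for AP forces (Hz).
#' @param hs_threshold_online_n Online heel-strike threshold on raw normal
#'   force (N).
#' @param hs_threshold_offline_n Offline heel-strike threshold on
#'   median-filtered normal force (N).
#' @param median_window_ms Median filter window (ms).
#' @param late_window_strides Strides averaged for Baseline / Late
#'   Adaptation.
#' @param early_window_strides Strides averaged for early epochs.
#' @param bin_size_strides Bin size for time-course summaries.
#' @param min_stance_ms,min_swing_ms Debounce durations for event detection.
#' @param rng_seed Integer seed recorded with every run.
#' @return Object of class `processing_params` (named list).
#' @export
processing_params <- function(lowpass_cutoff_hz = 20,
                              hs_threshold_online_n = 30,
                              hs_threshold_offline_n = 10,
                              median_window_ms = 5,
                              late_window_strides = 40L,
                              early_window_strides = 5L,
                              bin_size_strides = 5L,
                              min_stance_ms = 100,
                              min_swing_ms = 100,
                              rng_seed = 1L) {
  p <- list(lowpass_cutoff_hz = lowpass_cutoff_hz,
            hs_threshold_online_n = hs_threshold_online_n,
            hs_threshold_offline_n = hs_threshold_offline_n,
            median_window_ms = median_window_ms,
            late_window_strides = as.integer(late_window_strides),
            early_window_strides = as.integer(early_window_strides),
            bin_size_strides = as.integer(bin_size_strides),
            min_stance_ms = min_stance_ms,
            min_swing_ms = min_swing_ms,
            rng_seed = as.integer(rng_seed))
  for (w in c("late_window_strides", "early_window_strides",
              "bin_size_strides")) {
    if (p[[w]] < 1L) abort(sprintf("`%s` must be >= 1", w),
                           class = "splitbelt_invalid_parameter")
  }
  stopif_not_scalar_pos(p$lowpass_cutoff_hz, "lowpass_cutoff_hz")
  structure(p, class = "processing_params")
}

epoch_names <- c("baseline_slow", "baseline_mid", "adaptation",
                 "post_adaptation")

#' Default epoch plan for a session
#'
#' Baseline / Adaptation / Post-Adaptation structure with tied belts at the
#' mid speed in baseline and post-adaptation and a 2:1 split (paretic side
#' slow) during adaptation. The flat session additionally starts with a
#' slow-speed tied baseline; the incline session drops it.
#'
#' @param mid_speed Mid speed (m/s).
#' @param paretic_side `"left"` or `"right"`.
#' @param include_slow_baseline Include the slow tied baseline epoch?
#' @param n_baseline,n_adaptation,n_post Planned strides per epoch.
#' @return Tibble with columns `epoch`, `planned_strides`,
#'   `left_belt_speed`, `right_belt_speed`.
#' @export
default_epoch_plan <- function(mid_speed, paretic_side,
                               include_slow_baseline = TRUE,
                               n_baseline = 50L, n_adaptation = 600L,
                               n_post = 300L) {
  sp <- derive_belt_speeds(mid_speed)
  paretic_side <- match.arg(paretic_side, c("left", "right"))
  adapt_left <- if (paretic_side == "left") sp[["slow"]] else sp[["fast"]]
  adapt_right <- if (paretic_side == "right") sp[["slow"]] else sp[["fast"]]
  plan <- tibble(
    epoch = c(if (include_slow_baseline) "baseline_slow", "baseline_mid",
              "adaptation", "post_adaptation"),
    planned_strides = as.integer(c(if (include_slow_baseline) n_baseline,
                                   n_baseline, n_adaptation, n_post)),
    left_belt_speed = c(if (include_slow_baseline) sp[["slow"]], mid_speed,
                        adapt_left, mid_speed),
    right_belt_speed = c(if (include_slow_baseline) sp[["slow"]], mid_speed,
                         adapt_right, mid_speed))
  plan
}

#' Build and validate a session protocol configuration
#'
#' @param subject_id Subject identifier.
#' @param mass_kg Body mass (kg).
#' @param paretic_side `"left"` or `"right"` (side contralateral to the
#'   lesion; walks on the slow belt during adaptation).
#' @param slope_deg Treadmill inclination in degrees (>= 0).
#' @param mid_speed Mid speed (m/s); slow/fast derived when absent.
#' @param slow_speed,fast_speed Optional explicit belt speeds; must agree
#'   with the derivation rule within 0.01 m/s.
#' @param epoch_plan Optional epoch plan tibble (see
#'   [default_epoch_plan()]).
#' @param processing Optional [processing_params()].
#' @return Object of class `protocol_config`.
#' @export
protocol_config <- function(subject_id, mass_kg, paretic_side, slope_deg,
                            mid_speed, slow_speed = NULL, fast_speed = NULL,
                            epoch_plan = NULL, processing = NULL) {
  stopif_not_scalar_pos(mass_kg, "mass_kg")
  stopif_not_scalar_pos(mid_speed, "mid_speed")
  if (!is.numeric(slope_deg) || slope_deg < 0 || slope_deg >= 90) {
    abort("`slope_deg` must be in [0, 90)", class = "splitbelt_schema_error")
  }
  paretic_side <- match.arg(paretic_side, c("left", "right"))
  sp <- derive_belt_speeds(mid_speed)
  for (nm in c("slow", "fast")) {
    given <- if (nm == "slow") slow_speed else fast_speed
    if (!is.null(given) && abs(given - sp[[nm]]) > 0.01 + 1e-9) {
      abort(sprintf(
        "`%s_speed` (%.2f) inconsistent with 66.6%%/133.3%% rule (%.2f)",
        nm, given, sp[[nm]]), class = "splitbelt_schema_error")
    }
  }
  cfg <- structure(list(
    subject_id = as.character(subject_id),
    mass_kg = mass_kg,
    paretic_side = paretic_side,
    slope_deg = slope_deg,
    mid_speed = mid_speed,
    slow_speed = slow_speed %||% sp[["slow"]],
    fast_speed = fast_speed %||% sp[["fast"]],
    epoch_plan = epoch_plan %||%
      default_epoch_plan(mid_speed, paretic_side,
                         include_slow_baseline = slope_deg == 0),
    processing = processing %||% processing_params()),
    class = "protocol_config")
  validate_epoch_plan(cfg)
  cfg
}

validate_epoch_plan <- function(cfg) {
  plan <- cfg$epoch_plan
  need <- c("epoch", "planned_strides", "left_belt_speed",
            "right_belt_speed")
  miss <- setdiff(need, names(plan))
  if (length(miss)) {
    abort(sprintf("epoch_plan missing column(s): %s",
                  paste(miss, collapse = ", ")),
          class = "splitbelt_schema_error")
  }
  bad <- setdiff(plan$epoch, epoch_names)
  if (length(bad)) {
    abort(sprintf("unknown epoch name(s): %s", paste(bad, collapse = ", ")),
          class = "splitbelt_schema_error")
  }
  if (any(plan$planned_strides < 1)) {
    abort("planned_strides must be positive", class = "splitbelt_schema_error")
  }
  tol <- 0.005 + 1e-9
  for (i in seq_len(nrow(plan))) {
    ep <- plan$epoch[i]
    l <- plan$left_belt_speed[i]; r <- plan$right_belt_speed[i]
    if (ep %in% c("baseline_mid", "post_adaptation") &&
        (abs(l - cfg$mid_speed) > tol || abs(r - cfg$mid_speed) > tol)) {
      abort(sprintf("epoch %s must run both belts at mid speed", ep),
            class = "splitbelt_schema_error")
    }
    if (ep == "adaptation") {
      paretic <- if (cfg$paretic_side == "left") l else r
      other <- if (cfg$paretic_side == "left") r else l
      if (abs(paretic - cfg$slow_speed) > tol ||
          abs(other - cfg$fast_speed) > tol) {
        abort("adaptation must run the paretic belt slow, contralateral fast",
              class = "splitbelt_schema_error")
      }
    }
  }
  invisible(cfg)
}

#' Load a protocol configuration from YAML or JSON
#'
#' Reads the documented config schema, applies derived defaults (slow/fast
#' speeds, epoch plan, processing constants) and validates invariants.
#' Unknown epoch names, missing required fields and speed-rule violations
#' raise schema errors naming the offending key.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A [protocol_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path),
          class = "splitbelt_schema_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  required <- c("subject_id", "mass_kg", "paretic_side", "slope_deg",
                "mid_speed")
  miss <- setdiff(required, names(raw))
  if (length(miss)) {
    abort(sprintf("config missing required field(s): %s",
                  paste(miss, collapse = ", ")),
          class = "splitbelt_schema_error")
  }
  plan <- if (!is.null(raw$epoch_plan)) as_tibble(raw$epoch_plan)
  proc <- if (!is.null(raw$processing)) {
    do.call(processing_params, raw$processing)
  }
  if (is.null(raw$processing$rng_seed)) {
    sb_log("info", "config %s: rng_seed absent, default %d applied",
           raw$subject_id, processing_params()$rng_seed)
  }
  protocol_config(subject_id = raw$subject_id, mass_kg = raw$mass_kg,
                  paretic_side = raw$paretic_side,
                  slope_deg = raw$slope_deg, mid_speed = raw$mid_speed,
                  slow_speed = raw$slow_speed, fast_speed = raw$fast_speed,
                  epoch_plan = plan, processing = proc)
}

#' Write a protocol configuration to YAML
#'
#' @param config A [protocol_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$epoch_plan <- as.list(as.data.frame(x$epoch_plan))
  x$processing <- unclass(x$processing)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Clinical characteristics of the reference chronic-stroke cohort
#'
#' The 12-participant cohort of chronic stroke survivors whose protocol this
#' package models: age, gender, affected body side, lower-extremity
#' Fugl-Meyer score, belt speeds (slow/mid/fast, m/s), total adaptation and
#' post-adaptation stride counts in the flat and incline sessions, and the
#' incline-session slope. Used for protocol arithmetic checks and to scale
#' the synthetic study.
#'
#' @return Tibble with one row per participant.
#' @export
stroke_cohort <- function() {
  tibble(
    id = paste0("P", 1:12),
    age = c(43, 55, 64, 58, 66, 60, 77, 59, 52, 66, 75, 49),
    gender = c("F", "F", "F", "F", "M", "F", "M", "M", "M", "M", "M", "M"),
    affected_side = c(rep("right", 9), "left", "right", "right"),
    fugl_meyer = c(33, 26, 29, 21, 30, 26, 30, 32, 32, 29, 32, 33),
    slow_speed = c(0.75, 0.54, 0.40, 0.30, 0.51, 0.60, 0.23, 0.47, 0.64,
                   0.51, 0.63, 0.47),
    mid_speed = c(1.13, 0.81, 0.60, 0.45, 0.77, 0.90, 0.35, 0.70, 0.96,
                  0.76, 0.94, 0.71),
    fast_speed = c(1.50, 1.08, 0.80, 0.60, 1.02, 1.20, 0.47, 0.93, 1.28,
                   1.01, 1.25, 0.95),
    adapt_strides_flat = c(907, 867, 617, 901, 606, 907, 589, 905, 903,
                           908, 913, 931),
    adapt_strides_incline = c(609, 301, 368, 406, 452, 597, 605, 608, 602,
                              519, 497, 450),
    post_strides_flat = c(605, 642, 307, 625, 599, 600, 598, 600, 603,
                          602, 552, 303),
    post_strides_incline = c(303, 300, 10, 10, 302, 300, 302, 306, 302,
                             299, 306, 300),
    incline_slope_deg = c(8.5, 5, 5, 5, 5, 5, 5, 8.5, 5, 8.5, 5, 5))
}
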