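#' Marker trajectory time series
#'
#' One labelled marker's positions at the kinematic sampling rate (100 Hz
#' nominal), with a per-frame validity mask; invalid frames carry NA
#' positions (occlusion gaps).
#'
#' @param marker Marker name (e.g. `"ankle_L"`).
#' @param time_s Strictly increasing frame times (s).
#' @param xyz_mm Numeric matrix (n x 3) of positions in mm.
#' @param valid Logical validity mask (default: rows without NA).
#' @param frame Coordinate frame, `"surface"` or `"lab"`.
#' @return Object of class `marker_series`.
#' @export
marker_series <- function(marker, time_s, xyz_mm, valid = NULL,
                          frame = c("surface", "lab")) {
  frame <- match.arg(frame)
  xyz_mm <- as.matrix(xyz_mm)
  if (ncol(xyz_mm) != 3L || nrow(xyz_mm) != length(time_s)) {
    abort("`xyz_mm` must be an n x 3 matrix matching `time_s`",
          class = "splitbelt_format_error")
  }
  if (is.unsorted(time_s, strictly = TRUE)) {
    abort("marker times must be strictly increasing",
          class = "splitbelt_format_error")
  }
  valid <- valid %||% stats::complete.cases(xyz_mm)
  xyz_mm[!valid, ] <- NA_real_
  dimnames(xyz_mm) <- NULL
  structure(list(marker = marker, time_s = as.numeric(time_s),
                 xyz_mm = unname(xyz_mm), valid = valid,
                 filled = logical(length(time_s)), frame = frame),
            class = "marker_series")
}

#' Force-plate time series for one belt
#'
#' @param side Belt side, `"left"` or `"right"`.
#' @param time_s Strictly increasing sample times (s, 1000 Hz nominal).
#' @param f_ap_n,f_ml_n,f_normal_n Force components (N):
#'   anterior-posterior, mediolateral, surface-normal.
#' @param frame Coordinate frame, `"surface"` or `"lab"`.
#' @return Object of class `force_series`.
#' @export
force_series <- function(side, time_s, f_ap_n, f_ml_n, f_normal_n,
                         frame = c("surface", "lab")) {
  frame <- match.arg(frame)
  side <- match.arg(side, c("left", "right"))
  n <- length(time_s)
  if (length(f_ap_n) != n || length(f_ml_n) != n || length(f_normal_n) != n) {
    abort("force components must match `time_s` in length",
          class = "splitbelt_format_error")
  }
  if (is.unsorted(time_s, strictly = TRUE)) {
    abort("force times must be strictly increasing",
          class = "splitbelt_format_error")
  }
  structure(list(side = side, time_s = as.numeric(time_s),
                 f_ap_n = as.numeric(f_ap_n), f_ml_n = as.numeric(f_ml_n),
                 f_normal_n = as.numeric(f_normal_n), frame = frame),
            class = "force_series")
}

sampling_rate <- function(time_s) {
  1 / median(diff(time_s))
}

#' One recorded session: markers, forces, protocol metadata
#'
#' Marker and force streams share the recording clock (t = 0 at recording
#' start); the epoch schedule gives the belt-speed timeline used for stride
#' epoch assignment.
#'
#' @param markers Named list of [marker_series()] (requires both ankles and
#'   both greater trochanters: `ankle_L`, `ankle_R`, `troch_L`, `troch_R`).
#' @param forces Named list of [force_series()] with elements `left`,
#'   `right`.
#' @param config [protocol_config()].
#' @param epoch_schedule Tibble `epoch`, `t_start`, `t_end`,
#'   `left_belt_speed`, `right_belt_speed`, or `NULL` when unknown.
#' @return Object of class `trial_recording`.
#' @export
trial_recording <- function(markers, forces, config, epoch_schedule = NULL) {
  need <- c("ankle_L", "ankle_R", "troch_L", "troch_R")
  miss <- setdiff(need, names(markers))
  if (length(miss)) {
    abort(sprintf("missing required marker(s): %s",
                  paste(miss, collapse = ", ")),
          class = "splitbelt_format_error")
  }
  miss <- setdiff(c("left", "right"), names(forces))
  if (length(miss)) {
    abort(sprintf("missing force plate(s): %s", paste(miss, collapse = ", ")),
          class = "splitbelt_format_error")
  }
  structure(list(markers = markers, forces = forces, config = config,
                 epoch_schedule = epoch_schedule),
            class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf(
    "<trial_recording> subject %s: %d markers @%.0f Hz, forces @%.0f Hz, slope %.1f deg\n",
    x$config$subject_id, length(x$markers),
    sampling_rate(x$markers[[1]]$time_s),
    sampling_rate(x$forces$left$time_s), x$config$slope_deg))
  invisible(x)
}
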