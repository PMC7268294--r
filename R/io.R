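# On-disk formats. Markers and forces travel as long TSV with a one-line
# header comment declaring the sampling rate and coordinate frame; stride
# tables as TSV; outcomes and stats reports as JSON. All writers and
# readers are mutually inverse to numeric precision.

fmt_header <- function(fs, frame) sprintf("# fs_hz=%.10g frame=%s", fs, frame)

parse_header <- function(path) {
  line <- readLines(path, n = 1L)
  if (!grepl("^# fs_hz=", line)) {
    abort(sprintf("%s: missing '# fs_hz=... frame=...' header", path),
          class = "splitbelt_format_error")
  }
  fs <- as.numeric(sub("^# fs_hz=([0-9.eE+-]+) .*$", "\\1", line))
  frame <- sub("^.* frame=(\\w+)$", "\\1", line)
  list(fs = fs, frame = frame)
}

#' Write marker trajectories to long TSV
#'
#' Columns `time_s  marker  x_mm  y_mm  z_mm`; masked frames carry NA
#' coordinates. A header comment declares sampling rate and frame.
#'
#' @param markers Named list of [marker_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_markers_tsv <- function(markers, path) {
  tabs <- lapply(markers, function(m) {
    tibble(time_s = m$time_s, marker = m$marker,
           x_mm = m$xyz_mm[, 1], y_mm = m$xyz_mm[, 2],
           z_mm = m$xyz_mm[, 3])
  })
  tab <- dplyr::bind_rows(tabs)
  writeLines(fmt_header(sampling_rate(markers[[1]]$time_s),
                        markers[[1]]$frame), path)
  readr::write_tsv(tab, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read marker trajectories from long TSV
#'
#' @param path Path written by [write_markers_tsv()].
#' @return Named list of [marker_series()].
#' @export
read_markers_tsv <- function(path) {
  hdr <- parse_header(path)
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  need <- c("time_s", "marker", "x_mm", "y_mm", "z_mm")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    abort(sprintf("%s: missing column(s) %s", path,
                  paste(miss, collapse = ", ")),
          class = "splitbelt_format_error")
  }
  out <- lapply(split(tab, tab$marker), function(m) {
    if (is.unsorted(m$time_s, strictly = TRUE)) {
      abort(sprintf("%s: non-monotone timestamps for marker %s", path,
                    m$marker[1]), class = "splitbelt_format_error")
    }
    fs <- sampling_rate(m$time_s)
    if (abs(fs - hdr$fs) > 0.01 * hdr$fs) {
      abort(sprintf("%s: sampling rate %.3f Hz differs from header %.3f Hz",
                    path, fs, hdr$fs), class = "splitbelt_format_error")
    }
    marker_series(m$marker[1], m$time_s,
                  cbind(m$x_mm, m$y_mm, m$z_mm), frame = hdr$frame)
  })
  out[unique(tab$marker)]
}

#' Write per-belt forces to TSV
#'
#' Columns `time_s  side  f_ap_n  f_ml_n  f_normal_n`, side in
#' left/right (one force plate per belt).
#'
#' @param forces Named list of [force_series()] (`left`, `right`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_forces_tsv <- function(forces, path) {
  tab <- dplyr::bind_rows(lapply(forces, function(f) {
    tibble(time_s = f$time_s, side = f$side, f_ap_n = f$f_ap_n,
           f_ml_n = f$f_ml_n, f_normal_n = f$f_normal_n)
  }))
  writeLines(fmt_header(sampling_rate(forces[[1]]$time_s),
                        forces[[1]]$frame), path)
  readr::write_tsv(tab, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read per-belt forces from TSV
#'
#' @param path Path written by [write_forces_tsv()].
#' @return Named list of [force_series()].
#' @export
read_forces_tsv <- function(path) {
  hdr <- parse_header(path)
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  need <- c("time_s", "side", "f_ap_n", "f_ml_n", "f_normal_n")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    abort(sprintf("%s: missing column(s) %s", path,
                  paste(miss, collapse = ", ")),
          class = "splitbelt_format_error")
  }
  lapply(split(tab, tab$side), function(f) {
    fs <- sampling_rate(f$time_s)
    if (abs(fs - hdr$fs) > 0.01 * hdr$fs) {
      abort(sprintf("%s: sampling rate %.3f Hz differs from header %.3f Hz",
                    path, fs, hdr$fs), class = "splitbelt_format_error")
    }
    force_series(f$side[1], f$time_s, f$f_ap_n, f$f_ml_n, f$f_normal_n,
                 frame = hdr$frame)
  })
}

#' Write / read an epoch schedule
#'
#' @param schedule Tibble `epoch`, `t_start`, `t_end`, `left_belt_speed`,
#'   `right_belt_speed`.
#' @param path TSV path.
#' @return `path` / the schedule tibble.
#' @export
write_schedule_tsv <- function(schedule, path) {
  readr::write_tsv(schedule, path)
  invisible(path)
}

#' @rdname write_schedule_tsv
#' @export
read_schedule_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Assemble a trial recording from on-disk signals
#'
#' Reads markers and forces (both declare t = 0 at recording start; no
#' cross-correlation alignment is attempted) and validates the required
#' marker set and sampling rates.
#'
#' @param markers_path,forces_path TSV paths.
#' @param config [protocol_config()].
#' @param schedule_path Optional epoch-schedule TSV for epoch assignment.
#' @return A [trial_recording()].
#' @export
read_trial <- function(markers_path, forces_path, config,
                       schedule_path = NULL) {
  markers <- read_markers_tsv(markers_path)
  forces <- read_forces_tsv(forces_path)
  schedule <- if (!is.null(schedule_path)) read_schedule_tsv(schedule_path)
  trial_recording(markers, forces, config, schedule)
}

#' Write a trial recording's signals (and schedule) to a directory
#'
#' @param trial A [trial_recording()].
#' @param dir Output directory (created if needed). Writes `markers.tsv`,
#'   `forces.tsv`, `schedule.tsv`, and `truth.tsv` when the trial carries
#'   synthetic truth.
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_markers_tsv(trial$markers, file.path(dir, "markers.tsv"))
  write_forces_tsv(trial$forces, file.path(dir, "forces.tsv"))
  if (!is.null(trial$epoch_schedule)) {
    write_schedule_tsv(trial$epoch_schedule, file.path(dir, "schedule.tsv"))
  }
  truth <- attr(trial, "truth")
  if (!is.null(truth)) {
    readr::write_tsv(truth, file.path(dir, "truth.tsv"))
  }
  invisible(dir)
}

#' Write / read a stride table
#'
#' @param stride_table Stride table tibble.
#' @param path TSV path.
#' @return `path` / the stride table.
#' @export
write_stride_table <- function(stride_table, path) {
  readr::write_tsv(stride_table, path)
  invisible(path)
}

#' @rdname write_stride_table
#' @export
read_stride_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write / read epoch outcomes as JSON
#'
#' Outcomes are keyed by parameter, each holding the five outcome measures
#' plus diagnostics; numbers survive the round trip to full precision.
#'
#' @param outcomes Outcomes tibble from [compute_outcomes()].
#' @param path JSON path.
#' @return `path` / the outcomes tibble.
#' @export
write_outcomes <- function(outcomes, path) {
  keyed <- split(outcomes[, setdiff(names(outcomes), "parameter")],
                 outcomes$parameter)
  keyed <- lapply(keyed, function(r) lapply(as.list(r), unname))
  jsonlite::write_json(keyed[unique(outcomes$parameter)], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_outcomes
#' @export
read_outcomes <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- dplyr::bind_rows(lapply(raw, as_tibble))
  out$parameter <- names(raw)
  out[, c("parameter", setdiff(names(out), "parameter"))]
}
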