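# Gait event detection from normal ground-reaction forces: a heel strike is
# the first sample at or above threshold of a sufficiently long loaded
# interval, stance end the first sample back below threshold of a
# sufficiently long unloaded interval. Short excursions in either direction
# are debounced (merged) before events are emitted.

#' Detect heel strikes and stance ends from a normal-force channel
#'
#' @param series A [force_series()]; use median-filtered force with the 10 N
#'   threshold for offline analysis, raw force with the 30 N threshold to
#'   emulate the real-time stride counter.
#' @param threshold_n Force threshold (N).
#' @param min_stance_ms Minimum duration of a loaded interval (ms); shorter
#'   suprathreshold excursions are discarded.
#' @param min_swing_ms Minimum duration of an unloaded interval (ms);
#'   shorter subthreshold dips are merged into the surrounding stance.
#' @return Tibble of events: `time_s`, `kind` (`heel_strike` /
#'   `stance_end`), `sample_idx` (1-based), `side`.
#' @export
detect_stance <- function(series, threshold_n = 10, min_stance_ms = 100,
                          min_swing_ms = 100) {
  f <- series$f_normal_n
  fs <- sampling_rate(series$time_s)
  if (length(f) == 0L || all(!is.finite(f)) || all(f < threshold_n)) {
    sb_log("warning", "side %s: no suprathreshold force, no events",
           series$side)
    return(tibble(time_s = numeric(), kind = character(),
                  sample_idx = integer(), side = character()))
  }
  min_stance <- max(1L, ceiling(min_stance_ms * fs / 1000 - 1e-6))
  min_swing <- max(1L, ceiling(min_swing_ms * fs / 1000 - 1e-6))
  above <- f >= threshold_n
  # pass 1: merge sub-min_swing unloaded dips bounded by loaded runs
  r <- rle(above)
  if (length(r$lengths) > 2L) {
    inner <- 2:(length(r$lengths) - 1L)
    fix <- inner[!r$values[inner] & r$lengths[inner] < min_swing]
    if (length(fix)) {
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (k in fix) above[starts[k]:ends[k]] <- TRUE
    }
  }
  # pass 2: drop loaded runs shorter than min_stance
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  short <- which(r$values & r$lengths < min_stance)
  for (k in short) above[starts[k]:ends[k]] <- FALSE
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  hs_idx <- starts[r$values]
  se_idx <- ends[r$values] + 1L
  se_idx <- se_idx[se_idx <= length(f)]   # recording may end mid-stance
  if (length(hs_idx) == 0L) {
    sb_log("warning", "side %s: all loaded intervals debounced away",
           series$side)
    return(tibble(time_s = numeric(), kind = character(),
                  sample_idx = integer(), side = character()))
  }
  ev <- rbind(
    data.frame(sample_idx = hs_idx, kind = "heel_strike"),
    data.frame(sample_idx = se_idx, kind = "stance_end"))
  ev <- ev[order(ev$sample_idx), ]
  tibble(time_s = series$time_s[ev$sample_idx], kind = ev$kind,
         sample_idx = as.integer(ev$sample_idx), side = series$side)
}

#' Segment strides from per-leg heel-strike events
#'
#' A stride is the interval between two consecutive heel strikes of the
#' reference leg; a well-formed stride contains exactly one contralateral
#' heel strike. Malformed intervals (zero or multiple contralateral
#' strikes) are dropped and counted in the log.
#'
#' @param events_ref,events_other Event tibbles from [detect_stance()] for
#'   the reference leg (paretic, by convention) and the contralateral leg.
#' @param ref_leg,other_leg Leg labels for the output.
#' @return Tibble of strides: `stride_idx`, `lead_leg`, `t_start`,
#'   `t_contra`, `t_end`, `t_stance_end_ref`, `t_stance_end_other`.
#' @export
segment_strides <- function(events_ref, events_other,
                            ref_leg = "paretic", other_leg = "nonparetic") {
  hs_r <- events_ref$time_s[events_ref$kind == "heel_strike"]
  hs_o <- events_other$time_s[events_other$kind == "heel_strike"]
  se_r <- events_ref$time_s[events_ref$kind == "stance_end"]
  se_o <- events_other$time_s[events_other$kind == "stance_end"]
  if (length(hs_r) < 2L) {
    sb_log("warning", "fewer than 2 reference heel strikes; no strides")
    return(tibble(stride_idx = integer(), lead_leg = character(),
                  t_start = numeric(), t_contra = numeric(),
                  t_end = numeric(), t_stance_end_ref = numeric(),
                  t_stance_end_other = numeric()))
  }
  n_dropped <- 0L
  out <- vector("list", length(hs_r) - 1L)
  for (i in seq_len(length(hs_r) - 1L)) {
    t0 <- hs_r[i]; t1 <- hs_r[i + 1L]
    contra <- hs_o[hs_o >= t0 & hs_o < t1]
    if (length(contra) != 1L) {
      n_dropped <- n_dropped + 1L
      next
    }
    first_after <- function(x, t) {
      x <- x[x > t]
      if (length(x)) x[1] else NA_real_
    }
    out[[i]] <- tibble(stride_idx = i, lead_leg = ref_leg, t_start = t0,
                       t_contra = contra, t_end = t1,
                       t_stance_end_ref = first_after(se_r, t0),
                       t_stance_end_other = first_after(se_o, contra))
  }
  if (n_dropped > 0L) {
    sb_log("info", "segment_strides: dropped %d malformed stride(s)",
           n_dropped)
  }
  strides <- dplyr::bind_rows(out)
  strides$stride_idx <- seq_len(nrow(strides))
  strides
}

#' Label strides with their protocol epoch
#'
#' Each stride takes the epoch active at its starting heel strike. Strides
#' spanning a belt-speed transition (epoch boundary) are dropped so no
#' stride mixes conditions; strides starting outside any scheduled epoch
#' (e.g. during a resting break that somehow produced force) are dropped
#' with a warning.
#'
#' @param strides Stride tibble from [segment_strides()].
#' @param schedule Tibble `epoch`, `t_start`, `t_end` (plus belt speeds)
#'   covering the recording.
#' @return `strides` with an `epoch` column; dropped rows removed.
#' @export
assign_epochs <- function(strides, schedule) {
  need <- setdiff(epoch_names[-1], schedule$epoch)
  if (length(need)) {
    abort(sprintf("epoch schedule missing epoch(s): %s",
                  paste(need, collapse = ", ")),
          class = "splitbelt_schema_error")
  }
  find_ep <- function(t) {
    k <- which(schedule$t_start <= t & t < schedule$t_end)
    if (length(k) == 1L) k else NA_integer_
  }
  k0 <- vapply(strides$t_start, find_ep, integer(1))
  # t_end is the next same-leg heel strike; use the sample just before so a
  # stride ending exactly on a boundary is not counted as spanning it
  k1 <- vapply(strides$t_end - 1e-9, find_ep, integer(1))
  keep <- !is.na(k0) & !is.na(k1) & k0 == k1
  n_out <- sum(is.na(k0))
  n_span <- sum(keep == FALSE) - n_out
  if (n_span > 0L) {
    sb_log("info", "assign_epochs: dropped %d transition-spanning stride(s)",
           n_span)
  }
  if (n_out > 0L) {
    sb_log("warning", "assign_epochs: dropped %d stride(s) outside schedule",
           n_out)
  }
  strides <- strides[keep, ]
  strides$epoch <- schedule$epoch[k0[keep]]
  strides
}
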