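# Signal conditioning: coordinate rotation into the treadmill-surface frame,
# marker gap filling, and force filtering. Kinematic channels are not
# low-pass filtered; only forces are.

rotation_lab_to_surface <- function(slope_deg) {
  th <- slope_deg * pi / 180
  # rotate about the mediolateral (y) axis by -slope so that the lab vector
  # (cos th, 0, sin th) -- a unit vector along the inclined belt -- maps to
  # +x, and +z becomes orthogonal to the belt surface (right-handed frame)
  matrix(c(cos(th), 0, sin(th),
           0, 1, 0,
           -sin(th), 0, cos(th)), nrow = 3, byrow = TRUE)
}

#' Rotate a series from the lab frame to the treadmill-surface frame
#'
#' Applies the rotation about the mediolateral axis that aligns +x with the
#' uphill belt direction and +z with the surface normal, identically to
#' marker positions and force vectors. With `slope_deg = 0` this is the
#' identity. Pass a negative slope to undo the transform.
#'
#' @param series A [marker_series()] or [force_series()].
#' @param slope_deg Treadmill inclination (degrees), |slope| < 90.
#' @return The same type of series, expressed in the surface frame.
#' @export
rotate_to_surface <- function(series, slope_deg) {
  if (abs(slope_deg) >= 90) {
    abort("|slope_deg| must be < 90", class = "splitbelt_invalid_parameter")
  }
  UseMethod("rotate_to_surface")
}

#' @export
rotate_to_surface.marker_series <- function(series, slope_deg) {
  R <- rotation_lab_to_surface(slope_deg)
  series$xyz_mm <- series$xyz_mm %*% t(R)
  series$frame <- if (series$frame == "lab") "surface" else series$frame
  series
}

#' @export
rotate_to_surface.force_series <- function(series, slope_deg) {
  R <- rotation_lab_to_surface(slope_deg)
  v <- cbind(series$f_ap_n, series$f_ml_n, series$f_normal_n) %*% t(R)
  series$f_ap_n <- v[, 1]; series$f_ml_n <- v[, 2]; series$f_normal_n <- v[, 3]
  series$frame <- if (series$frame == "lab") "surface" else series$frame
  series
}

#' Fill marker occlusion gaps with local quintic interpolation
#'
#' Interior gaps of at most `max_gap_frames` invalid frames are filled, per
#' coordinate, by an interpolating quintic (degree-5 polynomial) fitted
#' through the three nearest valid frames on each side of the gap -- the
#' interpolating limit of a quintic smoothing spline. Longer gaps and
#' leading/trailing gaps are left masked and reported; originally valid
#' frames are never altered.
#'
#' @param series A [marker_series()].
#' @param max_gap_frames Longest gap (frames) that will be filled.
#' @return The series with filled frames marked in `$filled`.
#' @export
fill_gaps <- function(series, max_gap_frames = 10L) {
  valid <- series$valid
  if (sum(valid) < 6L) {
    abort("fill_gaps needs at least 6 valid frames",
          class = "splitbelt_invalid_parameter")
  }
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n_left <- 0L
  for (k in seq_along(r$lengths)) {
    if (r$values[k]) next
    gap <- starts[k]:ends[k]
    interior <- starts[k] > 1L && ends[k] < length(valid)
    if (!interior || r$lengths[k] > max_gap_frames) {
      n_left <- n_left + 1L
      next
    }
    left <- utils::tail(which(valid[seq_len(starts[k] - 1L)]), 3L)
    right <- which(valid) ; right <- utils::head(right[right > ends[k]], 3L)
    pts <- c(left, right)
    deg <- min(5L, length(pts) - 1L)
    t0 <- series$time_s[gap]
    tp <- series$time_s[pts]
    ctr <- mean(tp); scl <- max(diff(range(tp)), .Machine$double.eps)
    X <- outer((tp - ctr) / scl, 0:deg, `^`)
    Xg <- outer((t0 - ctr) / scl, 0:deg, `^`)
    for (j in 1:3) {
      beta <- qr.solve(X, series$xyz_mm[pts, j])
      series$xyz_mm[gap, j] <- Xg %*% beta
    }
    series$valid[gap] <- TRUE
    series$filled[gap] <- TRUE
  }
  if (n_left > 0L) {
    sb_log("warning", "marker %s: %d gap(s) left unfilled", series$marker,
           n_left)
  }
  series
}

#' Zero-phase low-pass filter for anterior-posterior forces
#'
#' 4th-order Butterworth design applied forward-backward
#' (zero phase lag) to the AP component only; mediolateral and normal
#' components are returned untouched.
#'
#' @param series A [force_series()].
#' @param cutoff_hz Cutoff frequency (Hz), default 20.
#' @return The filtered series.
#' @export
lowpass_ap <- function(series, cutoff_hz = 20) {
  fs <- sampling_rate(series$time_s)
  if (cutoff_hz >= fs / 2) {
    abort(sprintf("cutoff %.1f Hz >= Nyquist (%.1f Hz)", cutoff_hz, fs / 2),
          class = "splitbelt_invalid_parameter")
  }
  bf <- signal::butter(4, cutoff_hz / (fs / 2), type = "low")
  x <- series$f_ap_n
  n <- length(x)
  # odd (point-symmetric) reflection padding suppresses the start/end
  # transients of the forward-backward pass
  np <- min(n - 1L, ceiling(20 * fs / cutoff_hz))
  xp <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[n] - x[(n - 1):(n - np)])
  yp <- as.numeric(signal::filtfilt(bf, xp))
  series$f_ap_n <- yp[(np + 1):(np + n)]
  series
}

#' Running median on the normal force channel
#'
#' Centered running median with the window shrinking at the series edges,
#' applied to the surface-normal component (used before the
#' offline 10 N heel-strike threshold).
#'
#' @param series A [force_series()].
#' @param window_ms Window length in ms (default 5; 5 samples at 1000 Hz).
#' @return The filtered series.
#' @export
median_filter_normal <- function(series, window_ms = 5) {
  fs <- sampling_rate(series$time_s)
  k <- max(1L, round(window_ms * fs / 1000))
  if (k %% 2L == 0L) k <- k + 1L
  series$f_normal_n <- if (k == 1L) series$f_normal_n else
    as.numeric(stats::runmed(series$f_normal_n, k, endrule = "median"))
  series
}
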