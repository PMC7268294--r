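# Spatial gait parameters in the treadmill-surface frame: step lengths at
# heel strike, step length asymmetry, and the decomposition of each step
# into leading (alpha) and trailing (X) leg positions about the hips.

#' Step length from ankle positions at heel strike
#'
#' Anterior-posterior (x) distance between the two ankle markers at the
#' leading leg's heel strike, leading minus trailing, anterior positive.
#'
#' @param ankle_lead_x,ankle_trail_x Surface-frame ankle x positions (mm)
#'   at the leading leg's heel-strike frame.
#' @return Step length in mm.
#' @export
step_length <- function(ankle_lead_x, ankle_trail_x) {
  ankle_lead_x - ankle_trail_x
}

#' Step length asymmetry
#'
#' `(SL_nonparetic - SL_paretic) / (SL_nonparetic + SL_paretic)`: zero for
#' equal step lengths, positive when the non-paretic (fast-belt) step is
#' longer. Unitless and scale-invariant, so comparable across subjects
#' walking at different speeds.
#'
#' @param sl_nonparetic,sl_paretic Step lengths (mm).
#' @return Unitless asymmetry in [-1, 1]; NA (with a flag upstream) when
#'   the stride length is non-positive.
#' @export
step_length_asymmetry <- function(sl_nonparetic, sl_paretic) {
  denom <- sl_nonparetic + sl_paretic
  out <- (sl_nonparetic - sl_paretic) / denom
  out[denom <= 0] <- NA_real_
  out
}

#' Leading and trailing leg orientations at heel strike
#'
#' The hip position (proxy for the body) is the mean of the two greater
#' trochanter x positions; alpha is the leading ankle relative to the hips
#' (positive when the foot lands ahead of the body), X the trailing ankle
#' relative to the hips (negative behind the body). alpha_lead - X_trail
#' equals the step length identically.
#'
#' @param ankle_lead_x,ankle_trail_x Ankle x positions (mm) at heel strike.
#' @param troch_l_x,troch_r_x Greater trochanter x positions (mm).
#' @return Named list with `alpha`, `x`, `hip_x` (mm).
#' @export
leg_orientations <- function(ankle_lead_x, ankle_trail_x, troch_l_x,
                             troch_r_x) {
  hip_x <- (troch_l_x + troch_r_x) / 2
  list(alpha = ankle_lead_x - hip_x, x = ankle_trail_x - hip_x,
       hip_x = hip_x)
}

# Marker x position at the kinematic frame nearest to a force-derived event
# time (<= 5 ms discretisation at 100 Hz). Returns NA when the frame is
# masked, which flags the stride as missing downstream.
marker_x_at <- function(series, t) {
  idx <- pmin(pmax(round((t - series$time_s[1]) *
                           sampling_rate(series$time_s)) + 1, 1),
              length(series$time_s))
  x <- series$xyz_mm[idx, 1]
  x[!series$valid[idx]] <- NA_real_
  x
}

# Per-stride spatial parameters for a paretic-referenced stride table.
# Each stride contributes two steps: the paretic step (at the paretic heel
# strike opening the stride) and the non-paretic step (at the contained
# contralateral heel strike).
stride_spatial <- function(strides, markers, paretic_side) {
  sides <- if (paretic_side == "left") {
    c(paretic = "ankle_L", nonparetic = "ankle_R")
  } else {
    c(paretic = "ankle_R", nonparetic = "ankle_L")
  }
  ank_p <- markers[[sides[["paretic"]]]]
  ank_n <- markers[[sides[["nonparetic"]]]]
  hip_l <- markers$troch_L
  hip_r <- markers$troch_R

  at_paretic_hs <- list(
    lead = marker_x_at(ank_p, strides$t_start),
    trail = marker_x_at(ank_n, strides$t_start),
    tl = marker_x_at(hip_l, strides$t_start),
    tr = marker_x_at(hip_r, strides$t_start))
  at_nonparetic_hs <- list(
    lead = marker_x_at(ank_n, strides$t_contra),
    trail = marker_x_at(ank_p, strides$t_contra),
    tl = marker_x_at(hip_l, strides$t_contra),
    tr = marker_x_at(hip_r, strides$t_contra))

  o_p <- leg_orientations(at_paretic_hs$lead, at_paretic_hs$trail,
                          at_paretic_hs$tl, at_paretic_hs$tr)
  o_n <- leg_orientations(at_nonparetic_hs$lead, at_nonparetic_hs$trail,
                          at_nonparetic_hs$tl, at_nonparetic_hs$tr)

  sl_p <- step_length(at_paretic_hs$lead, at_paretic_hs$trail)
  sl_n <- step_length(at_nonparetic_hs$lead, at_nonparetic_hs$trail)
  tibble(
    sl_paretic_mm = sl_p,
    sl_nonparetic_mm = sl_n,
    sla = step_length_asymmetry(sl_n, sl_p),
    alpha_paretic_mm = o_p$alpha,
    alpha_nonparetic_mm = o_n$alpha,
    x_paretic_mm = o_n$x,      # paretic leg trails at the non-paretic strike
    x_nonparetic_mm = o_p$x)   # and vice versa
}
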