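# Kinetic gait parameters: body-weight normalisation and per-stride peak
# propulsion from the anterior-posterior ground-reaction force. Slope-
# specific gravity biases are deliberately not removed here; epoch
# differencing downstream handles between-epoch comparisons.

#' Normalise forces by body mass
#'
#' @param force_n Force in N (vector).
#' @param mass_kg Body mass in kg (positive scalar).
#' @return Force in N/kg.
#' @export
normalize_force <- function(force_n, mass_kg) {
  stopif_not_scalar_pos(mass_kg, "mass_kg")
  force_n / mass_kg
}

#' Peak propulsion within one stance phase
#'
#' The propulsion peak is the maximum of the (low-pass filtered,
#' body-weight normalised) AP force between peak braking and stance end.
#' Anchoring the search at the braking minimum excludes the brief positive
#' AP transient that can immediately follow heel strike. If the AP force is
#' never negative during stance, the maximum over the second half of stance
#' is returned and the stride flagged atypical.
#'
#' @param ap Normalised AP force samples over the stance interval (N/kg).
#' @return List with `peak` (N/kg), `braking_min` (N/kg), `t_peak_idx`
#'   (index into `ap`), `atypical` (logical).
#' @export
peak_propulsion <- function(ap) {
  if (length(ap) == 0L || all(!is.finite(ap))) {
    return(list(peak = NA_real_, braking_min = NA_real_,
                t_peak_idx = NA_integer_, atypical = TRUE))
  }
  i_min <- which.min(ap)
  if (ap[i_min] >= 0) {
    half <- ap[seq.int(ceiling(length(ap) / 2), length(ap))]
    return(list(peak = max(half), braking_min = ap[i_min],
                t_peak_idx = ceiling(length(ap) / 2) + which.max(half) - 1L,
                atypical = TRUE))
  }
  seg <- ap[i_min:length(ap)]
  list(peak = max(seg), braking_min = ap[i_min],
       t_peak_idx = i_min + which.max(seg) - 1L, atypical = FALSE)
}

# Per-stride propulsion peaks for both legs. Each leg's AP force is read
# from its own belt's plate over [heel strike, stance end]; cross-stepping
# onto the wrong belt is not detected (documented limitation).
stride_kinetics <- function(strides, forces, paretic_side, mass_kg) {
  sides <- c(paretic = paretic_side,
             nonparetic = setdiff(c("left", "right"), paretic_side))
  out <- list()
  for (leg in names(sides)) {
    fser <- forces[[sides[[leg]]]]
    ap <- normalize_force(fser$f_ap_n, mass_kg)
    t0 <- if (leg == "paretic") strides$t_start else strides$t_contra
    t1 <- if (leg == "paretic") strides$t_stance_end_ref else
      strides$t_stance_end_other
    peak <- atyp <- rep(NA_real_, nrow(strides))
    tvec <- fser$time_s
    for (i in seq_len(nrow(strides))) {
      if (!is.finite(t0[i]) || !is.finite(t1[i])) next
      i0 <- findInterval(t0[i] - 1e-9, tvec) + 1L
      i1 <- findInterval(t1[i] - 1e-9, tvec)
      if (i1 < i0) next
      pk <- peak_propulsion(ap[i0:i1])
      peak[i] <- pk$peak
      atyp[i] <- as.numeric(pk$atypical)
    }
    out[[paste0("prop_", leg, "_nkg")]] <- peak
    out[[paste0("prop_", leg, "_atypical")]] <- as.logical(atyp)
  }
  as_tibble(out)
}
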