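# Synthetic split-belt trials: stride-parameter truth series with
# exponential adaptation / washout dynamics, plus raw marker and force
# signals carrying that truth, so the full pipeline can be validated
# against known values without motion-capture data. Waveforms are
# phenomenological templates (no musculoskeletal simulation): they have the
# qualitative shape of human gait signals and exercise every detector and
# extraction rule.

#' Adaptation dynamics for one stride parameter
#'
#' Within the adaptation epoch the parameter follows
#' `p(s) = p_ss + (p0 - p_ss) * exp(-s / tau)` (s = 0, 1, ... strides from
#' epoch start); within post-adaptation it follows
#' `baseline_mid + a0 * exp(-s / tau_w)`; baseline epochs are stationary
#' around their stated means. I.i.d. Gaussian stride-to-stride noise with
#' `noise_sd` is added on top.
#'
#' @param baseline_mid Mean during the mid-speed baseline epoch.
#' @param p0,p_ss Initial and steady-state value during adaptation.
#' @param tau Adaptation time constant (strides, > 0).
#' @param a0 After-effect at the first post-adaptation stride.
#' @param tau_w Washout time constant (strides, > 0).
#' @param noise_sd Stride-to-stride noise SD (>= 0).
#' @param baseline_slow Mean during the slow baseline epoch (defaults to
#'   `baseline_mid`).
#' @return Object of class `adapt_param`.
#' @export
adapt_param <- function(baseline_mid, p0 = baseline_mid,
                        p_ss = baseline_mid, tau = 45, a0 = 0, tau_w = 12,
                        noise_sd = 0, baseline_slow = NULL) {
  if (!is.numeric(tau) || tau <= 0 || !is.numeric(tau_w) || tau_w <= 0) {
    abort("`tau` and `tau_w` must be positive",
          class = "splitbelt_invalid_parameter")
  }
  if (noise_sd < 0) {
    abort("`noise_sd` must be >= 0", class = "splitbelt_invalid_parameter")
  }
  structure(list(baseline_mid = baseline_mid,
                 baseline_slow = baseline_slow %||% baseline_mid,
                 p0 = p0, p_ss = p_ss, tau = tau, a0 = a0, tau_w = tau_w,
                 noise_sd = noise_sd),
            class = "adapt_param")
}

#' Generate stride-by-stride true parameter series
#'
#' @param params Named list of [adapt_param()] objects, one per parameter.
#' @param epoch_plan Tibble with `epoch` and `planned_strides` (e.g. from
#'   [default_epoch_plan()]).
#' @param seed Integer seed; identical seeds give identical series.
#' @return Tibble with `stride_idx`, `epoch`, `epoch_stride` and one column
#'   per parameter.
#' @export
generate_stride_series <- function(params, epoch_plan, seed = 1L) {
  if (is.null(names(params)) || any(names(params) == "")) {
    abort("`params` must be a named list", class = "splitbelt_invalid_parameter")
  }
  set.seed(seed)
  out <- tibble(
    stride_idx = seq_len(sum(epoch_plan$planned_strides)),
    epoch = rep(epoch_plan$epoch, epoch_plan$planned_strides),
    epoch_stride = unlist(lapply(epoch_plan$planned_strides, seq_len)))
  s <- out$epoch_stride - 1L   # 0-indexed within epoch
  for (nm in names(params)) {
    p <- params[[nm]]
    if (!inherits(p, "adapt_param")) {
      abort(sprintf("params$%s is not an adapt_param", nm),
            class = "splitbelt_invalid_parameter")
    }
    mu <- numeric(nrow(out))
    for (ep in unique(out$epoch)) {
      i <- out$epoch == ep
      mu[i] <- switch(ep,
        baseline_slow = p$baseline_slow,
        baseline_mid = p$baseline_mid,
        adaptation = p$p_ss + (p$p0 - p$p_ss) * exp(-s[i] / p$tau),
        post_adaptation = p$baseline_mid + p$a0 * exp(-s[i] / p$tau_w))
    }
    out[[nm]] <- mu + rnorm(nrow(out), 0, p$noise_sd)
  }
  out
}

#' Default truth dynamics for a synthetic session
#'
#' Speed- and slope-scaled defaults for the six primitive stride
#' parameters (leading position alpha, trailing position X and peak
#' propulsion P, per leg): magnitudes scale with the belt speed the leg
#' walks on (alpha about 252 v mm, X about -348 v mm, P about 1.6 v N/kg),
#' inclination shifts X backward and adds the gravitational component
#' g sin(slope) to propulsion, and the paretic leg carries a fixed deficit
#' factor. Adaptation starts with an overshoot past the speed-specific
#' steady state (onset perturbation) and decays exponentially; post-
#' adaptation retains half the adaptation shift, with the trailing-position
#' after-effect swapped between legs (ipsilateral alpha, contralateral X
#' retention).
#'
#' @param config [protocol_config()].
#' @param noise `"none"` for noise-free truth or `"realistic"` for
#'   stride-to-stride SDs of 8 mm (positions) and 0.06 N/kg (propulsion).
#' @return Named list of [adapt_param()] for `alpha_paretic`,
#'   `alpha_nonparetic`, `x_paretic`, `x_nonparetic`, `prop_paretic`,
#'   `prop_nonparetic`.
#' @export
default_adaptation_params <- function(config,
                                      noise = c("realistic", "none")) {
  noise <- match.arg(noise)
  sn <- sin(config$slope_deg * pi / 180)
  alpha_f <- function(v, paretic) 252 * v * (if (paretic) 0.92 else 1)
  x_f <- function(v) -348 * v - 150 * sn
  prop_f <- function(v, paretic) (1.6 * v + 9.81 * sn) *
    (if (paretic) 0.75 else 1)
  pos_sd <- if (noise == "realistic") 8 else 0
  prop_sd <- if (noise == "realistic") 0.06 else 0
  kappa <- 1.6   # onset overshoot
  rho <- 0.5     # post-adaptation retention
  mk <- function(f, v_adapt, a0, sdv, ...) {
    bm <- f(config$mid_speed, ...)
    ss <- f(v_adapt, ...)
    adapt_param(baseline_mid = bm, p0 = bm + kappa * (ss - bm), p_ss = ss,
                tau = 45, a0 = a0, tau_w = 12, noise_sd = sdv,
                baseline_slow = f(config$slow_speed, ...))
  }
  x_p_ss <- x_f(config$slow_speed)
  x_np_ss <- x_f(config$fast_speed)
  x_bm <- x_f(config$mid_speed)
  list(
    alpha_paretic = mk(alpha_f, config$slow_speed,
                       a0 = rho * (alpha_f(config$slow_speed, TRUE) -
                                     alpha_f(config$mid_speed, TRUE)),
                       sdv = pos_sd, paretic = TRUE),
    alpha_nonparetic = mk(alpha_f, config$fast_speed,
                          a0 = rho * (alpha_f(config$fast_speed, FALSE) -
                                        alpha_f(config$mid_speed, FALSE)),
                          sdv = pos_sd, paretic = FALSE),
    x_paretic = mk(x_f, config$slow_speed,
                   a0 = rho * (x_np_ss - x_bm), sdv = pos_sd),
    x_nonparetic = mk(x_f, config$fast_speed,
                      a0 = rho * (x_p_ss - x_bm), sdv = pos_sd),
    prop_paretic = mk(prop_f, config$slow_speed,
                      a0 = -0.2 * (prop_f(config$slow_speed, TRUE) -
                                     prop_f(config$mid_speed, TRUE)),
                      sdv = prop_sd, paretic = TRUE),
    prop_nonparetic = mk(prop_f, config$fast_speed,
                         a0 = -0.4 * (prop_f(config$fast_speed, FALSE) -
                                        prop_f(config$mid_speed, FALSE)),
                         sdv = prop_sd, paretic = FALSE))
}

# belt speed (m/s) for a leg in an epoch, from the epoch plan
belt_speed_for <- function(config, epoch, leg) {
  row <- config$epoch_plan[config$epoch_plan$epoch == epoch, ]
  side <- if (leg == "paretic") config$paretic_side else
    setdiff(c("left", "right"), config$paretic_side)
  if (side == "left") row$left_belt_speed else row$right_belt_speed
}

#' Synthesize raw marker and force signals from a truth series
#'
#' Builds a full recording in the treadmill-surface frame and rotates it to
#' the lab frame by the session slope (the analysis must undo the
#' rotation): per stance a two-Gaussian normal-force waveform scaled to
#' body weight (zero in swing, crossing the 30 N detection threshold at the
#' scheduled heel strike), a biphasic braking-then-propulsion AP waveform
#' whose propulsion maximum encodes the stride's true peak (with an
#' optional brief positive transient after heel strike to exercise the
#' exclusion rule), ankle markers that land at hip + alpha and travel
#' backward at belt speed until the contralateral strike at hip + X, and
#' hip markers oscillating smoothly about a fixed point. Heel strikes are
#' scheduled on the 100 Hz kinematic frame grid and the attained alpha/X at
#' the scheduled frames are recorded, so the returned truth is exactly
#' consistent with the emitted signals. Resting breaks between epochs are
#' zero-force gaps (no steps taken).
#'
#' @param truth Truth series from [generate_stride_series()] containing the
#'   six primitive parameters of [default_adaptation_params()].
#' @param config [protocol_config()]; its epoch plan must match `truth`.
#' @param seed Integer seed for the sensor noise.
#' @param marker_noise_mm,force_noise_n White sensor noise SDs.
#' @param include_transient Add the early-stance positive AP transient?
#' @return A [trial_recording()] (lab frame) with the attained stride truth
#'   in `attr(x, "truth")`.
#' @export
synthesize_trial <- function(truth, config, seed = 1L,
                             marker_noise_mm = 0.5, force_noise_n = 1,
                             include_transient = TRUE) {
  set.seed(seed + 1L)
  mfs <- 100; ffs <- 1000
  mass <- config$mass_kg; g <- 9.81
  hipA <- 8; hipf <- 0.9; hip_wob <- 5
  hip_x <- function(t) hipA * sin(2 * pi * hipf * t)
  snap <- function(t) round(t * mfs) / mfs

  plan <- config$epoch_plan
  if (!identical(as.character(rle(truth$epoch)$values), plan$epoch) ||
      !identical(rle(truth$epoch)$lengths,
                 as.integer(plan$planned_strides))) {
    abort("truth series does not match the config epoch plan",
          class = "splitbelt_invalid_parameter")
  }

  # --- schedule heel strikes; record attained trailing positions --------
  # landings[[leg]]: time, alpha (desired, attained exactly at the snapped
  # frame because the ankle is placed relative to the hip), belt speed,
  # true peak propulsion for that stance
  land_p <- list(); land_n <- list()
  sched <- list()
  attained <- truth
  attained$t_start <- NA_real_
  attained$t_contra <- NA_real_
  attained$t_end <- NA_real_
  cursor <- 2.0
  rest_after <- c(baseline_slow = 5, baseline_mid = 5, adaptation = 1,
                  post_adaptation = 0)
  for (e in seq_len(nrow(plan))) {
    ep <- plan$epoch[e]
    rows <- which(truth$epoch == ep)
    v_p <- belt_speed_for(config, ep, "paretic") * 1000   # mm/s
    v_n <- belt_speed_for(config, ep, "nonparetic") * 1000
    ep_t0 <- cursor - 0.2
    # non-paretic lead-in step
    t_np_prev <- snap(cursor)
    a_np_prev <- truth$alpha_nonparetic[rows[1]]
    land_n[[length(land_n) + 1L]] <-
      c(t_np_prev, a_np_prev, v_n, truth$prop_nonparetic[rows[1]])
    t_p <- numeric(length(rows) + 1L)
    t_np <- numeric(length(rows))
    for (k in seq_along(rows)) {
      i <- rows[k]
      # non-paretic -> paretic step; trailing non-paretic reaches x_np
      t1 <- snap(t_np_prev +
                   (a_np_prev - truth$x_nonparetic[i]) / v_n)
      attained$x_nonparetic[i] <-
        (hip_x(t_np_prev) + a_np_prev - v_n * (t1 - t_np_prev)) - hip_x(t1)
      t_p[k] <- t1
      land_p[[length(land_p) + 1L]] <-
        c(t1, truth$alpha_paretic[i], v_p, truth$prop_paretic[i])
      # paretic -> non-paretic step; trailing paretic reaches x_p
      t2 <- snap(t1 + (truth$alpha_paretic[i] - truth$x_paretic[i]) / v_p)
      attained$x_paretic[i] <-
        (hip_x(t1) + truth$alpha_paretic[i] - v_p * (t2 - t1)) - hip_x(t2)
      t_np[k] <- t2
      land_n[[length(land_n) + 1L]] <-
        c(t2, truth$alpha_nonparetic[i], v_n, truth$prop_nonparetic[i])
      t_np_prev <- t2
      a_np_prev <- truth$alpha_nonparetic[i]
    }
    # closing paretic strike ends the last stride of the epoch
    iN <- rows[length(rows)]
    t1 <- snap(t_np_prev + (a_np_prev - truth$x_nonparetic[iN]) / v_n)
    t_p[length(rows) + 1L] <- t1
    land_p[[length(land_p) + 1L]] <-
      c(t1, truth$alpha_paretic[iN], v_p, truth$prop_paretic[iN])
    attained$t_start[rows] <- t_p[seq_along(rows)]
    attained$t_contra[rows] <- t_np
    attained$t_end[rows] <- t_p[seq_along(rows) + 1L]
    ep_t1 <- t1 + 1.2
    sched[[e]] <- tibble(epoch = ep, t_start = ep_t0, t_end = ep_t1,
                         left_belt_speed = plan$left_belt_speed[e],
                         right_belt_speed = plan$right_belt_speed[e])
    cursor <- ep_t1 + rest_after[[ep]] + 0.2
  }
  schedule <- dplyr::bind_rows(sched)
  land_p <- do.call(rbind, land_p); land_n <- do.call(rbind, land_n)

  # --- stance intervals per leg -----------------------------------------
  # Stance covers ~62% of the own stride and must extend past the
  # contralateral strike (double support) so the trailing position is
  # attained while the foot is still belt-bound; it must also leave a
  # swing gap before the next own strike. Epoch-final stances (next events
  # only after a resting gap) fall back to a nominal stride duration.
  stance_for <- function(land, land_other) {
    n <- nrow(land)
    t_next <- c(land[-1, 1], NA)
    T_own <- pmin(t_next - land[, 1], 1.6)
    T_own[is.na(T_own)] <- if (n > 1) T_own[n - 1] else 1.2
    contra <- vapply(land[, 1], function(t0) {
      cand <- land_other[land_other[, 1] > t0, 1]
      if (length(cand)) cand[1] else Inf
    }, numeric(1))
    needs_cover <- is.finite(contra) & (contra - land[, 1]) < 1.2
    se <- land[, 1] + 0.62 * T_own
    se[needs_cover] <- pmax(se, contra + 0.12 * T_own)[needs_cover]
    within <- !is.na(t_next) & (t_next - land[, 1]) < 2.5
    se[within] <- pmin(se, t_next - pmax(0.15, 0.25 * T_own))[within]
    if (any(needs_cover & se <= contra)) {
      abort("stride duration too short for the stance templates",
            class = "splitbelt_generation_error")
    }
    se
  }
  se_p <- stance_for(land_p, land_n)
  se_n <- stance_for(land_n, land_p)

  t_end_rec <- max(se_p, se_n) + 1
  mt <- seq(0, t_end_rec, by = 1 / mfs)
  ft <- seq(0, t_end_rec, by = 1 / ffs)
  # indices i with t0 <= grid[i] < t1 on a uniform grid starting at 0
  idx_range <- function(t0, t1, fs, n) {
    i0 <- max(1L, as.integer(ceiling(t0 * fs - 1e-9)) + 1L)
    i1 <- min(n, as.integer(ceiling(t1 * fs - 1e-9)))
    if (i1 < i0) integer(0) else i0:i1
  }

  # --- ankle trajectories (surface frame) -------------------------------
  ankle_traj <- function(land, se) {
    x <- numeric(length(mt)); z <- numeric(length(mt))
    n <- nrow(land)
    x[] <- hip_x(land[1, 1]) + land[1, 2]; z[] <- 40
    for (j in seq_len(n)) {
      L <- land[j, 1]; P <- hip_x(L) + land[j, 2]; v <- land[j, 3]
      i_st <- idx_range(L, se[j], mfs, length(mt))
      x[i_st] <- P - v * (mt[i_st] - L)
      z[i_st] <- 40
      x_lift <- P - v * (se[j] - L)
      if (j < n) {
        Lnext <- land[j + 1, 1]
        i_sw <- idx_range(se[j], Lnext, mfs, length(mt))
        u <- (mt[i_sw] - se[j]) / (Lnext - se[j])
        x1 <- hip_x(Lnext) + land[j + 1, 2]
        x[i_sw] <- x_lift + (x1 - x_lift) * (1 - cos(pi * u)) / 2
        z[i_sw] <- 40 + 80 * sin(pi * pmin(u, 1))
      } else {
        x[mt >= se[j]] <- x_lift
      }
    }
    list(x = x, z = z)
  }
  tr_p <- ankle_traj(land_p, se_p)
  tr_n <- ankle_traj(land_n, se_n)

  hip_xs <- hip_x(mt)
  wob <- hip_wob * sin(2 * pi * 1.3 * mt)
  mk_marker <- function(name, x, y, z) {
    xyz <- cbind(x + rnorm(length(mt), 0, marker_noise_mm),
                 y + rnorm(length(mt), 0, marker_noise_mm),
                 z + rnorm(length(mt), 0, marker_noise_mm))
    marker_series(name, mt, xyz, frame = "surface")
  }
  p_is_left <- config$paretic_side == "left"
  markers <- list(
    ankle_L = mk_marker("ankle_L", if (p_is_left) tr_p$x else tr_n$x, 120,
                        if (p_is_left) tr_p$z else tr_n$z),
    ankle_R = mk_marker("ankle_R", if (p_is_left) tr_n$x else tr_p$x, -120,
                        if (p_is_left) tr_n$z else tr_p$z),
    troch_L = mk_marker("troch_L", hip_xs + wob, 170,
                        900 + 15 * sin(2 * pi * 1.8 * mt)),
    troch_R = mk_marker("troch_R", hip_xs - wob, -170,
                        900 + 15 * cos(2 * pi * 1.8 * mt)))

  # --- force waveforms (surface frame) ----------------------------------
  force_traj <- function(land, se) {
    prop_nkg <- land[, 4]
    fn <- numeric(length(ft)); fap <- numeric(length(ft))
    for (j in seq_len(nrow(land))) {
      i_st <- idx_range(land[j, 1], se[j], ffs, length(ft))
      phi <- (ft[i_st] - land[j, 1]) / (se[j] - land[j, 1])
      fn[i_st] <- 1.1 * mass * g *
        (exp(-0.5 * ((phi - 0.25) / 0.13)^2) +
           exp(-0.5 * ((phi - 0.75) / 0.13)^2))
      P <- prop_nkg[j] * mass
      B <- max(0.3 * mass, 0.8 * P)
      ap <- ifelse(phi <= 0.5, -B * sin(2 * pi * phi),
                   P * sin(2 * pi * (phi - 0.5)))
      if (include_transient) {
        ap <- ap + 0.3 * mass * exp(-0.5 * ((phi - 0.03) / 0.012)^2)
      }
      fap[i_st] <- ap
    }
    list(fn = fn, fap = fap)
  }
  f_p <- force_traj(land_p, se_p)
  f_n <- force_traj(land_n, se_n)

  mk_force <- function(side, f) {
    force_series(side, ft,
                 f_ap_n = f$fap + rnorm(length(ft), 0, force_noise_n),
                 f_ml_n = rnorm(length(ft), 0, force_noise_n),
                 f_normal_n = f$fn + rnorm(length(ft), 0, force_noise_n),
                 frame = "surface")
  }
  forces <- list(left = mk_force("left", if (p_is_left) f_p else f_n),
                 right = mk_force("right", if (p_is_left) f_n else f_p))

  # rotate everything into the lab frame; the analysis undoes this
  to_lab <- function(s) {
    s <- rotate_to_surface(s, -config$slope_deg)
    s$frame <- "lab"
    s
  }
  markers <- lapply(markers, to_lab)
  forces <- lapply(forces, to_lab)

  attained$sl_paretic_mm <- attained$alpha_paretic - attained$x_nonparetic
  attained$sl_nonparetic_mm <- attained$alpha_nonparetic - attained$x_paretic
  attained$sla <- step_length_asymmetry(attained$sl_nonparetic_mm,
                                        attained$sl_paretic_mm)
  trial <- trial_recording(markers, forces, config, schedule)
  attr(trial, "truth") <- attained
  trial
}

#' Simulate a complete synthetic session
#'
#' Convenience wrapper: builds (or accepts) truth dynamics, generates the
#' stride series and synthesizes the raw recording.
#'
#' @param config [protocol_config()].
#' @param seed Integer seed controlling truth noise and sensor noise.
#' @param params Optional named list of [adapt_param()]; defaults to
#'   [default_adaptation_params()].
#' @param noise `"realistic"` or `"none"` (truth and sensor noise).
#' @param ... Passed to [synthesize_trial()].
#' @return List with `trial` ([trial_recording()]) and `truth` (attained
#'   stride truth tibble).
#' @export
simulate_session <- function(config, seed = 1L, params = NULL,
                             noise = c("realistic", "none"), ...) {
  noise <- match.arg(noise)
  params <- params %||% default_adaptation_params(config, noise = noise)
  truth0 <- generate_stride_series(params, config$epoch_plan, seed = seed)
  sens <- if (noise == "none") list(marker_noise_mm = 0, force_noise_n = 0)
    else list(marker_noise_mm = 0.5, force_noise_n = 1)
  args <- utils::modifyList(sens, list(...))
  trial <- do.call(synthesize_trial,
                   c(list(truth = truth0, config = config, seed = seed),
                     args))
  list(trial = trial, truth = attr(trial, "truth"))
}
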