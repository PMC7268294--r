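# Shared fixtures: a small protocol, a cached noise-free synthetic session
# (built once per test run), and independent brute-force oracles for event
# detection and peak-propulsion extraction.

small_config <- function(slope_deg = 0, paretic_side = "right",
                         mid_speed = 0.75, n_adaptation = 120L,
                         n_post = 40L) {
  protocol_config(
    subject_id = "T1", mass_kg = 70, paretic_side = paretic_side,
    slope_deg = slope_deg, mid_speed = mid_speed,
    epoch_plan = default_epoch_plan(mid_speed, paretic_side,
                                    include_slow_baseline = slope_deg == 0,
                                    n_baseline = 50L,
                                    n_adaptation = n_adaptation,
                                    n_post = n_post))
}

.session_cache <- new.env(parent = emptyenv())

# noise-free end-to-end session shared across test files
noise_free_session <- function() {
  if (is.null(.session_cache$nf)) {
    cfg <- small_config()
    sim <- simulate_session(cfg, seed = 3, noise = "none")
    st <- suppressMessages(extract_strides(sim$trial))
    .session_cache$nf <- list(config = cfg, trial = sim$trial,
                              truth = sim$truth, stride_table = st)
  }
  .session_cache$nf
}

# join extracted strides to generator truth by (rounded) start time
match_truth <- function(stride_table, truth) {
  stride_table$key <- round(stride_table$t_start, 6)
  truth$key <- round(truth$t_start, 6)
  merge(stride_table, truth, by = "key", suffixes = c("", "_true"))
}

# Literal brute-force event oracle: enumerate runs with explicit loops,
# merge sub-min_swing unloaded runs lying strictly between loaded runs,
# then discard sub-min_stance loaded runs, then read events off the runs.
oracle_events <- function(f, thr, min_stance, min_swing) {
  n <- length(f)
  above <- f >= thr
  runs <- list(); i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && above[j + 1L] == above[i]) j <- j + 1L
    runs[[length(runs) + 1L]] <- list(start = i, end = j, up = above[i])
    i <- j + 1L
  }
  if (length(runs) > 2L) {
    keep <- rep(TRUE, length(runs))
    for (k in 2:(length(runs) - 1L)) {
      r <- runs[[k]]
      if (!r$up && (r$end - r$start + 1L) < min_swing) runs[[k]]$up <- TRUE
    }
    # coalesce adjacent loaded runs
    merged <- list(runs[[1]])
    for (k in 2:length(runs)) {
      last <- merged[[length(merged)]]
      if (runs[[k]]$up == last$up) {
        merged[[length(merged)]]$end <- runs[[k]]$end
      } else {
        merged[[length(merged) + 1L]] <- runs[[k]]
      }
    }
    runs <- merged
  }
  runs <- Filter(function(r) !(r$up && (r$end - r$start + 1L) < min_stance),
                 runs)
  hs <- vapply(Filter(function(r) r$up, runs), function(r) r$start,
               numeric(1))
  se <- vapply(Filter(function(r) r$up, runs), function(r) r$end + 1L,
               numeric(1))
  list(heel_strike = as.integer(hs), stance_end = as.integer(se[se <= n]))
}

# literal peak-propulsion oracle: scan for the braking minimum, then scan
# forward for the maximum; all-nonnegative stance falls back to the
# second-half maximum
oracle_peak <- function(ap) {
  i_min <- 1L
  for (i in seq_along(ap)) if (ap[i] < ap[i_min]) i_min <- i
  if (ap[i_min] >= 0) {
    lo <- ceiling(length(ap) / 2)
    best <- -Inf
    for (i in lo:length(ap)) if (ap[i] > best) best <- ap[i]
    return(best)
  }
  best <- -Inf
  for (i in i_min:length(ap)) if (ap[i] > best) best <- ap[i]
  best
}

# random piecewise-constant force trace (levels and durations random) that
# exercises debouncing, for oracle-equivalence properties
random_force_trace <- function(fs = 200, dur_s = 5) {
  n <- fs * dur_s
  f <- numeric(0)
  while (length(f) < n) {
    len <- sample(2:80, 1)
    lev <- sample(c(0, runif(1, 0, 100)), 1, prob = c(0.4, 0.6))
    f <- c(f, rep(lev, len))
  }
  f <- f[1:n]
  force_series("left", seq(0, by = 1 / fs, length.out = n),
               f_ap_n = numeric(n), f_ml_n = numeric(n), f_normal_n = f)
}

# independent projection oracle: closed-form balanced sums of squares for
# a two-factor within-subject design (cell means and marginal means)
oracle_within_ss <- function(d) {
  g <- mean(d$y)
  A <- nlevels(factor(d$a)); B <- nlevels(factor(d$b))
  n <- nlevels(factor(d$s))
  m_s <- tapply(d$y, d$s, mean); m_a <- tapply(d$y, d$a, mean)
  m_b <- tapply(d$y, d$b, mean)
  m_ab <- tapply(d$y, list(d$a, d$b), mean)
  m_as <- tapply(d$y, list(d$a, d$s), mean)
  m_bs <- tapply(d$y, list(d$b, d$s), mean)
  ss <- list(
    subject = A * B * sum((m_s - g)^2),
    a = n * B * sum((m_a - g)^2),
    b = n * A * sum((m_b - g)^2))
  ss$ab <- n * sum((m_ab - outer(m_a, rep(1, B)) -
                      outer(rep(1, A), m_b) + g)^2)
  ss$as <- B * sum((m_as - outer(m_a, rep(1, n)) -
                      outer(rep(1, A), m_s) + g)^2)
  ss$bs <- A * sum((m_bs - outer(m_b, rep(1, n)) -
                      outer(rep(1, B), m_s) + g)^2)
  ss$total <- sum((d$y - g)^2)
  ss$abs <- ss$total - ss$subject - ss$a - ss$b - ss$ab - ss$as - ss$bs
  ss
}
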