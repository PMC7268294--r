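test_that("stride series follow the exponential adaptation model", {
  plan <- tibble::tibble(epoch = c("baseline_mid", "adaptation",
                                   "post_adaptation"),
                         planned_strides = c(5L, 60L, 20L))
  par <- list(sla = adapt_param(baseline_mid = 0.1, p0 = -0.2,
                                p_ss = -0.05, tau = 50, a0 = 0.15,
                                tau_w = 10, noise_sd = 0))
  tr <- generate_stride_series(par, plan, seed = 1)
  ad <- tr$sla[tr$epoch == "adaptation"]
  # s = 0 gives p0; s = 50 gives the closed-form value
  expect_equal(ad[1], -0.2)
  expect_equal(ad[51], -0.05 + (-0.2 - -0.05) * exp(-1), tolerance = 1e-12)
  expect_equal(round(ad[51], 4), -0.1052)
  # baseline stationary at its mean; washout decays toward baseline
  expect_equal(tr$sla[tr$epoch == "baseline_mid"], rep(0.1, 5))
  po <- tr$sla[tr$epoch == "post_adaptation"]
  expect_equal(po[1], 0.1 + 0.15)
  expect_equal(po[20], 0.1 + 0.15 * exp(-19 / 10), tolerance = 1e-12)

  # tau -> 0+ collapses to the steady state after the first stride
  par2 <- list(p = adapt_param(0, p0 = 1, p_ss = 3, tau = 1e-9))
  tr2 <- generate_stride_series(par2, plan, seed = 1)
  expect_equal(tr2$p[tr2$epoch == "adaptation"][-1], rep(3, 59))

  expect_error(adapt_param(0, tau = 0), class = "splitbelt_invalid_parameter")
  expect_error(adapt_param(0, noise_sd = -1),
               class = "splitbelt_invalid_parameter")
})

test_that("identical seeds give bit-identical trials", {
  cfg <- small_config(n_adaptation = 50L, n_post = 10L)
  a <- simulate_session(cfg, seed = 9, noise = "realistic")
  b <- simulate_session(cfg, seed = 9, noise = "realistic")
  expect_identical(a$truth, b$truth)
  expect_identical(a$trial$markers$ankle_L$xyz_mm,
                   b$trial$markers$ankle_L$xyz_mm)
  expect_identical(a$trial$forces$left$f_ap_n, b$trial$forces$left$f_ap_n)
  c_ <- simulate_session(cfg, seed = 10, noise = "realistic")
  expect_false(identical(a$truth, c_$truth))
})

test_that("the slope rotation embeds the belt direction correctly", {
  cfg <- small_config(slope_deg = 8.5, mid_speed = 0.7)
  sim <- simulate_session(cfg, seed = 5, noise = "none")
  expect_equal(sim$trial$markers$ankle_L$frame, "lab")
  # a surface-frame displacement along the belt appears in the lab frame
  # tilted by the slope: undoing the rotation must recover pure +x motion
  mk <- rotate_to_surface(sim$trial$markers$troch_L, 8.5)
  z_range <- diff(range(mk$xyz_mm[, 3]))
  z_range_lab <- diff(range(sim$trial$markers$ankle_L$xyz_mm[, 3]))
  expect_lt(z_range, 50)        # surface frame: only the bobbing remains
  expect_gt(z_range_lab, 100)   # lab frame mixes x travel into z
})

test_that("full-loop recovery holds for the incline session too", {
  cfg <- small_config(slope_deg = 8.5, n_adaptation = 60L, n_post = 20L)
  sim <- simulate_session(cfg, seed = 7, noise = "none")
  st <- suppressMessages(extract_strides(sim$trial))
  m <- match_truth(st, sim$truth)
  expect_equal(nrow(m), nrow(sim$truth))
  expect_lt(max(abs(m$alpha_paretic_mm - m$alpha_paretic)), 2)
  expect_lt(max(abs(m$x_nonparetic_mm - m$x_nonparetic)), 2)
  expect_lt(max(abs(m$sla - m$sla_true)), 0.005)
  expect_lt(max(abs(m$prop_paretic_nkg / m$prop_paretic - 1)), 0.01)
  # sign conventions: landing ahead of the hips, trailing behind
  expect_true(all(m$alpha_paretic > 0 & m$alpha_nonparetic > 0))
  expect_true(all(m$x_paretic < 0 & m$x_nonparetic < 0))
})

test_that("a truth/plan mismatch and short strides raise generation errors", {
  cfg <- small_config(n_adaptation = 50L, n_post = 10L)
  par <- default_adaptation_params(cfg, noise = "none")
  other_plan <- default_epoch_plan(0.75, "right", TRUE, 50L, 60L, 10L)
  tr <- generate_stride_series(par, other_plan, seed = 1)
  expect_error(synthesize_trial(tr, cfg, seed = 1),
               class = "splitbelt_invalid_parameter")
})
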