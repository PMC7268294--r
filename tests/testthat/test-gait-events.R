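test_that("detector matches the brute-force scan oracle on random traces", {
  set.seed(21)
  for (rep in 1:100) {
    f <- random_force_trace()
    ev <- detect_stance(f, threshold_n = 10, min_stance_ms = 100,
                        min_swing_ms = 100)
    # 200 Hz, 100 ms -> 20 samples
    orc <- oracle_events(f$f_normal_n, 10, 20L, 20L)
    expect_identical(ev$sample_idx[ev$kind == "heel_strike"],
                     orc$heel_strike)
    expect_identical(ev$sample_idx[ev$kind == "stance_end"],
                     orc$stance_end)
  }
})

test_that("degenerate and debounced inputs produce no spurious events", {
  t1k <- seq(0, 1, by = 1e-3)
  n <- length(t1k)
  zero <- force_series("left", t1k, numeric(n), numeric(n), numeric(n))
  expect_equal(nrow(suppressMessages(detect_stance(zero, 10))), 0L)

  # 2-sample 50 N blip in swing is debounced away
  blip <- numeric(n); blip[500:501] <- 50
  fs <- force_series("left", t1k, numeric(n), numeric(n), blip)
  expect_equal(nrow(suppressMessages(
    detect_stance(fs, 10, min_stance_ms = 50))), 0L)

  # a short unloaded dip inside stance does not split it
  stance <- numeric(n); stance[101:500] <- 600; stance[300:302] <- 0
  fdip <- force_series("left", t1k, numeric(n), numeric(n), stance)
  ev <- detect_stance(fdip, 10)
  expect_equal(sum(ev$kind == "heel_strike"), 1L)
  expect_equal(ev$sample_idx[ev$kind == "heel_strike"], 101L)
  expect_equal(ev$sample_idx[ev$kind == "stance_end"], 501L)
})

test_that("strides are consecutive same-leg strikes with one contralateral", {
  mk_ev <- function(times, side) tibble::tibble(
    time_s = times, kind = "heel_strike",
    sample_idx = as.integer(times * 1000), side = side)
  left <- mk_ev(c(0.0, 1.2), "left")
  right <- mk_ev(c(0.6, 1.8), "right")
  st <- segment_strides(left, right, ref_leg = "left",
                        other_leg = "right")
  expect_equal(nrow(st), 1L)
  expect_equal(st$t_start, 0.0)
  expect_equal(st$t_contra, 0.6)
  expect_equal(st$t_end, 1.2)

  # a missing contralateral strike drops that stride only
  left3 <- mk_ev(c(0, 1.2, 2.4, 3.6), "left")
  right3 <- mk_ev(c(0.6, 3.0), "right")    # nothing in [1.2, 2.4)
  st3 <- suppressMessages(segment_strides(left3, right3, "left", "right"))
  expect_equal(nrow(st3), 2L)
  expect_equal(st3$t_start, c(0, 2.4))

  expect_equal(nrow(suppressMessages(
    segment_strides(mk_ev(0.5, "left"), right, "left", "right"))), 0L)
})

test_that("epoch labels follow the schedule and transitions drop strides", {
  sched <- tibble::tibble(
    epoch = c("baseline_mid", "adaptation", "post_adaptation"),
    t_start = c(0, 10, 20), t_end = c(10, 20, 30),
    left_belt_speed = c(1, 0.67, 1), right_belt_speed = c(1, 1.33, 1))
  strides <- tibble::tibble(
    stride_idx = 1:4, lead_leg = "paretic",
    t_start = c(1.0, 9.5, 12.0, 21.0), t_contra = c(1.5, 9.9, 12.5, 21.5),
    t_end = c(2.0, 10.5, 13.0, 22.0),
    t_stance_end_ref = NA_real_, t_stance_end_other = NA_real_)
  out <- suppressMessages(assign_epochs(strides, sched))
  expect_equal(out$epoch, c("baseline_mid", "adaptation",
                            "post_adaptation"))
  expect_false(9.5 %in% out$t_start)   # straddles the tied->split change

  expect_error(assign_epochs(strides, sched[-2, ]), "adaptation",
               class = "splitbelt_schema_error")
})

test_that("online (30 N raw) and offline (10 N filtered) strikes agree", {
  ses <- noise_free_session()
  cfg <- ses$config
  f <- rotate_to_surface(ses$trial$forces$right, cfg$slope_deg)
  cmp <- compare_threshold_modes(f, cfg$processing)
  expect_gt(nrow(cmp), 200)
  expect_lt(max(abs(cmp$dt_s)), 0.010)
})

test_that("stride counts per epoch equal the generator truth", {
  ses <- noise_free_session()
  counts <- table(ses$stride_table$epoch)
  plan <- ses$config$epoch_plan
  expect_equal(as.integer(counts[plan$epoch]), plan$planned_strides)
})
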