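test_that("belt speeds derive from the mid speed with half-away rounding", {
  expect_equal(derive_belt_speeds(0.70), c(slow = 0.47, fast = 0.93))
  expect_equal(derive_belt_speeds(1.00), c(slow = 0.67, fast = 1.33))
  # half-away-from-zero, not banker's rounding: 0.666*0.625 = 0.41625
  expect_equal(derive_belt_speeds(0.625)[["slow"]], 0.42)
  expect_error(derive_belt_speeds(0), class = "splitbelt_invalid_parameter")
  expect_error(derive_belt_speeds(-1), class = "splitbelt_invalid_parameter")
})

test_that("cohort table speeds are consistent with the derivation rule", {
  tab <- stroke_cohort()
  sp <- t(vapply(tab$mid_speed, derive_belt_speeds, numeric(2)))
  # every slow speed reproduces exactly; fast speeds agree to the printed
  # resolution (the printed mid speeds are themselves rounded)
  expect_equal(sp[, 1], tab$slow_speed)
  expect_true(all(abs(sp[, 2] - tab$fast_speed) <= 0.01 + 1e-9))
  # the protocol's "same averaged speed" property holds row by row
  expect_true(all(abs((tab$slow_speed + tab$fast_speed) / 2 -
                        tab$mid_speed) <= 0.01 + 1e-9))
  # fast:slow is 2:1 within the rounding of the two rules
  expect_true(all(abs(tab$fast_speed / tab$slow_speed - 2) < 0.08))
})

test_that("protocol config validates speeds and epoch plans", {
  cfg <- protocol_config("P8", 80, "right", 8.5, 0.70)
  expect_equal(cfg$slow_speed, 0.47)
  expect_equal(cfg$fast_speed, 0.93)
  expect_false("baseline_slow" %in% cfg$epoch_plan$epoch)  # incline session
  flat <- protocol_config("P8", 80, "right", 0, 0.70)
  expect_true("baseline_slow" %in% flat$epoch_plan$epoch)
  # explicit speed inconsistent with the rule by > 0.01 m/s
  expect_error(protocol_config("X", 80, "right", 0, 0.70, slow_speed = 0.55),
               class = "splitbelt_schema_error")
  # paretic belt must run slow during adaptation
  bad_plan <- default_epoch_plan(0.70, "left")
  expect_error(protocol_config("X", 80, "right", 0, 0.70,
                               epoch_plan = bad_plan),
               class = "splitbelt_schema_error")
  bad_name <- default_epoch_plan(0.70, "right")
  bad_name$epoch[1] <- "warmup"
  expect_error(protocol_config("X", 80, "right", 0, 0.70,
                               epoch_plan = bad_name),
               class = "splitbelt_schema_error")
})

test_that("configs round-trip through YAML and JSON with defaults applied", {
  cfg <- protocol_config("P8", 80, "right", 8.5, 0.70)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  back <- load_config(path)
  expect_equal(back$slow_speed, cfg$slow_speed)
  expect_equal(back$fast_speed, cfg$fast_speed)
  expect_equal(as.data.frame(back$epoch_plan),
               as.data.frame(cfg$epoch_plan))
  expect_equal(back$processing$rng_seed, cfg$processing$rng_seed)

  jpath <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(subject_id = "J1", mass_kg = 70,
                            paretic_side = "left", slope_deg = 0,
                            mid_speed = 0.70), jpath, auto_unbox = TRUE)
  expect_message(jcfg <- load_config(jpath), "rng_seed absent")
  expect_equal(jcfg$slow_speed, 0.47)

  expect_error(load_config(withr::local_tempfile(fileext = ".yaml")),
               class = "splitbelt_schema_error")
  ypath <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(subject_id = "Y1", mass_kg = 70), ypath)
  expect_error(load_config(ypath), "mid_speed",
               class = "splitbelt_schema_error")
})
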