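test_that("surface rotation maps the belt direction to +x and is isometric", {
  th <- 8.5
  t100 <- seq(0, 0.1, by = 0.01)
  v <- c(cos(th * pi / 180), 0, sin(th * pi / 180))
  mk <- marker_series("ankle_L", t100,
                      matrix(rep(v, each = length(t100)), ncol = 3),
                      frame = "lab")
  rot <- rotate_to_surface(mk, th)
  expect_equal(rot$xyz_mm[1, ], c(1, 0, 0), tolerance = 1e-12)
  expect_equal(rot$frame, "surface")

  # slope 0 is the identity
  set.seed(4)
  xyz <- matrix(rnorm(length(t100) * 3), ncol = 3)
  mk0 <- marker_series("m", t100, xyz, frame = "lab")
  expect_equal(rotate_to_surface(mk0, 0)$xyz_mm, xyz, tolerance = 1e-12)

  # norms preserved, and theta then -theta round-trips
  rot2 <- rotate_to_surface(mk0, 37)
  expect_equal(sqrt(rowSums(rot2$xyz_mm^2)), sqrt(rowSums(xyz^2)),
               tolerance = 1e-9)
  back <- rotate_to_surface(rot2, -37)
  expect_equal(back$xyz_mm, xyz, tolerance = 1e-9)

  # identical transform for force vectors
  fs <- force_series("left", t100, rep(v[1], 11), rep(v[2], 11),
                     rep(v[3], 11), frame = "lab")
  frot <- rotate_to_surface(fs, th)
  expect_equal(c(frot$f_ap_n[1], frot$f_ml_n[1], frot$f_normal_n[1]),
               c(1, 0, 0), tolerance = 1e-12)
  expect_error(rotate_to_surface(fs, 95),
               class = "splitbelt_invalid_parameter")
})

test_that("quintic gap filling reproduces polynomials and flags long gaps", {
  t100 <- seq(0, 0.99, by = 0.01)
  # degree-5 polynomial is in the model space: exact recovery
  quintic <- 5 + 300 * t100 - 80 * t100^2 + 40 * t100^3 - 9 * t100^4 +
    2 * t100^5
  xyz <- unname(cbind(quintic, quintic / 2, quintic^0))
  m <- marker_series("a", t100, xyz)
  m$xyz_mm[41:45, ] <- NA; m$valid[41:45] <- FALSE
  filled <- fill_gaps(m, max_gap_frames = 10)
  expect_true(all(filled$valid))
  expect_true(all(filled$filled[41:45]))
  expect_equal(filled$xyz_mm[41:45, 1], quintic[41:45], tolerance = 1e-6)
  # originally valid frames are untouched
  expect_identical(filled$xyz_mm[-(41:45), ], xyz[-(41:45), ])

  # linear ramps restored (polynomial subspace)
  lin <- marker_series("a", t100,
                       unname(cbind(10 * t100, 0 * t100, 1 + t100)))
  lin$xyz_mm[20:24, ] <- NA; lin$valid[20:24] <- FALSE
  lf <- fill_gaps(lin, 10)
  expect_equal(lf$xyz_mm[20:24, 1], 10 * t100[20:24], tolerance = 1e-8)

  # gapless series unchanged
  g <- fill_gaps(marker_series("a", t100, xyz), 10)
  expect_identical(g$xyz_mm, xyz)

  # over-long and leading gaps stay masked (reported, not an error)
  long <- marker_series("a", t100, xyz)
  long$xyz_mm[c(1:3, 30:45), ] <- NA; long$valid[c(1:3, 30:45)] <- FALSE
  suppressMessages(lfill <- fill_gaps(long, max_gap_frames = 10))
  expect_false(any(lfill$valid[30:45]))
  expect_false(any(lfill$valid[1:3]))
})

test_that("the AP low-pass is unity at DC, flat at 2 Hz, strong at 100 Hz", {
  t1k <- seq(0, 4, by = 1e-3)
  mk <- function(x) force_series("left", t1k, x, numeric(length(t1k)),
                                 numeric(length(t1k)))
  const <- lowpass_ap(mk(rep(5, length(t1k))))
  expect_equal(const$f_ap_n, rep(5, length(t1k)), tolerance = 1e-9)

  s2 <- lowpass_ap(mk(sin(2 * pi * 2 * t1k)))
  mid <- t1k > 1 & t1k < 3
  expect_gt(max(abs(s2$f_ap_n[mid])), 0.99)
  expect_lt(max(abs(s2$f_ap_n[mid])), 1.01)

  s100 <- lowpass_ap(mk(sin(2 * pi * 100 * t1k)))
  expect_lt(max(abs(s100$f_ap_n[mid])), 0.03)   # > 97% attenuation

  # zero phase: the response to a centered impulse is time-symmetric
  imp <- numeric(length(t1k)); imp[2001] <- 1
  r <- lowpass_ap(mk(imp))$f_ap_n
  expect_equal(r[2001 + 1:200], r[2001 - 1:200], tolerance = 1e-9)

  # other components untouched; cutoff must respect Nyquist
  s <- mk(sin(t1k)); s$f_normal_n <- cos(t1k)
  expect_identical(lowpass_ap(s)$f_normal_n, cos(t1k))
  expect_error(lowpass_ap(mk(t1k), cutoff_hz = 600),
               class = "splitbelt_invalid_parameter")

  # near-idempotent on signals already band-limited below the cutoff
  once <- lowpass_ap(mk(sin(2 * pi * 2 * t1k)))
  twice <- lowpass_ap(once)
  expect_lt(max(abs(twice$f_ap_n[mid] - once$f_ap_n[mid])), 0.01)
})

test_that("the running median rejects spikes and keeps step timing", {
  t1k <- seq(0, 0.2, by = 1e-3)
  n <- length(t1k)
  mk <- function(x) force_series("left", t1k, numeric(n), numeric(n), x)
  expect_equal(median_filter_normal(mk(rep(7, n)))$f_normal_n, rep(7, n))

  spike <- numeric(n); spike[100] <- 500
  expect_equal(median_filter_normal(mk(spike))$f_normal_n, numeric(n))

  # 0 -> 500 N step at sample k: first filtered sample >= 10 N is still k
  k <- 120
  step <- c(numeric(k - 1), rep(500, n - k + 1))
  sf <- median_filter_normal(mk(step))$f_normal_n
  expect_equal(which(sf >= 10)[1], k)
})
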