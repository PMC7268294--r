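test_that("paired t and d_z match hand-computed closed forms", {
  x <- c(2, -1, 3, 0, 1); y <- numeric(5)
  r <- paired_t(x, y)
  expect_equal(r$t, sqrt(2), tolerance = 1e-10)
  expect_equal(r$df, 4)
  expect_equal(r$cohens_d, 1 / sqrt(2.5), tolerance = 1e-10)
  expect_equal(r$p, 2 * pt(sqrt(2), 4, lower.tail = FALSE),
               tolerance = 1e-12)

  # exact null case (symmetric differences) and antisymmetry
  set.seed(51)
  a <- rnorm(12); b <- rnorm(12)
  null_r <- paired_t(c(-2, -1, 0, 1, 2) + a[1:5], a[1:5])
  expect_equal(null_r$t, 0, tolerance = 1e-12)
  expect_equal(null_r$p, 1, tolerance = 1e-12)
  expect_equal(null_r$cohens_d, 0, tolerance = 1e-12)
  expect_equal(paired_t(a, b)$t, -paired_t(b, a)$t, tolerance = 1e-12)
  expect_equal(paired_t(a, b)$cohens_d, -paired_t(b, a)$cohens_d,
               tolerance = 1e-12)
  expect_error(paired_t(1, 2), class = "splitbelt_degenerate_data")
  expect_error(paired_t(a, a), class = "splitbelt_degenerate_data")

  # d_av variant uses the average of the two sample SDs
  expect_equal(paired_t(a, b, variant = "dav")$cohens_d,
               mean(a - b) / mean(c(sd(a), sd(b))), tolerance = 1e-12)
})

test_that("one-sample tests apply the Bonferroni multiplication rule", {
  set.seed(52)
  s1 <- rnorm(10, 0.5); s2 <- rnorm(8)
  r <- one_sample_t_bonferroni(list(s1, s2))
  expect_equal(r$p_corrected, pmin(1, 2 * r$p_raw))
  r1 <- one_sample_t_bonferroni(list(s1), m = 1)
  expect_equal(r1$p_corrected, r1$p_raw)
  expect_equal(one_sample_t_bonferroni(list(s1), m = 4)$p_corrected,
               min(1, 4 * r1$p_raw))
  sym <- c(-2, -1, 0, 1, 2)
  r0 <- one_sample_t_bonferroni(list(sym))
  expect_equal(r0$t, 0)
  expect_equal(r0$p_corrected, 1)
  expect_error(one_sample_t_bonferroni(list(rep(1, 5))),
               class = "splitbelt_degenerate_data")
})

test_that("rm_anova reproduces the projection oracle on balanced designs", {
  set.seed(53)
  for (rep in 1:5) {
    d <- expand.grid(s = paste0("S", 1:12), a = c("a1", "a2"),
                     b = c("b1", "b2"))
    d$y <- rnorm(nrow(d)) + as.numeric(d$a == "a2") * 0.4
    fit <- rm_anova(d, dv = "y", subject = "s", within = c("a", "b"))
    ss <- oracle_within_ss(d)
    expect_equal(fit$ss[fit$effect == "a"], ss$a, tolerance = 1e-8)
    expect_equal(fit$ss[fit$effect == "b"], ss$b, tolerance = 1e-8)
    expect_equal(fit$ss[fit$effect == "a:b"], ss$ab, tolerance = 1e-8)
    expect_equal(fit$ss_error[fit$effect == "a"], ss$as, tolerance = 1e-8)
    expect_equal(fit$ss_error[fit$effect == "b"], ss$bs, tolerance = 1e-8)
    expect_equal(fit$ss_error[fit$effect == "a:b"], ss$abs,
                 tolerance = 1e-8)
    expect_equal(attr(fit, "ss_total"), ss$total, tolerance = 1e-8)
    # F against the effect-by-subject interaction mean square
    expect_equal(fit$F[fit$effect == "a"],
                 (ss$a / 1) / (ss$as / 11), tolerance = 1e-8)
    expect_equal(fit$eta_sq, fit$ss / ss$total, tolerance = 1e-12)
    expect_true(all(fit$eta_sq >= 0 & fit$eta_sq <= 1))
  }
})

test_that("a single two-level within factor reduces to the paired t", {
  set.seed(54)
  x <- rnorm(12, 1); y <- rnorm(12)
  d <- data.frame(s = rep(paste0("S", 1:12), 2),
                  a = rep(c("x", "y"), each = 12), y = c(x, y))
  fit <- rm_anova(d, dv = "y", subject = "s", within = "a")
  tt <- paired_t(x, y)
  expect_equal(fit$F[fit$effect == "a"], tt$t^2, tolerance = 1e-10)
  expect_equal(fit$p[fit$effect == "a"], tt$p, tolerance = 1e-10)
})

test_that("rm_anova handles degenerate, incomplete and mixed designs", {
  d <- expand.grid(s = paste0("S", 1:6), a = c("a1", "a2"))
  d$y <- 5
  fit <- rm_anova(d, dv = "y", subject = "s", within = "a")
  expect_equal(fit$F[fit$effect == "a"], 0)
  expect_equal(fit$p[fit$effect == "a"], 1)

  # incomplete subjects are dropped listwise
  d2 <- expand.grid(s = paste0("S", 1:6), a = c("a1", "a2"))
  set.seed(55); d2$y <- rnorm(nrow(d2))
  d2 <- d2[-1, ]
  fit2 <- suppressMessages(rm_anova(d2, "y", "s", within = "a"))
  oracle <- rm_anova(d2[d2$s != "S1", ], "y", "s", within = "a")
  expect_equal(fit2$ss, oracle$ss, tolerance = 1e-12)

  # mixed design: between factor tested in the between-unit stratum and
  # the full decomposition still sums to the total SS
  d3 <- expand.grid(u = paste0("U", 1:10), a = c("a1", "a2"))
  set.seed(56); d3$y <- rnorm(nrow(d3))
  d3$g <- ifelse(as.integer(sub("U", "", d3$u)) <= 5, "g1", "g2")
  fit3 <- rm_anova(d3, "y", subject = "u", within = "a", between = "g")
  expect_setequal(fit3$effect, c("g", "a", "a:g"))
  expect_equal(fit3$error_term[fit3$effect == "g"], "u")
  expect_equal(sum(fit3$ss) + sum(unique(fit3$ss_error)),
               attr(fit3, "ss_total"), tolerance = 1e-8)
  d4 <- d3; d4$g <- "g1"; d4$g[1] <- "g2"   # unit in two between levels
  expect_error(rm_anova(d4, "y", "u", within = "a", between = "g"),
               class = "splitbelt_design_error")
})

test_that("Lilliefors D matches nortest and the MC p behaves", {
  set.seed(57)
  for (rep in 1:20) {
    x <- rnorm(sample(10:60, 1), sample(-5:5, 1), runif(1, 0.5, 3))
    expect_equal(lilliefors(x, n_replicates = 50, seed = 1)$d,
                 unname(nortest::lillie.test(x)$statistic),
                 tolerance = 1e-12)
  }
  # a sample at exact normal quantiles is as normal as it gets
  q <- qnorm((seq_len(50) - 0.5) / 50)
  expect_gt(lilliefors(q, n_replicates = 2000, seed = 2)$p, 0.5)
  expect_error(lilliefors(rep(1, 10)), class = "splitbelt_degenerate_data")
  expect_error(lilliefors(rnorm(3)), class = "splitbelt_degenerate_data")
})

test_that("Lilliefors power against the uniform matches the oracle level", {
  # reference implementation (nortest) rejects uniform n = 100 samples in
  # roughly 60-65% of runs; the Monte Carlo version must sit in the same
  # power band, far above the 5% size but below ~90%
  null_d <- lilliefors_null(100, n_replicates = 2000, seed = 3)
  set.seed(58)
  rej <- vapply(1:30, function(i) {
    lilliefors(runif(100), null_distribution = null_d)$p <= 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.35)
  expect_lt(mean(rej), 0.90)
})

test_that("through-origin regression matches closed forms and lm", {
  r <- regress_origin(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$slope, 1, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  expect_equal(max(abs(attr(r, "residuals"))), 0, tolerance = 1e-12)

  r2 <- regress_origin(c(1, 2), c(2, 3))
  expect_equal(r2$slope, 8 / 5, tolerance = 1e-12)

  # absolute values erase signs
  set.seed(59)
  z <- rnorm(30)
  expect_equal(regress_origin(z, -z)$slope, 1, tolerance = 1e-12)

  # cross-check every statistic against lm through the origin
  zz <- runif(40, 0.5, 3); yy <- 1.2 * zz + rnorm(40, 0, 0.3)
  mine <- regress_origin(zz, yy)
  lmfit <- summary(lm(yy ~ zz - 1))
  expect_equal(mine$slope, unname(coef(lmfit)[1, 1]), tolerance = 1e-10)
  expect_equal(mine$se, unname(coef(lmfit)[1, 2]), tolerance = 1e-10)
  expect_equal(mine$r_squared, lmfit$r.squared, tolerance = 1e-10)
  expect_equal(mine$pearson_r, cor(zz, yy), tolerance = 1e-12)
  expect_true(mine$ci_lo < mine$slope && mine$slope < mine$ci_hi)

  # scale equivariance: y-scale multiplies, z-scale divides
  expect_equal(regress_origin(zz, 3 * yy)$slope, 3 * mine$slope,
               tolerance = 1e-10)
  expect_equal(regress_origin(2 * zz, yy)$slope, mine$slope / 2,
               tolerance = 1e-10)

  expect_error(regress_origin(numeric(3), rnorm(3)),
               class = "splitbelt_singular_fit")
  expect_error(regress_origin(1, 1), class = "splitbelt_invalid_parameter")
})
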