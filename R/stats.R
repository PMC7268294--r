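# Statistical battery for the group analyses: paired and one-sample
# t-tests with the paired Cohen's d_z, Bonferroni correction,
# repeated-measures / mixed ANOVA with classical error terms and eta
# squared, Monte Carlo Lilliefors normality, and regression through the
# origin on absolute values with Pearson r as effect size.

#' Paired t-test with paired Cohen's d
#'
#' Two-sided paired t on matched samples, with the paired effect size
#' d_z = mean(diff) / sd(diff). (The averaged-variance variant d_av =
#' mean(diff) / mean(sd(x), sd(y)) is available via `variant`.)
#'
#' @param x,y Matched numeric samples of equal length (n >= 2).
#' @param variant Effect-size variant, `"dz"` (default) or `"dav"`.
#' @return Tibble: `t`, `df`, `p`, `mean_diff`, `cohens_d`, `n`.
#' @export
paired_t <- function(x, y, variant = c("dz", "dav")) {
  variant <- match.arg(variant)
  if (length(x) != length(y)) {
    abort("paired samples must have equal length",
          class = "splitbelt_invalid_parameter")
  }
  d <- x - y
  if (length(d) < 2L || sd(d) == 0) {
    abort("paired differences are degenerate (n < 2 or zero variance)",
          class = "splitbelt_degenerate_data")
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  cd <- if (variant == "dz") mean(d) / sd(d) else
    mean(d) / mean(c(sd(x), sd(y)))
  tibble(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value, mean_diff = mean(d), cohens_d = cd,
         n = length(d))
}

#' One-sample t-tests with Bonferroni correction
#'
#' Tests each sample in a list against `mu0`, multiplying each p-value by
#' the number of comparisons (capped at 1).
#'
#' @param samples List of numeric vectors (each n >= 2, nonzero variance).
#' @param mu0 Null value (default 0).
#' @param m Number of comparisons (default `length(samples)`).
#' @return Tibble with one row per sample: `t`, `df`, `p_raw`,
#'   `p_corrected`, `mean`, `cohens_d`, `n`.
#' @export
one_sample_t_bonferroni <- function(samples, mu0 = 0,
                                    m = length(samples)) {
  rows <- lapply(seq_along(samples), function(i) {
    x <- samples[[i]]
    if (length(x) < 2L || sd(x) == 0) {
      abort(sprintf("sample %d is degenerate (n < 2 or zero variance)", i),
            class = "splitbelt_degenerate_data")
    }
    ht <- stats::t.test(x, mu = mu0)
    tibble(sample = i, t = unname(ht$statistic),
           df = unname(ht$parameter), p_raw = ht$p.value,
           p_corrected = min(1, m * ht$p.value), mean = mean(x),
           cohens_d = (mean(x) - mu0) / sd(x), n = length(x))
  })
  dplyr::bind_rows(rows)
}

#' Repeated-measures / mixed ANOVA with subject as random blocking factor
#'
#' Univariate sums-of-squares decomposition with subjects as a random
#' blocking factor: each within-subject fixed effect is tested against its
#' effect-by-subject interaction mean square (classical repeated-measures
#' error terms); in a mixed design the between-subject factor is tested
#' against the between-subject residual. Effect sizes are eta squared,
#' SS_effect / SS_total over the full decomposition. Requires a complete
#' balanced within design; subjects with missing cells are dropped
#' listwise (logged).
#'
#' @param data Data frame in long format.
#' @param dv Name of the response column.
#' @param subject Name of the blocking-unit column (in a mixed design each
#'   unit must appear in exactly one level of the between factor; pass
#'   subject-by-group units if the same subjects contribute to several
#'   between levels).
#' @param within Character vector of within-unit factor names.
#' @param between Optional between-unit factor name.
#' @return Tibble with one row per effect: `effect`, `ss`, `df`, `ms`,
#'   `error_term`, `ss_error`, `df_error`, `F`, `p`, `eta_sq`.
#' @export
rm_anova <- function(data, dv, subject, within, between = NULL) {
  data <- as.data.frame(data)
  data[[subject]] <- factor(data[[subject]])
  for (f in c(within, between)) data[[f]] <- factor(data[[f]])
  # listwise deletion to a complete within design
  cells <- interaction(data[, within, drop = FALSE], drop = FALSE)
  n_cells <- length(levels(cells))
  counts <- table(data[[subject]], cells)
  ok <- rownames(counts)[apply(counts == 1L, 1, all)]
  if (length(ok) < nlevels(data[[subject]])) {
    sb_log("info", "rm_anova: dropping %d incomplete subject(s)",
           nlevels(data[[subject]]) - length(ok))
    data <- data[data[[subject]] %in% ok, ]
    data[[subject]] <- droplevels(data[[subject]])
  }
  if (nlevels(data[[subject]]) < 2L) {
    abort("rm_anova needs at least 2 complete subjects",
          class = "splitbelt_design_error")
  }
  if (nrow(data) != nlevels(data[[subject]]) * n_cells) {
    abort("design is not complete/balanced after deletion",
          class = "splitbelt_design_error")
  }
  if (!is.null(between)) {
    grp <- table(data[[subject]], data[[between]]) > 0
    if (any(rowSums(grp) != 1L)) {
      abort("each unit must belong to exactly one between-factor level",
            class = "splitbelt_design_error")
    }
  }
  fixed <- paste(c(within, between), collapse = " * ")
  err <- paste0("Error(", subject, "/(", paste(within, collapse = " * "),
                "))")
  form <- stats::as.formula(paste(dv, "~", fixed, "+", err))
  fit <- stats::aov(form, data = data)
  smry <- summary(fit)
  rows <- list()
  ss_total <- 0
  for (stratum in names(smry)) {
    tab <- smry[[stratum]][[1]]
    terms <- trimws(rownames(tab))
    ss_total <- ss_total + sum(tab[, "Sum Sq"])
    resid_i <- which(terms == "Residuals")
    ss_err <- if (length(resid_i)) tab[resid_i, "Sum Sq"] else NA_real_
    df_err <- if (length(resid_i)) tab[resid_i, "Df"] else NA_real_
    for (i in seq_along(terms)) {
      if (terms[i] == "Residuals") next
      rows[[length(rows) + 1L]] <- tibble(
        effect = terms[i], ss = tab[i, "Sum Sq"], df = tab[i, "Df"],
        ms = tab[i, "Mean Sq"],
        error_term = sub("^Error: ", "", stratum),
        ss_error = ss_err, df_error = df_err,
        # zero-SS effects are reported as F = 0 (p = 1) even when the
        # error SS is also zero (degenerate constant data)
        F = if (tab[i, "Sum Sq"] < 1e-12) 0 else
          if (!is.na(ss_err)) tab[i, "Mean Sq"] / (ss_err / df_err)
          else NA_real_,
        p = if (tab[i, "Sum Sq"] < 1e-12) 1 else
          if (!is.na(ss_err)) {
            stats::pf(tab[i, "Mean Sq"] / (ss_err / df_err), tab[i, "Df"],
                      df_err, lower.tail = FALSE)
          } else NA_real_)
    }
  }
  out <- dplyr::bind_rows(rows)
  out$eta_sq <- out$ss / ss_total
  attr(out, "ss_total") <- ss_total
  out
}

#' Lilliefors normality test with Monte Carlo p-value
#'
#' D is the Kolmogorov-Smirnov supremum distance between the empirical CDF
#' and a normal CDF with mean and SD estimated from the sample; the
#' p-value is the Monte Carlo proportion of null statistics (Gaussian
#' samples of the same n, parameters re-estimated per replicate) at least
#' as large as the observed D, with the (1 + k)/(R + 1) correction so p is
#' in (0, 1].
#'
#' @param x Numeric sample (n >= 4, nonzero variance).
#' @param n_replicates Monte Carlo replicates (default 10000).
#' @param seed Integer seed for reproducibility.
#' @param null_distribution Optional precomputed vector of null D values
#'   for this n (from [lilliefors_null()]), bypassing simulation.
#' @return Tibble: `d`, `p`, `n`, `n_replicates`, `seed`.
#' @export
lilliefors <- function(x, n_replicates = 10000L, seed = 1L,
                       null_distribution = NULL) {
  n <- length(x)
  if (n < 4L || sd(x) == 0) {
    abort("lilliefors needs n >= 4 and nonzero variance",
          class = "splitbelt_degenerate_data")
  }
  d <- lilliefors_d(x)
  null_d <- null_distribution %||% lilliefors_null(n, n_replicates, seed)
  p <- (1 + sum(null_d >= d)) / (length(null_d) + 1)
  tibble(d = d, p = p, n = n, n_replicates = length(null_d),
         seed = seed)
}

# supremum distance between the ECDF and the fitted normal CDF
lilliefors_d <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  cdf <- pnorm(z)
  max(pmax(seq_len(n) / n - cdf, cdf - (seq_len(n) - 1) / n))
}

#' Null distribution of the Lilliefors statistic
#'
#' @param n Sample size.
#' @param n_replicates Number of Gaussian null samples.
#' @param seed Integer seed.
#' @return Numeric vector of null D values.
#' @export
lilliefors_null <- function(n, n_replicates = 10000L, seed = 1L) {
  set.seed(seed)
  vapply(seq_len(n_replicates),
         function(i) lilliefors_d(rnorm(n)), numeric(1))
}

#' Regression through the origin on absolute values
#'
#' Fits `|y| = a * |z|` (or `y = a * z` with `use_abs = FALSE`):
#' `a = sum(z'y') / sum(z'^2)`, `se = sqrt(sum((y' - a z')^2) / (n - 1) /
#' sum(z'^2))` with df = n - 1, 95% CI `a +/- t_{0.975, n-1} se`, the
#' uncentered `r_squared = 1 - sum((y' - a z')^2) / sum(y'^2)`, and the
#' ordinary (centered) Pearson correlation of (z', y') as effect size.
#'
#' @param z,y Matched predictor and response (n >= 3).
#' @param use_abs Transform both variables by absolute value first
#'   (default TRUE).
#' @return Tibble: `slope`, `se`, `ci_lo`, `ci_hi`, `t`, `df`,
#'   `r_squared`, `pearson_r`, `p`, `n`; residuals in
#'   `attr(, "residuals")`.
#' @export
regress_origin <- function(z, y, use_abs = TRUE) {
  if (length(z) != length(y) || length(z) < 2L) {
    abort("regress_origin needs matched samples with n >= 2",
          class = "splitbelt_invalid_parameter")
  }
  zp <- if (use_abs) abs(z) else z
  yp <- if (use_abs) abs(y) else y
  szz <- sum(zp^2)
  if (szz == 0) {
    abort("all-zero predictor", class = "splitbelt_singular_fit")
  }
  n <- length(zp)
  a <- sum(zp * yp) / szz
  res <- yp - a * zp
  se <- sqrt(sum(res^2) / (n - 1) / szz)
  tq <- qt(0.975, n - 1)
  tstat <- a / se
  out <- tibble(slope = a, se = se, ci_lo = a - tq * se,
                ci_hi = a + tq * se, t = tstat, df = n - 1,
                r_squared = 1 - sum(res^2) / sum(yp^2),
                pearson_r = stats::cor(zp, yp),
                p = 2 * pt(abs(tstat), n - 1, lower.tail = FALSE), n = n)
  attr(out, "residuals") <- res
  out
}
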