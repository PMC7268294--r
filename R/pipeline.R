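# Session- and study-level orchestration: simulate (or load) a session,
# extract strides, compute outcomes, and run the group statistical
# battery over a cohort of synthetic subjects.

#' Run one synthetic session end to end
#'
#' @param config [protocol_config()].
#' @param seed Integer seed.
#' @param noise `"realistic"` or `"none"`.
#' @param params Optional truth dynamics ([default_adaptation_params()]).
#' @param keep_trial Keep the raw recording in the result (large)?
#' @return List: `stride_table`, `outcomes`, `epoch_means`, `truth`,
#'   `config`, and optionally `trial`.
#' @export
run_session <- function(config, seed = 1L,
                        noise = c("realistic", "none"), params = NULL,
                        keep_trial = FALSE) {
  noise <- match.arg(noise)
  sim <- simulate_session(config, seed = seed, params = params,
                          noise = noise)
  st <- extract_strides(sim$trial)
  oc <- compute_outcomes(st, config$processing)
  out <- list(stride_table = st, outcomes = oc,
              epoch_means = epoch_means(st, config$processing),
              truth = sim$truth, config = config)
  if (keep_trial) out$trial <- sim$trial
  out
}

# raw epoch means used by the leg-orientation regressions: slow baseline
# (when collected), late adaptation and early post-adaptation
epoch_means <- function(stride_table, processing = processing_params(),
                        parameters = NULL) {
  parameters <- parameters %||%
    intersect(outcome_parameters, names(stride_table))
  nl <- processing$late_window_strides
  ne <- processing$early_window_strides
  has_slow <- "baseline_slow" %in% stride_table$epoch
  rows <- lapply(parameters, function(par) {
    x_ad <- stride_table[[par]][stride_table$epoch == "adaptation"]
    x_po <- stride_table[[par]][stride_table$epoch == "post_adaptation"]
    tibble(
      parameter = par,
      baseline_slow = if (has_slow) {
        mean(utils::tail(stride_table[[par]][
          stride_table$epoch == "baseline_slow" &
            is.finite(stride_table[[par]])], nl))
      } else NA_real_,
      late_adaptation_raw = mean(utils::tail(x_ad[is.finite(x_ad)], nl)),
      early_post_raw = mean(utils::head(x_po[is.finite(x_po)], ne)))
  })
  dplyr::bind_rows(rows)
}

#' Simulate and analyse a full synthetic study
#'
#' One flat and one incline session per synthetic subject, scaled to the
#' reference cohort: each subject takes a mid speed and incline slope from
#' [stroke_cohort()]. Returns per-session outcomes in long format plus the
#' session objects.
#'
#' @param seed Study-level seed; subject/session seeds are derived from it.
#' @param n_subjects Number of subjects (up to 12).
#' @param noise `"realistic"` or `"none"`.
#' @param n_baseline,n_adaptation,n_post Strides per epoch.
#' @param keep_sessions Keep full session objects (stride tables etc.)?
#' @return List: `outcomes` (tibble subject x session x parameter),
#'   `epoch_means`, `sessions` (list or NULL).
#' @export
run_study <- function(seed = 1L, n_subjects = 12L,
                      noise = c("realistic", "none"),
                      n_baseline = 50L, n_adaptation = 200L, n_post = 60L,
                      keep_sessions = FALSE) {
  noise <- match.arg(noise)
  cohort <- utils::head(stroke_cohort(), n_subjects)
  masses <- 60 + 3 * (seq_len(nrow(cohort)) - 1)   # fixed synthetic masses
  oc <- list(); em <- list(); sessions <- list()
  for (i in seq_len(nrow(cohort))) {
    for (sess in c("flat", "incline")) {
      slope <- if (sess == "flat") 0 else cohort$incline_slope_deg[i]
      cfg <- protocol_config(
        subject_id = cohort$id[i], mass_kg = masses[i],
        paretic_side = cohort$affected_side[i], slope_deg = slope,
        mid_speed = cohort$mid_speed[i],
        epoch_plan = default_epoch_plan(
          cohort$mid_speed[i], cohort$affected_side[i],
          include_slow_baseline = sess == "flat",
          n_baseline = n_baseline, n_adaptation = n_adaptation,
          n_post = n_post))
      s_seed <- (seed * 1000L + i * 10L +
                   (if (sess == "flat") 0L else 1L)) %% .Machine$integer.max
      res <- run_session(cfg, seed = s_seed, noise = noise)
      oc[[length(oc) + 1L]] <- dplyr::mutate(
        res$outcomes, subject = cohort$id[i], session = sess,
        .before = 1)
      em[[length(em) + 1L]] <- dplyr::mutate(
        res$epoch_means, subject = cohort$id[i], session = sess,
        .before = 1)
      if (keep_sessions) {
        sessions[[paste(cohort$id[i], sess, sep = "_")]] <- res
      }
    }
  }
  list(outcomes = dplyr::bind_rows(oc), epoch_means = dplyr::bind_rows(em),
       sessions = if (keep_sessions) sessions)
}

#' Group statistical battery over a synthetic study
#'
#' Mirrors the study's group analyses on unbiased outcome values: paired
#' flat-vs-incline t-tests (with paired Cohen's d) for step length
#' asymmetry outcomes; one-sample t-tests with Bonferroni correction for
#' step-length de-adaptation (delta_post) per leg and slope; a mixed ANOVA
#' on step-length changes with slope and leg as repeated factors and epoch
#' (delta_adapt vs delta_post) as a between factor; a repeated-measures
#' ANOVA on baseline propulsion (slope x leg); through-origin regressions
#' |y| = a|z| relating slow-baseline to late-adaptation leg orientations
#' (paretic leg, flat session) and late-adaptation to early-post
#' orientations (ipsilateral alpha, contralateral X, both legs and
#' sessions); and Lilliefors normality gates on every tested sample.
#'
#' @param study Result of [run_study()].
#' @param mc_seed Seed for the Lilliefors Monte Carlo p-values.
#' @return List of result tibbles: `sla_paired`, `sl_delta_post`,
#'   `sl_anova`, `prop_baseline_anova`, `reg_baseline_adapt`,
#'   `reg_adapt_post`, `normality`.
#' @export
study_stats <- function(study, mc_seed = 1L) {
  oc <- study$outcomes
  em <- study$epoch_means
  wide <- function(par, measure) {
    sub <- oc[oc$parameter == par, c("subject", "session", measure)]
    flat <- sub[sub$session == "flat", ]
    inc <- sub[sub$session == "incline", ]
    merge(flat, inc, by = "subject", suffixes = c("_flat", "_incline"))
  }

  sla_paired <- dplyr::bind_rows(lapply(
    c("baseline", "late_adaptation", "delta_adapt", "after_effects"),
    function(ms) {
      w <- wide("sla", ms)
      dplyr::mutate(paired_t(w[[paste0(ms, "_incline")]],
                             w[[paste0(ms, "_flat")]]),
                    measure = ms, .before = 1)
    }))

  dp <- list(); labels <- character()
  for (par in c("sl_paretic_mm", "sl_nonparetic_mm")) {
    for (sess in c("flat", "incline")) {
      dp[[length(dp) + 1L]] <-
        oc$delta_post[oc$parameter == par & oc$session == sess]
      labels <- c(labels, paste(par, sess, sep = "_"))
    }
  }
  sl_delta_post <- one_sample_t_bonferroni(dp)
  sl_delta_post$label <- labels

  long_sl <- oc[oc$parameter %in% c("sl_paretic_mm", "sl_nonparetic_mm"), ]
  an_dat <- dplyr::bind_rows(
    tibble(subject = long_sl$subject, slope = long_sl$session,
           leg = sub("sl_(.*)_mm", "\\1", long_sl$parameter),
           epoch = "delta_adapt", value = long_sl$delta_adapt),
    tibble(subject = long_sl$subject, slope = long_sl$session,
           leg = sub("sl_(.*)_mm", "\\1", long_sl$parameter),
           epoch = "delta_post", value = long_sl$delta_post))
  an_dat$unit <- paste(an_dat$subject, an_dat$epoch, sep = ":")
  sl_anova <- rm_anova(an_dat, dv = "value", subject = "unit",
                       within = c("slope", "leg"), between = "epoch")

  long_p <- oc[oc$parameter %in% c("prop_paretic_nkg",
                                   "prop_nonparetic_nkg"), ]
  p_dat <- tibble(subject = long_p$subject, slope = long_p$session,
                  leg = sub("prop_(.*)_nkg", "\\1", long_p$parameter),
                  value = long_p$baseline)
  prop_baseline_anova <- rm_anova(p_dat, dv = "value", subject = "subject",
                                  within = c("slope", "leg"))

  # slow baseline predicts late adaptation (paretic leg, flat session)
  emf <- em[em$session == "flat" &
              em$parameter %in% c("alpha_paretic_mm", "x_paretic_mm"), ]
  reg_baseline_adapt <- regress_origin(emf$baseline_slow,
                                       emf$late_adaptation_raw)

  # late adaptation predicts early post: ipsilateral alpha, contralateral X
  pairs <- list(c("alpha_paretic_mm", "alpha_paretic_mm"),
                c("alpha_nonparetic_mm", "alpha_nonparetic_mm"),
                c("x_paretic_mm", "x_nonparetic_mm"),
                c("x_nonparetic_mm", "x_paretic_mm"))
  z <- c(); y <- c()
  for (pr in pairs) {
    for (sess in c("flat", "incline")) {
      a <- em[em$session == sess & em$parameter == pr[1], ]
      b <- em[em$session == sess & em$parameter == pr[2], ]
      m <- merge(a[, c("subject", "late_adaptation_raw")],
                 b[, c("subject", "early_post_raw")], by = "subject")
      z <- c(z, m$late_adaptation_raw); y <- c(y, m$early_post_raw)
    }
  }
  reg_adapt_post <- regress_origin(z, y)

  norm_samples <- list(
    sla_late_diff = wide("sla", "late_adaptation")$late_adaptation_incline -
      wide("sla", "late_adaptation")$late_adaptation_flat,
    sla_after_diff = wide("sla", "after_effects")$after_effects_incline -
      wide("sla", "after_effects")$after_effects_flat)
  null_d <- lilliefors_null(length(norm_samples[[1]]),
                            n_replicates = 2000L, seed = mc_seed)
  normality <- dplyr::bind_rows(lapply(names(norm_samples), function(nm) {
    dplyr::mutate(lilliefors(norm_samples[[nm]],
                             null_distribution = null_d, seed = mc_seed),
                  sample = nm, .before = 1)
  }))
  for (i in seq_len(nrow(normality))) {
    sb_log("info", "normality gate %s: D=%.3f p=%.3f -> %s",
           normality$sample[i], normality$d[i], normality$p[i],
           if (normality$p[i] > 0.05) "parametric tests proceed"
           else "non-normal (logged; parametric tests still reported)")
  }

  list(sla_paired = sla_paired, sl_delta_post = sl_delta_post,
       sl_anova = sl_anova, prop_baseline_anova = prop_baseline_anova,
       reg_baseline_adapt = reg_baseline_adapt,
       reg_adapt_post = reg_adapt_post, normality = normality)
}

#' Write a stats report to JSON and TSV
#'
#' @param stats Result of [study_stats()].
#' @param path_json,path_tsv Output paths (either may be NULL).
#' @return Invisibly, the flattened report tibble.
#' @export
write_stats_report <- function(stats, path_json = NULL, path_tsv = NULL) {
  flat <- dplyr::bind_rows(lapply(names(stats), function(nm) {
    tab <- stats[[nm]]
    tab$analysis <- nm
    tab
  }))
  if (!is.null(path_json)) {
    jsonlite::write_json(stats, path_json, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  }
  if (!is.null(path_tsv)) readr::write_tsv(flat, path_tsv)
  invisible(flat)
}
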