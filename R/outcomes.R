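# Epoch outcome measures: collapse each stride-parameter series into the
# five study outcomes per parameter. Baseline is the mean of the last 40
# valid strides of the mid-speed baseline; Late Adaptation and
# After-Effects are baseline-referenced; the change scores are
# within-epoch differences. delta_post = -after_effects identically by
# construction, and this identity is asserted on every run.

outcome_parameters <- c("sla", "sl_paretic_mm", "sl_nonparetic_mm",
                        "alpha_paretic_mm", "alpha_nonparetic_mm",
                        "x_paretic_mm", "x_nonparetic_mm",
                        "prop_paretic_nkg", "prop_nonparetic_nkg")

window_mean <- function(x, n, from = c("tail", "head"), what, epoch) {
  from <- match.arg(from)
  x <- x[is.finite(x)]   # missing-flagged strides skipped; window extends
  if (length(x) < n) {
    abort(sprintf("epoch %s has %d valid strides, %d required for %s",
                  epoch, length(x), n, what),
          class = "splitbelt_epoch_length_error")
  }
  if (from == "tail") mean(utils::tail(x, n)) else mean(utils::head(x, n))
}

#' Compute the five epoch outcome measures per parameter
#'
#' For every stride parameter: `baseline` (mean of the last
#' `late_window_strides` valid strides of the mid-speed baseline epoch),
#' `late_adaptation` (mean of the last `late_window_strides` adaptation
#' strides minus baseline), `after_effects` (mean of the first
#' `early_window_strides` post-adaptation strides minus baseline),
#' `delta_adapt` (late minus early adaptation) and `delta_post` (baseline
#' minus early post-adaptation). Raw early-epoch means are kept as
#' diagnostics. Missing-flagged strides are skipped with the window
#' extended to reach the required count; epochs with too few valid strides
#' raise an error naming the epoch.
#'
#' @param stride_table Stride table from [extract_strides()] (or a truth
#'   table with the same parameter columns and an `epoch` column).
#' @param processing [processing_params()] supplying the window sizes.
#' @param parameters Parameter columns to summarise (defaults to all
#'   present among the standard set).
#' @return Tibble with one row per parameter and columns `baseline`,
#'   `late_adaptation`, `after_effects`, `delta_adapt`, `delta_post`,
#'   `early_adaptation_raw`, `early_post_raw`.
#' @export
compute_outcomes <- function(stride_table,
                             processing = processing_params(),
                             parameters = NULL) {
  parameters <- parameters %||%
    intersect(outcome_parameters, names(stride_table))
  nl <- processing$late_window_strides
  ne <- processing$early_window_strides
  series <- function(ep, par) {
    stride_table[[par]][stride_table$epoch == ep]
  }
  rows <- lapply(parameters, function(par) {
    base <- window_mean(series("baseline_mid", par), nl, "tail",
                        "baseline", "baseline_mid")
    late_ad <- window_mean(series("adaptation", par), nl, "tail",
                           "late adaptation", "adaptation")
    early_ad <- window_mean(series("adaptation", par), ne, "head",
                            "early adaptation", "adaptation")
    early_po <- window_mean(series("post_adaptation", par), ne, "head",
                            "early post-adaptation", "post_adaptation")
    n_ad <- sum(is.finite(series("adaptation", par)))
    if (n_ad < nl + ne) {
      abort(sprintf(
        "epoch adaptation has %d valid strides, %d required", n_ad,
        nl + ne), class = "splitbelt_epoch_length_error")
    }
    tibble(parameter = par, baseline = base,
           late_adaptation = late_ad - base,
           after_effects = early_po - base,
           delta_adapt = late_ad - early_ad,
           delta_post = base - early_po,
           early_adaptation_raw = early_ad, early_post_raw = early_po)
  })
  out <- dplyr::bind_rows(rows)
  stopifnot(max(abs(out$delta_post + out$after_effects)) < 1e-12)
  out
}

#' Subtract the session baseline from a stride series
#'
#' Removes the subject-session bias so epochs are comparable across
#' sessions and subjects. Re-application is refused (the operation is not
#' idempotent): tables carry a `bias_removed` attribute.
#'
#' @param stride_table Stride table.
#' @param outcomes Outcomes tibble from [compute_outcomes()] for the same
#'   session (its `baseline` column supplies the bias).
#' @return The stride table with parameter columns bias-removed.
#' @export
remove_baseline_bias <- function(stride_table, outcomes) {
  if (isTRUE(attr(stride_table, "bias_removed"))) {
    abort("baseline bias already removed from this table",
          class = "splitbelt_invalid_parameter")
  }
  for (i in seq_len(nrow(outcomes))) {
    par <- outcomes$parameter[i]
    stride_table[[par]] <- stride_table[[par]] - outcomes$baseline[i]
  }
  attr(stride_table, "bias_removed") <- TRUE
  stride_table
}

#' Average consecutive strides into non-overlapping bins
#'
#' @param x Numeric stride series.
#' @param bin_size Strides per bin (>= 1). A trailing partial bin is kept
#'   and flagged.
#' @return Tibble `bin_idx`, `value`, `n_strides`, `partial`.
#' @export
bin_strides <- function(x, bin_size = 5L) {
  bin_size <- as.integer(bin_size)
  if (bin_size < 1L) {
    abort("`bin_size` must be >= 1", class = "splitbelt_invalid_parameter")
  }
  idx <- (seq_along(x) - 1L) %/% bin_size + 1L
  tibble(bin_idx = seq_len(max(idx)),
         value = as.numeric(tapply(x, idx, mean)),
         n_strides = as.integer(tapply(x, idx, length)),
         partial = as.integer(tapply(x, idx, length)) < bin_size)
}

#' Binned time course for all parameters of a stride table
#'
#' @param stride_table Stride table with `epoch` column.
#' @param bin_size Strides per bin.
#' @param parameters Parameter columns (default: standard set present).
#' @return Tibble `bin_idx`, `epoch`, `parameter`, `value`, `n_strides`.
#' @export
binned_timecourse <- function(stride_table, bin_size = 5L,
                              parameters = NULL) {
  parameters <- parameters %||%
    intersect(outcome_parameters, names(stride_table))
  out <- list()
  for (ep in unique(stride_table$epoch)) {
    sub <- stride_table[stride_table$epoch == ep, ]
    for (par in parameters) {
      b <- bin_strides(sub[[par]], bin_size)
      out[[length(out) + 1L]] <- tibble(
        bin_idx = b$bin_idx, epoch = ep, parameter = par,
        value = b$value, n_strides = b$n_strides)
    }
  }
  dplyr::bind_rows(out)
}
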