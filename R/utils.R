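#' @importFrom rlang %||% abort warn inform
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median sd approx uniroot rnorm runif pt qt pnorm ecdf
NULL

# Round half away from zero to `digits` decimals. base::round() rounds half to
# even, which is the wrong convention for reproducing treadmill speed settings.
round_half_away <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stopif_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number", name),
          class = "splitbelt_invalid_parameter")
  }
  invisible(x)
}

# Minimal leveled logger; level set per call chain via option so CLI and
# pipeline runs can be replayed from their logs.
sb_log <- function(level = c("info", "warning", "debug"), fmt, ...) {
  level <- match.arg(level)
  threshold <- c(debug = 1L, info = 2L, warning = 3L)
  opt <- getOption("splitbelt.log_level", "info")
  if (threshold[[level]] >= threshold[[opt %||% "info"]]) {
    message(sprintf("[splitbelt %s] %s", level, sprintf(fmt, ...)))
  }
  invisible(NULL)
}

`%||%` <- rlang::`%||%`
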