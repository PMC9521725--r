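# Internal helpers shared across stages. Time is milliseconds from recording
# start; sample indices are 1-based inside R, the on-disk convention is
# 0-based; windows are half-open [start, end).

#' Convert a time in ms to the nearest 1-based sample index
#' @noRd
ms_to_idx <- function(t_ms, fs) {
  as.integer(round(t_ms * fs / 1000)) + 1L
}

#' Convert a 1-based sample index to time in ms
#' @noRd
idx_to_ms <- function(i, fs) {
  (i - 1L) * 1000 / fs
}

#' Sample period in ms
#' @noRd
sample_period_ms <- function(fs) 1000 / fs

#' Population standard deviation (divide by n, not n - 1)
#' @noRd
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

#' Pearson correlation that tolerates zero-variance inputs
#'
#' Returns 0 when either vector is (numerically) constant: a flat segment
#' carries no morphology information, so it should neither match nor
#' anti-match a template.
#' @noRd
safe_cor <- function(x, y) {
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx < .Machine$double.eps ||
      sy < .Machine$double.eps) {
    return(0)
  }
  stats::cor(x, y)
}

#' Robust noise-floor estimate (MAD-based sd) of a signal
#' @noRd
robust_sd <- function(x) {
  stats::mad(x, constant = 1.4826)
}

#' Stop with a structured condition carrying a typed class
#' @noRd
stop_typed <- function(type, message) {
  cond <- structure(
    class = c(type, "deepmapr_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  )
  stop(cond)
}

#' Typed non-error outcome used by pipeline stages for early termination
#'
#' Stages signal "no-S2", "capture-indeterminate", "insufficient-S1" and the
#' like as values, never as thrown errors, so the pipeline can log them.
#' @noRd
typed_outcome <- function(type, detail = NULL) {
  structure(list(type = type, detail = detail), class = "deep_outcome")
}

#' Test for a typed early-termination outcome
#'
#' Pipeline stages report conditions such as `"no_s2"`,
#' `"capture_indeterminate"` or `"insufficient_s1"` as typed values rather
#' than errors; this predicate recognises them (optionally checking the
#' specific type).
#'
#' @param x Any object.
#' @param type Optional type string to match.
#' @return Logical.
#' @export
is_outcome <- function(x, type = NULL) {
  inherits(x, "deep_outcome") && (is.null(type) || identical(x$type, type))
}

#' Format numbers for lossless decimal round-trip (17 significant digits)
#' @noRd
fmt_full <- function(x) {
  trimws(formatC(x, digits = 17, format = "g"))
}
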