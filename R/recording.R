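#' Multichannel paced recording
#'
#' Container for one paced acquisition: surface-ECG leads plus bipolar
#' intracardiac electrograms sampled at a common rate, with a 3D position
#' (mm) for every bipolar channel. All channels must have identical length;
#' the sampling rate must resolve sub-millisecond latencies (>= 1000 Hz)
#' because decrement values are measured in milliseconds.
#'
#' @param sampling_rate Samples per second (Hz), >= 1000.
#' @param surface Numeric matrix, samples x leads, column names are lead
#'   names (e.g. "I", "II", "V1"). Units mV.
#' @param bipolar Numeric matrix, samples x bipoles, column names are channel
#'   names. Units mV.
#' @param positions Numeric matrix, bipoles x 3, row names matching the
#'   bipolar channel names; x/y/z in mm.
#'
#' @return An object of class `deep_recording` with elements
#'   `sampling_rate`, `surface`, `bipolar`, `positions`, `duration`
#'   (samples per channel).
#' @seealso [validate_recording()]
#' @export
#' @examples
#' fs <- 1000
#' n <- 2000
#' surf <- matrix(rnorm(n * 2, sd = 0.05), n, 2,
#'                dimnames = list(NULL, c("I", "II")))
#' bip <- matrix(rnorm(n * 3, sd = 0.01), n, 3,
#'               dimnames = list(NULL, c("B1", "B2", "B3")))
#' pos <- matrix(rnorm(9, sd = 10), 3, 3,
#'               dimnames = list(c("B1", "B2", "B3"), c("x", "y", "z")))
#' rec <- deep_recording(fs, surf, bip, pos)
#' validate_recording(rec)
deep_recording <- function(sampling_rate, surface, bipolar, positions) {
  surface <- as.matrix(surface)
  bipolar <- as.matrix(bipolar)
  positions <- as.matrix(positions)
  colnames(positions) <- c("x", "y", "z")
  rec <- structure(
    list(
      sampling_rate = as.numeric(sampling_rate),
      surface = surface,
      bipolar = bipolar,
      positions = positions,
      duration = nrow(bipolar)
    ),
    class = "deep_recording"
  )
  viol <- validate_recording(rec)
  if (length(viol) > 0L) {
    stop_typed("invalid_recording",
               paste0("invalid recording: ", paste(viol, collapse = "; ")))
  }
  rec
}

#' Check the structural invariants of a recording
#'
#' Diagnostic counterpart of [deep_recording()]: never throws, returns a
#' character vector with one entry per violated invariant (empty when the
#' recording is well-formed). Checked invariants: all channels share one
#' length; sampling rate is at least 1000 Hz; every bipolar channel has
#' exactly one finite 3D position; channel names are unique and non-empty.
#'
#' @param recording A `deep_recording` (or a list shaped like one).
#' @return Character vector of violations; `character(0)` if none.
#' @export
validate_recording <- function(recording) {
  v <- character(0)
  fs <- recording$sampling_rate
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs < 1000) {
    v <- c(v, "sampling_rate must be a single finite number >= 1000 Hz")
  }
  ns <- nrow(recording$surface)
  nb <- nrow(recording$bipolar)
  if (is.null(ns) || is.null(nb) || ns != nb || nb < 1L) {
    v <- c(v, "surface and bipolar channels must share one positive length")
  }
  bn <- colnames(recording$bipolar)
  if (is.null(bn) || anyDuplicated(bn) || any(!nzchar(bn))) {
    v <- c(v, "bipolar channels must have unique non-empty names")
  }
  sn <- colnames(recording$surface)
  if (is.null(sn) || anyDuplicated(sn) || any(!nzchar(sn))) {
    v <- c(v, "surface leads must have unique non-empty names")
  }
  pos <- recording$positions
  if (is.null(pos) || !is.matrix(pos) || ncol(pos) != 3L ||
      nrow(pos) != ncol(recording$bipolar) ||
      is.null(rownames(pos)) || !is.null(bn) && !setequal(rownames(pos), bn)) {
    v <- c(v, "every bipolar channel needs exactly one named 3D position")
  } else if (any(!is.finite(pos))) {
    v <- c(v, "electrode positions must be finite")
  }
  if (!identical(recording$duration, nrow(recording$bipolar))) {
    v <- c(v, "duration must equal the per-channel sample count")
  }
  v
}

#' @export
print.deep_recording <- function(x, ...) {
  cat("Paced multichannel recording\n")
  cat(sprintf("  sampling rate : %g Hz\n", x$sampling_rate))
  cat(sprintf("  duration      : %d samples (%.1f ms)\n",
              x$duration, idx_to_ms(x$duration, x$sampling_rate)))
  cat(sprintf("  surface leads : %d (%s)\n", ncol(x$surface),
              paste(utils::head(colnames(x$surface), 6), collapse = ", ")))
  cat(sprintf("  bipolar chans : %d (%s%s)\n", ncol(x$bipolar),
              paste(utils::head(colnames(x$bipolar), 6), collapse = ", "),
              if (ncol(x$bipolar) > 6) ", ..." else ""))
  invisible(x)
}

#' Duration of a recording in ms
#' @param recording A `deep_recording`.
#' @return Length of each channel in ms.
#' @export
recording_duration_ms <- function(recording) {
  recording$duration * 1000 / recording$sampling_rate
}
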