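#' Extract post-stimulus surface-ECG segments for every beat
#'
#' For each stimulus in the train (all S1 beats plus S2 when present),
#' returns the surface-lead samples in a fixed window after the stimulus
#' (default 20-140 ms, covering the paced QRS). Windows that would extend
#' past the end of the recording are marked unavailable rather than
#' truncated, so all available segments have identical length and are
#' sample-aligned on the stimulus.
#'
#' @param recording A [deep_recording()].
#' @param train A [classify_train()] result; needs at least 2 S1 beats.
#' @param config A [deep_config()]; uses `capture.window_ms`,
#'   `capture.leads`.
#' @return A list of class `beat_segments`: `segments` (list over beats;
#'   each entry a samples x leads matrix or `NULL` when unavailable),
#'   `beat_times` (ms), `beat_labels` ("S1"/"S2"), `leads`.
#' @export
extract_beat_segments <- function(recording, train, config = deep_config()) {
  if (length(train$s1_times) < 2L) {
    stop_typed("too_few_beats", "need at least 2 S1 beats to build segments")
  }
  fs <- recording$sampling_rate
  win <- config$capture.window_ms
  leads <- config$capture.leads
  if (is.null(leads)) leads <- colnames(recording$surface)
  missing_leads <- setdiff(leads, colnames(recording$surface))
  if (length(missing_leads) > 0L) {
    stop_typed("bad_config", paste0("unknown capture leads: ",
                                    paste(missing_leads, collapse = ", ")))
  }
  beat_times <- train$s1_times
  beat_labels <- rep("S1", length(beat_times))
  if (train$has_s2) {
    beat_times <- c(beat_times, train$s2_time)
    beat_labels <- c(beat_labels, "S2")
  }
  n_win <- as.integer(round((win[2] - win[1]) * fs / 1000))
  segments <- vector("list", length(beat_times))
  for (b in seq_along(beat_times)) {
    i0 <- ms_to_idx(beat_times[b] + win[1], fs)
    idx <- seq.int(i0, length.out = n_win)   # half-open [start, end)
    if (idx[1] < 1L || idx[n_win] > recording$duration) {
      segments[b] <- list(NULL)
    } else {
      segments[[b]] <- recording$surface[idx, leads, drop = FALSE]
    }
  }
  structure(list(segments = segments, beat_times = beat_times,
                 beat_labels = beat_labels, leads = leads),
            class = "beat_segments")
}

#' Confirm myocardial capture per beat by surface-QRS correlation
#'
#' Capture means the stimulus actually depolarized the ventricle, which
#' shows as a consistent paced QRS on the surface ECG. The reference
#' template is the per-lead sample-wise median of all available S1 segments
#' (median, not mean, so one non-captured beat cannot contaminate it). Each
#' beat's score is the Pearson correlation at zero lag between its segment
#' and the template, averaged over leads; a beat is captured when its score
#' reaches the threshold. Scores are scale-invariant: rescaling all leads by
#' a positive constant changes no decision.
#'
#' @param segments A [extract_beat_segments()] result.
#' @param config A [deep_config()]; uses `capture.threshold`.
#' @return A data.frame of class `capture_result` with columns `time_ms`,
#'   `label`, `score` (in [-1, 1], NA when the segment was unavailable) and
#'   `captured`; or, when fewer than 2 S1 segments are available, a typed
#'   `"capture_indeterminate"` outcome (see [is_outcome()]) instructing the
#'   pipeline to skip decrement computation for the train.
#' @export
confirm_capture <- function(segments, config = deep_config()) {
  is_s1 <- segments$beat_labels == "S1"
  avail <- !vapply(segments$segments, is.null, logical(1))
  s1_avail <- which(is_s1 & avail)
  if (length(s1_avail) < 2L) {
    return(typed_outcome("capture_indeterminate",
                         "fewer than 2 usable S1 surface segments"))
  }
  # per-lead sample-wise median template over S1 segments
  arr <- simplify2array(segments$segments[s1_avail])  # samples x leads x beats
  template <- apply(arr, c(1, 2), stats::median)

  thr <- config$capture.threshold
  score <- rep(NA_real_, length(segments$segments))
  for (b in seq_along(segments$segments)) {
    seg <- segments$segments[[b]]
    if (is.null(seg)) next
    score[b] <- mean(vapply(seq_len(ncol(seg)), function(j) {
      safe_cor(seg[, j], template[, j])
    }, numeric(1)))
  }
  out <- data.frame(time_ms = segments$beat_times,
                    label = segments$beat_labels,
                    score = score,
                    captured = !is.na(score) & score >= thr,
                    stringsAsFactors = FALSE)
  class(out) <- c("capture_result", "data.frame")
  out
}

#' Is a whole train usable for decrement measurement?
#'
#' A train supports DeEP extraction only when the beats that enter the
#' measurement — the last 3 S1 beats and the extra-stimulus — are all
#' captured.
#'
#' @param capture A `capture_result` from [confirm_capture()].
#' @return `TRUE`/`FALSE`; `FALSE` with attribute `"reason"` naming the
#'   failing beats.
#' @export
train_usable <- function(capture) {
  s1 <- which(capture$label == "S1")
  s2 <- which(capture$label == "S2")
  last3 <- utils::tail(s1, 3L)
  need <- c(last3, s2)
  ok <- all(capture$captured[need])
  if (!ok) {
    bad <- need[!capture$captured[need]]
    attr(ok, "reason") <- sprintf(
      "capture not confirmed at %s",
      paste(sprintf("%s@%.0fms", capture$label[bad], capture$time_ms[bad]),
            collapse = ", "))
  }
  ok
}
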