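#' Detect pacing artifacts in a multichannel recording
#'
#' The pacing stimulus appears as an impulse-like, supra-threshold deflection
#' simultaneously on (nearly) every channel. Each channel is scanned for
#' samples exceeding the amplitude threshold; contiguous supra-threshold runs
#' closer than the refractory period are merged and represented by their
#' absolute peak. Per-channel peaks are then pooled and clustered across
#' channels within the coincidence window; a cluster seen on at least the
#' configured fraction of channels becomes one stimulus event (its time is
#' the median of the contributing peak times). A final refractory pass
#' suppresses double detections of a single artifact.
#'
#' @param recording A [deep_recording()].
#' @param config A [deep_config()]; uses `stimulus.threshold_mv`,
#'   `stimulus.coincidence_ms`, `stimulus.coincidence_fraction`,
#'   `stimulus.refractory_ms`.
#' @return A data.frame of class `stimulus_events` with columns `time_ms`
#'   (ascending) and `label` (all `"unknown"`; labels are assigned only by
#'   [classify_train()]). Zero rows when nothing crosses threshold.
#' @export
detect_pacing_artifacts <- function(recording, config = deep_config()) {
  fs <- recording$sampling_rate
  thr <- config$stimulus.threshold_mv
  refr <- config$stimulus.refractory_ms
  coin <- config$stimulus.coincidence_ms
  frac <- config$stimulus.coincidence_fraction

  all_ch <- cbind(recording$surface, recording$bipolar)
  n_ch <- ncol(all_ch)
  peaks_t <- numeric(0)
  peaks_ch <- integer(0)
  refr_n <- max(1L, as.integer(round(refr * fs / 1000)))

  for (j in seq_len(n_ch)) {
    x <- abs(all_ch[, j])
    over <- which(x > thr)
    if (length(over) == 0L) next
    # split supra-threshold samples into clusters separated by > refractory
    brk <- c(0L, which(diff(over) > refr_n), length(over))
    for (g in seq_len(length(brk) - 1L)) {
      seg <- over[(brk[g] + 1L):brk[g + 1L]]
      pk <- seg[which.max(x[seg])]
      peaks_t <- c(peaks_t, idx_to_ms(pk, fs))
      peaks_ch <- c(peaks_ch, j)
    }
  }

  empty <- data.frame(time_ms = numeric(0), label = character(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("stimulus_events", "data.frame")
  if (length(peaks_t) == 0L) return(empty)

  ord <- order(peaks_t)
  peaks_t <- peaks_t[ord]
  peaks_ch <- peaks_ch[ord]
  # cluster pooled peaks: a gap > coincidence window starts a new cluster
  cl <- cumsum(c(1, diff(peaks_t) > coin))
  need <- ceiling(frac * n_ch)
  times <- vapply(split(seq_along(peaks_t), cl), function(ii) {
    if (length(unique(peaks_ch[ii])) >= need)
      stats::median(peaks_t[ii]) else NA_real_
  }, numeric(1))
  times <- sort(times[!is.na(times)])

  # final refractory pass across events: keep an event only if it trails the
  # last kept one by at least the refractory period
  if (length(times) > 1L) {
    kept <- times[1L]
    for (t in times[-1L]) {
      if (t - kept[length(kept)] >= refr) kept <- c(kept, t)
    }
    times <- kept
  }
  out <- data.frame(time_ms = times,
                    label = rep("unknown", length(times)),
                    stringsAsFactors = FALSE)
  class(out) <- c("stimulus_events", "data.frame")
  out
}

#' Classify detected stimuli into the S1 drive train and the extra-stimulus
#'
#' Estimates the drive cycle length as the median inter-event interval after
#' discarding intervals shorter than half the running median (robust to the
#' single short extra-stimulus interval). Events whose preceding interval
#' lies within the jitter band of that cycle length are labelled S1. The
#' first event whose preceding interval is at least 10% shorter than the
#' drive cycle length is the premature extra-stimulus (S2) and ends the
#' train; later events are ignored. When no interval qualifies, the train
#' carries no S2 and downstream decrement computation must be skipped.
#'
#' @param events A `stimulus_events` data.frame (or anything with a
#'   `time_ms` column); at least 3 events. Input order is irrelevant (times
#'   are sorted internally).
#' @param config A [deep_config()]; uses `stimulus.jitter_fraction` and
#'   `stimulus.s2_shortening`.
#' @return A list of class `pace_train`: `s1_times` (ms, ascending),
#'   `s1_interval` (ms), `s2_time` (ms or NA), `s2_coupling_interval` (ms or
#'   NA), `has_s2` (logical).
#' @export
classify_train <- function(events, config = deep_config()) {
  times <- sort(as.numeric(events$time_ms))
  if (length(times) < 3L) {
    stop_typed("too_few_events", "need at least 3 stimulus events to classify")
  }
  d <- diff(times)

  # robust drive-cycle estimate: drop intervals < 50% of the running median
  keep <- d
  med <- stats::median(keep)
  repeat {
    drop <- keep < 0.5 * med
    if (!any(drop)) break
    keep <- keep[!drop]
    med <- stats::median(keep)
  }
  s1_interval <- med
  jit <- config$stimulus.jitter_fraction
  shorten <- config$stimulus.s2_shortening

  s1_times <- times[1L]
  s2_time <- NA_real_
  for (i in seq_along(d)) {
    if (d[i] <= (1 - shorten) * s1_interval) {
      s2_time <- times[i + 1L]            # premature: this is the extra-stimulus
      break
    }
    if (abs(d[i] - s1_interval) <= jit * s1_interval) {
      s1_times <- c(s1_times, times[i + 1L])
    } else {
      break                                # train break (long pause etc.)
    }
  }
  structure(
    list(s1_times = s1_times,
         s1_interval = s1_interval,
         s2_time = s2_time,
         s2_coupling_interval = if (is.na(s2_time)) NA_real_ else
           s2_time - s1_times[length(s1_times)],
         has_s2 = !is.na(s2_time)),
    class = "pace_train"
  )
}

#' @export
print.pace_train <- function(x, ...) {
  cat(sprintf("Pace train: %d S1 beats, cycle length %.1f ms\n",
              length(x$s1_times), x$s1_interval))
  if (x$has_s2) {
    cat(sprintf("  extra-stimulus at %.1f ms (coupling %.1f ms)\n",
                x$s2_time, x$s2_coupling_interval))
  } else {
    cat("  no extra-stimulus found (decrement computation not possible)\n")
  }
  invisible(x)
}
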