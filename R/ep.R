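#' Band-limit a bipolar channel for near-field analysis
#'
#' Near-field evoked potentials are sharp, high-frequency deflections from
#' tissue adjacent to the bipole, whereas the far-field paced ventricular
#' complex is smooth and low-frequency. Separation here is by zero-phase
#' Butterworth band-pass filtering (default 30-300 Hz) after blanking the
#' pacing artifacts: samples within `ep.blank_ms` of each stimulus are
#' replaced by linear interpolation so the multi-millivolt artifact cannot
#' ring through the filter into the evoked-potential search window.
#'
#' @param recording A [deep_recording()].
#' @param channel Bipolar channel name.
#' @param stimulus_times Times (ms) of all stimuli to blank.
#' @param config A [deep_config()]; uses `ep.band_hz`, `ep.blank_ms`.
#' @return Numeric vector: the filtered channel, same length as the input.
#' @export
bandlimit_channel <- function(recording, channel, stimulus_times,
                              config = deep_config()) {
  fs <- recording$sampling_rate
  x <- recording$bipolar[, channel]
  half <- as.integer(round(config$ep.blank_ms * fs / 1000))
  for (t in stimulus_times) {
    i0 <- max(1L, ms_to_idx(t, fs) - half)
    i1 <- min(length(x), ms_to_idx(t, fs) + half)
    x[i0:i1] <- seq(x[i0], x[i1], length.out = i1 - i0 + 1L)
  }
  band <- config$ep.band_hz
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

new_ep <- function(channel, stimulus_time, fiducial_ms, amplitude,
                   morphology) {
  structure(list(channel = channel, stimulus_time = stimulus_time,
                 latency = fiducial_ms - stimulus_time,
                 fiducial_ms = fiducial_ms, amplitude = amplitude,
                 morphology = morphology),
            class = "evoked_potential")
}

#' @export
print.evoked_potential <- function(x, ...) {
  cat(sprintf("Evoked potential on %s: latency %.2f ms, amplitude %.3f mV\n",
              x$channel, x$latency, x$amplitude))
  invisible(x)
}

# peak fiducial inside a half-open index window; NULL when nothing exceeds
# the floor or the morphology window would leave the recording
find_peak_ep <- function(xf, fs, channel, stim_ms, i0, i1, floor_mv,
                         half_n) {
  if (i1 <= i0 || i0 < 1L || i1 > length(xf) + 1L) return(NULL)
  win <- i0:(i1 - 1L)
  pk <- win[which.max(abs(xf[win]))]
  if (abs(xf[pk]) <= floor_mv) return(NULL)
  if (pk - half_n < 1L || pk + half_n > length(xf)) return(NULL)
  new_ep(channel, stim_ms, idx_to_ms(pk, fs), xf[pk],
         xf[(pk - half_n):(pk + half_n)])
}

#' Detect the S1 evoked potentials on the last 3 captured drive beats
#'
#' For each of the last 3 captured S1 beats, band-limits the channel (see
#' [bandlimit_channel()]), searches the post-stimulus window (default from
#' 10 ms after the stimulus to 90% of the drive cycle length) and takes the
#' time of maximum absolute amplitude as the evoked-potential fiducial,
#' provided it exceeds the noise floor (a configurable multiple of the
#' channel's robust MAD-based sd). The sampled window around the fiducial is
#' kept as the morphology template for stability assessment and S2
#' matching.
#'
#' @param recording A [deep_recording()].
#' @param train A [classify_train()] result.
#' @param channel Bipolar channel name.
#' @param capture Optional `capture_result`; when given, only captured S1
#'   beats are used. Default: all S1 beats assumed captured.
#' @param config A [deep_config()]; uses `ep.search_start_ms`,
#'   `ep.search_fraction`, `ep.noise_mult`, `ep.morphology_halfwidth_ms`
#'   plus the [bandlimit_channel()] keys.
#' @return A list of `evoked_potential` objects (one per beat, at most 3),
#'   or a typed `"insufficient_s1"` outcome when fewer than 3 captured S1
#'   beats exist or fewer than 3 evoked potentials rise above the noise
#'   floor.
#' @export
detect_s1_eps <- function(recording, train, channel, capture = NULL,
                          config = deep_config()) {
  fs <- recording$sampling_rate
  s1 <- train$s1_times
  if (!is.null(capture)) {
    cap_s1 <- capture$time_ms[capture$label == "S1" & capture$captured]
    s1 <- s1[s1 %in% cap_s1]
  }
  if (length(s1) < 3L) {
    return(typed_outcome("insufficient_s1",
                         sprintf("%d captured S1 beats on %s",
                                 length(s1), channel)))
  }
  s1 <- utils::tail(s1, 3L)
  stim_all <- c(train$s1_times, if (train$has_s2) train$s2_time)
  xf <- bandlimit_channel(recording, channel, stim_all, config)
  floor_mv <- config$ep.noise_mult * robust_sd(xf)
  half_n <- as.integer(round(config$ep.morphology_halfwidth_ms * fs / 1000))

  eps <- list()
  for (t in s1) {
    # search up to the configured fraction of the interval to the NEXT
    # stimulus (drive cycle length, or the shorter S2 coupling interval for
    # the last S1 beat), so a neighbouring response is never picked up
    nxt <- stim_all[stim_all > t]
    gap <- if (length(nxt) > 0L) min(nxt) - t else train$s1_interval
    i0 <- ms_to_idx(t + config$ep.search_start_ms, fs)
    i1 <- min(ms_to_idx(t + config$ep.search_fraction *
                          min(train$s1_interval, gap), fs),
              length(xf) + 1L)
    ep <- find_peak_ep(xf, fs, channel, t, i0, i1, floor_mv, half_n)
    if (!is.null(ep)) eps[[length(eps) + 1L]] <- ep
  }
  if (length(eps) < 3L) {
    return(typed_outcome("insufficient_s1",
                         sprintf("only %d of 3 S1 evoked potentials above the noise floor on %s",
                                 length(eps), channel)))
  }
  eps
}

#' Assess stability of the last 3 S1 evoked potentials
#'
#' The drive-train response must be stable before a decrement can be
#' attributed to the extra-stimulus. Stability combines timing and shape:
#' the population standard deviation of the 3 latencies must not exceed
#' `ep.stability_sd_ms`, and the mean of the 3 pairwise normalized
#' correlations between morphology windows must reach `ep.stability_corr`.
#' The result is invariant to the order of the 3 inputs.
#'
#' @param eps List of exactly 3 `evoked_potential` objects.
#' @param config A [deep_config()].
#' @return A list of class `stability_result`: `latency_sd` (ms),
#'   `mean_pairwise_morphology_correlation`, `stable` (logical); or a typed
#'   `"insufficient_s1"` outcome when fewer than 3 are supplied.
#' @export
assess_stability <- function(eps, config = deep_config()) {
  if (is_outcome(eps)) return(eps)
  if (length(eps) != 3L) {
    return(typed_outcome("insufficient_s1",
                         sprintf("need exactly 3 S1 evoked potentials, got %d",
                                 length(eps))))
  }
  lat <- vapply(eps, `[[`, numeric(1), "latency")
  sd3 <- pop_sd(lat)
  pairs <- utils::combn(3L, 2L)
  cors <- vapply(seq_len(ncol(pairs)), function(k) {
    safe_cor(eps[[pairs[1, k]]]$morphology, eps[[pairs[2, k]]]$morphology)
  }, numeric(1))
  mcor <- mean(cors)
  structure(
    list(latency_sd = sd3,
         mean_pairwise_morphology_correlation = mcor,
         stable = sd3 <= config$ep.stability_sd_ms &&
           mcor >= config$ep.stability_corr),
    class = "stability_result"
  )
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("S1 stability: latency sd %.2f ms, morphology correlation %.3f -> %s\n",
              x$latency_sd, x$mean_pairwise_morphology_correlation,
              if (x$stable) "stable" else "unstable"))
  invisible(x)
}

#' Detect the extra-stimulus evoked potential by template matching
#'
#' Slides the morphology template of the latest stable S1 evoked potential
#' over the band-limited post-S2 window (from `ep.search_start_ms` after the
#' extra-stimulus to the end of the recording). The lag is chosen by matched
#' filtering — the placement maximizing the inner product of template and
#' signal, which weights shape agreement by amplitude — and the match is
#' accepted only if that placement both contains a deflection above the
#' noise floor (the same `ep.noise_mult` floor used for S1 detection) and
#' reaches a normalized correlation of `ep.s2_match_threshold` with the
#' template; otherwise the evoked potential is reported absent — the
#' premature stimulus may simply have blocked.
#'
#' @param recording A [deep_recording()].
#' @param train A [classify_train()] result with an extra-stimulus.
#' @param channel Bipolar channel name.
#' @param s1_template The latest S1 `evoked_potential` (its morphology is
#'   the template).
#' @param config A [deep_config()].
#' @return An `evoked_potential` with attribute `"match_score"`; `NULL` when
#'   no placement correlates above threshold; a typed `"no_s2"` outcome when
#'   the train has no extra-stimulus.
#' @export
detect_s2_ep <- function(recording, train, channel, s1_template,
                         config = deep_config()) {
  if (!isTRUE(train$has_s2)) {
    return(typed_outcome("no_s2", "train has no extra-stimulus"))
  }
  fs <- recording$sampling_rate
  stim_all <- c(train$s1_times, train$s2_time)
  xf <- bandlimit_channel(recording, channel, stim_all, config)
  tmpl <- s1_template$morphology
  L <- length(tmpl)
  ctr <- (L - 1L) %/% 2L + 1L    # template centre = the S1 peak fiducial

  i0 <- ms_to_idx(train$s2_time + config$ep.search_start_ms, fs)
  i_last <- length(xf) - L + 1L
  if (i0 > i_last) return(NULL)
  starts <- i0:i_last
  # Lag choice is by matched filter (inner product of template and signal),
  # the optimal detector for a known waveform in additive noise: it weights
  # shape agreement by amplitude, so a genuine evoked potential dominates
  # low-amplitude noise stretches that happen to correlate with the
  # oscillatory template. The chosen placement must then pass two gates:
  # a supra-noise-floor deflection (same ep.noise_mult floor as S1
  # detection) and the normalized-correlation threshold.
  mf <- vapply(starts, function(p) {
    sum(tmpl * xf[p:(p + L - 1L)])
  }, numeric(1))
  best <- which.max(mf)
  floor_mv <- config$ep.noise_mult * robust_sd(xf)
  seg <- xf[starts[best]:(starts[best] + L - 1L)]
  if (max(abs(seg)) <= floor_mv) return(NULL)
  score <- safe_cor(tmpl, seg)
  if (score < config$ep.s2_match_threshold) return(NULL)
  pk <- starts[best] + ctr - 1L
  ep <- new_ep(channel, train$s2_time, idx_to_ms(pk, fs), xf[pk], seg)
  attr(ep, "match_score") <- score
  ep
}
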