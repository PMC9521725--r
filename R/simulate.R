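#' Configuration for the synthetic paced-recording generator
#'
#' Describes one extra-stimulus pacing acquisition: a drive train of `n_s1`
#' stimuli at cycle length `s1_interval` followed (optionally) by one
#' premature extra-stimulus at coupling interval `s2_coupling`, recorded on
#' surface leads and bipolar intracardiac channels. Each bipolar channel
#' carries a near-field evoked potential at `base_ep_latency` after every
#' captured S1, and at `base_ep_latency + planted_decrement` after S2; the
#' planted decrement is the ground-truth DeEP value the pipeline must
#' recover.
#'
#' @param n_channels Number of bipolar channels.
#' @param s1_interval Drive cycle length, ms (default 600).
#' @param n_s1 Number of S1 stimuli (default 8, minimum 4).
#' @param s2_coupling Coupling interval from the last S1 to the
#'   extra-stimulus, ms; must be shorter than `s1_interval` (default 300,
#'   near a typical ventricular effective refractory period at this cycle
#'   length).
#' @param include_s2 If `FALSE`, no extra-stimulus is delivered (the
#'   pipeline must then terminate without computing decrements).
#' @param base_ep_latency Per-channel S1 evoked-potential latency, ms
#'   (recycled to `n_channels`).
#' @param planted_decrement Per-channel decrement, ms; 0 means no DeEP
#'   (recycled).
#' @param s2_block Per-channel logical; `TRUE` omits the S2 evoked potential
#'   entirely (conduction block at the extra-stimulus).
#' @param pacing_artifact_amplitude Biphasic stimulus-artifact amplitude, mV.
#' @param qrs_amplitude Surface paced-QRS amplitude, mV.
#' @param far_field_amplitude Far-field ventricular deflection amplitude on
#'   bipolar channels, mV.
#' @param ep_amplitude Near-field evoked-potential amplitude, mV.
#' @param noise_sd Additive white-noise standard deviation, mV.
#' @param capture_failure_beats Integer beat indices (1..n_s1 for S1 beats,
#'   n_s1 + 1 for S2) that fail to capture: the pacing artifact is kept but
#'   QRS, far-field and evoked potential are omitted.
#' @param sampling_rate Hz, >= 1000 (default 1000).
#' @param surface_leads Lead names (default the 12 standard leads).
#' @param channel_names Bipolar channel names (default B1..Bn).
#' @param pre_ms Quiescent time before the first stimulus, ms.
#' @param tail_ms Quiescent time after the last planted event, ms.
#' @param rng_seed Integer seed; one global seed drives all randomness
#'   (noise streams and electrode geometry), so identical seeds give
#'   bit-identical recordings.
#' @return A list of class `sim_config`.
#' @seealso [simulate_recording()]
#' @export
sim_config <- function(n_channels = 20,
                       s1_interval = 600,
                       n_s1 = 8,
                       s2_coupling = 300,
                       include_s2 = TRUE,
                       base_ep_latency = 40,
                       planted_decrement = 0,
                       s2_block = FALSE,
                       pacing_artifact_amplitude = 5,
                       qrs_amplitude = 1,
                       far_field_amplitude = 0.2,
                       ep_amplitude = 0.5,
                       noise_sd = 0.01,
                       capture_failure_beats = integer(0),
                       sampling_rate = 1000,
                       surface_leads = c("I", "II", "III", "aVR", "aVL",
                                         "aVF", "V1", "V2", "V3", "V4",
                                         "V5", "V6"),
                       channel_names = NULL,
                       pre_ms = 100,
                       tail_ms = 500,
                       rng_seed = 1L) {
  if (n_s1 < 4) stop_typed("bad_sim_config", "n_s1 must be >= 4")
  if (include_s2 && s2_coupling >= s1_interval) {
    stop_typed("bad_sim_config", "s2_coupling must be < s1_interval")
  }
  if (noise_sd < 0) stop_typed("bad_sim_config", "noise_sd must be >= 0")
  if (sampling_rate < 1000) {
    stop_typed("bad_sim_config", "sampling_rate must be >= 1000 Hz")
  }
  if (is.null(channel_names)) channel_names <- sprintf("B%d", seq_len(n_channels))
  base_ep_latency <- rep_len(base_ep_latency, n_channels)
  planted_decrement <- rep_len(planted_decrement, n_channels)
  s2_block <- rep_len(s2_block, n_channels)

  # The evoked-potential wavelet spans ~15 ms; its window must not cross the
  # next stimulus (S1 EP before the following S1 or before S2; S2 EP before
  # recording end, which the generator sizes itself).
  half_ep <- 8
  bad <- which(base_ep_latency + half_ep >=
                 min(s1_interval, if (include_s2) s2_coupling else Inf))
  if (length(bad) > 0L) {
    stop_typed("bad_sim_config",
               paste0("EP window would overlap the next stimulus on channel(s): ",
                      paste(channel_names[bad], collapse = ", ")))
  }
  structure(
    list(n_channels = n_channels, s1_interval = s1_interval, n_s1 = n_s1,
         s2_coupling = s2_coupling, include_s2 = include_s2,
         base_ep_latency = base_ep_latency,
         planted_decrement = planted_decrement, s2_block = s2_block,
         pacing_artifact_amplitude = pacing_artifact_amplitude,
         qrs_amplitude = qrs_amplitude,
         far_field_amplitude = far_field_amplitude,
         ep_amplitude = ep_amplitude, noise_sd = noise_sd,
         capture_failure_beats = as.integer(capture_failure_beats),
         sampling_rate = sampling_rate, surface_leads = surface_leads,
         channel_names = channel_names, pre_ms = pre_ms, tail_ms = tail_ms,
         rng_seed = as.integer(rng_seed)),
    class = "sim_config"
  )
}

# Waveform primitives. Shapes are stylized but spectrally realistic: the
# pacing artifact is broadband and impulse-like, the paced QRS is smooth and
# low-frequency (~10 Hz content, removed by the 30-300 Hz near-field band),
# and the evoked potential is a symmetric 150-Hz Gabor wavelet whose absolute
# maximum sits exactly at its centre sample, so the planted peak fiducial is
# unambiguous.

waveform_artifact <- function(fs, amp) {
  n <- max(2L, as.integer(round(2 * fs / 1000)))  # 2 ms biphasic
  half <- n %/% 2L
  c(rep(amp, half), rep(-amp, n - half))
}

waveform_qrs <- function(fs, amp) {
  t <- seq(0, 100, by = 1000 / fs)
  amp * (exp(-((t - 30) / 10)^2) - 0.45 * exp(-((t - 55) / 14)^2))
}

waveform_ep <- function(fs, amp) {
  n <- as.integer(round(15 * fs / 1000)) + 1L
  ic <- (n - 1L) %/% 2L + 1L               # centre on an exact sample
  t <- (seq_len(n) - ic) * 1000 / fs
  w <- amp * cos(2 * pi * 0.15 * t) * exp(-(t / 3.5)^2)
  attr(w, "peak_index") <- ic
  w
}

add_at <- function(x, start_idx, w) {
  idx <- seq.int(start_idx, length.out = length(w))
  keep <- idx >= 1L & idx <= length(x)
  x[idx[keep]] <- x[idx[keep]] + w[keep]
  x
}

#' Generate a synthetic paced recording with planted ground truth
#'
#' Builds the multichannel waveform described by a [sim_config()]: an
#' impulse-like pacing artifact at every stimulus time on all channels, a
#' common paced-QRS template on the surface leads for every captured beat, a
#' far-field deflection plus a near-field evoked-potential wavelet on each
#' bipolar channel (the S2 wavelet delayed by the planted decrement), and
#' additive white Gaussian noise. Capture-failure beats keep the artifact
#' but omit QRS, far-field and evoked potential. All randomness derives from
#' `config$rng_seed`, so identical configs give bit-identical output.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_result` with elements `recording` (a
#'   [deep_recording()]) and `truth`, where `truth` holds `stimulus_times`
#'   (data.frame time_ms/label), `latencies` (beats x channels matrix of
#'   planted sample-quantized EP latencies, NA when absent), `true_deep`
#'   (named per-channel planted decrement, NA for blocked channels),
#'   `captured` (per-beat logical) and `s2_time` (ms or NA).
#' @export
#' @examples
#' sim <- simulate_recording(sim_config(n_channels = 3, noise_sd = 0,
#'                                      planted_decrement = c(0, 20, 40)))
#' sim$truth$true_deep
simulate_recording <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$sampling_rate
  dt <- 1000 / fs
  n_beats <- config$n_s1 + as.integer(config$include_s2)

  s1_times <- config$pre_ms + (seq_len(config$n_s1) - 1L) * config$s1_interval
  stim_times <- s1_times
  labels <- rep("S1", config$n_s1)
  s2_time <- NA_real_
  if (config$include_s2) {
    s2_time <- s1_times[config$n_s1] + config$s2_coupling
    stim_times <- c(stim_times, s2_time)
    labels <- c(labels, "S2")
  }
  # quantize stimulus times to the sample grid
  stim_idx <- ms_to_idx(stim_times, fs)
  stim_times <- idx_to_ms(stim_idx, fs)
  if (config$include_s2) s2_time <- stim_times[n_beats]

  max_lat <- max(config$base_ep_latency +
                   ifelse(is.na(config$planted_decrement), 0,
                          config$planted_decrement))
  n_samp <- ms_to_idx(stim_times[n_beats] + max_lat + config$tail_ms, fs)

  captured <- !(seq_len(n_beats) %in% config$capture_failure_beats)

  art <- waveform_artifact(fs, config$pacing_artifact_amplitude)
  qrs <- waveform_qrs(fs, config$qrs_amplitude)
  ffd <- waveform_qrs(fs, config$far_field_amplitude)
  ep <- waveform_ep(fs, config$ep_amplitude)
  ep_peak <- attr(ep, "peak_index")
  qrs_onset_ms <- 20

  set.seed(config$rng_seed)

  n_surf <- length(config$surface_leads)
  surface <- matrix(0, n_samp, n_surf,
                    dimnames = list(NULL, config$surface_leads))
  # per-lead fixed polarity/scale so leads differ but beats are identical
  lead_scale <- seq(0.6, 1.4, length.out = n_surf) *
    rep_len(c(1, -1), n_surf)
  for (j in seq_len(n_surf)) {
    x <- numeric(n_samp)
    for (b in seq_len(n_beats)) {
      x <- add_at(x, stim_idx[b], art)
      if (captured[b]) {
        x <- add_at(x, stim_idx[b] + as.integer(round(qrs_onset_ms / dt)),
                    lead_scale[j] * qrs)
      }
    }
    if (config$noise_sd > 0) x <- x + stats::rnorm(n_samp, 0, config$noise_sd)
    surface[, j] <- x
  }

  bipolar <- matrix(0, n_samp, config$n_channels,
                    dimnames = list(NULL, config$channel_names))
  latencies <- matrix(NA_real_, n_beats, config$n_channels,
                      dimnames = list(NULL, config$channel_names))
  for (j in seq_len(config$n_channels)) {
    x <- numeric(n_samp)
    for (b in seq_len(n_beats)) {
      x <- add_at(x, stim_idx[b], art)
      if (!captured[b]) next
      x <- add_at(x, stim_idx[b] + as.integer(round(qrs_onset_ms / dt)), ffd)
      is_s2 <- config$include_s2 && b == n_beats
      if (is_s2 && config$s2_block[j]) next
      lat <- config$base_ep_latency[j] +
        if (is_s2) config$planted_decrement[j] else 0
      peak_idx <- stim_idx[b] + as.integer(round(lat / dt))
      x <- add_at(x, peak_idx - ep_peak + 1L, as.numeric(ep))
      latencies[b, j] <- idx_to_ms(peak_idx, fs) - stim_times[b]
    }
    if (config$noise_sd > 0) x <- x + stats::rnorm(n_samp, 0, config$noise_sd)
    bipolar[, j] <- x
  }

  # electrode geometry: deterministic cloud on a shell (radius 25-29 mm),
  # compatible with the default 30-mm chamber mesh
  u <- matrix(stats::rnorm(3 * config$n_channels), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  r <- stats::runif(config$n_channels, 25, 29)
  positions <- u * r
  dimnames(positions) <- list(config$channel_names, c("x", "y", "z"))

  recording <- deep_recording(fs, surface, bipolar, positions)
  true_deep <- ifelse(config$s2_block, NA_real_, config$planted_decrement)
  names(true_deep) <- config$channel_names
  truth <- list(
    stimulus_times = data.frame(time_ms = stim_times, label = labels,
                                stringsAsFactors = FALSE),
    latencies = latencies,
    true_deep = true_deep,
    captured = captured,
    s2_time = s2_time
  )
  structure(list(recording = recording, truth = truth, config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Synthetic paced recording\n")
  cat(sprintf("  beats   : %d S1 @ %g ms%s\n", x$config$n_s1,
              x$config$s1_interval,
              if (x$config$include_s2)
                sprintf(" + S2 at %g ms coupling", x$config$s2_coupling)
              else " (no extra-stimulus)"))
  cat(sprintf("  channels: %d bipolar, %d surface, fs %g Hz\n",
              ncol(x$recording$bipolar), ncol(x$recording$surface),
              x$recording$sampling_rate))
  cat(sprintf("  planted decrements (ms): %s\n",
              paste(format(x$truth$true_deep, digits = 3), collapse = ", ")))
  invisible(x)
}
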