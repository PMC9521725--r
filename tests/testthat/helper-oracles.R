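# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: the kappa oracle counts unit-by-unit, and the
# stimulus oracle is a plain threshold-crossing scan of the raw waveform.

# Cohen's kappa by explicit enumeration over units: observed agreement and
# chance agreement are accumulated one unit at a time from empirical
# marginal frequencies.
brute_kappa <- function(a, b) {
  n <- length(a)
  agree <- 0
  for (i in seq_len(n)) if (a[i] == b[i]) agree <- agree + 1
  p_o <- agree / n
  na1 <- 0; nb1 <- 0
  for (i in seq_len(n)) {
    if (a[i]) na1 <- na1 + 1
    if (b[i]) nb1 <- nb1 + 1
  }
  p_e <- (na1 / n) * (nb1 / n) + ((n - na1) / n) * ((n - nb1) / n)
  if (abs(1 - p_e) < 1e-12) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

# Brute-force stimulus scan on a clean (noise-free) multichannel waveform:
# a stimulus is any run of samples whose absolute value crosses `thr` on
# more than half the channels, merged when closer than `merge_ms`.
brute_stimulus_scan <- function(channels, fs, thr, merge_ms = 50) {
  n_ch <- ncol(channels)
  over_count <- rowSums(abs(channels) > thr)
  hot <- which(over_count >= ceiling(n_ch / 2))
  if (length(hot) == 0L) return(numeric(0))
  gaps <- which(diff(hot) > merge_ms * fs / 1000)
  starts <- hot[c(1L, gaps + 1L)]
  (starts - 1L) * 1000 / fs
}

# A small clean reference simulation shared by several test files.
clean_sim <- function(decrements = c(0, 20, 40), ...) {
  simulate_recording(sim_config(n_channels = length(decrements),
                                planted_decrement = decrements,
                                noise_sd = 0, ...))
}
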