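# Minimal WFDB reader/writer: single-segment records, all channels in one
# format-16 signal file (16-bit little-endian two's complement), one header
# line per signal with gain(baseline)/mV, first value and the standard
# 16-bit checksum. This covers the subset of the WFDB specification needed
# for interchange of paced multichannel recordings.

#' Write a multichannel signal matrix as a WFDB record
#'
#' @param signals Numeric matrix, samples x channels, named columns; mV.
#' @param fs Sampling frequency, Hz.
#' @param dir Output directory.
#' @param record Record name (basename of `.hea`/`.dat`).
#' @param gain ADC units per mV (default 1000, 1 µV resolution). Values are
#'   rounded to integer ADC units; digital values must fit in 16 bits.
#' @return The record path (without extension), invisibly.
#' @export
write_wfdb <- function(signals, fs, dir, record = "signals", gain = 1000) {
  signals <- as.matrix(signals)
  n_sig <- ncol(signals)
  n_samp <- nrow(signals)
  digital <- round(signals * gain)
  if (any(abs(digital) > 32767)) {
    stop_typed("wfdb_range",
               "signal exceeds the 16-bit range at this gain; lower the gain")
  }
  storage.mode(digital) <- "integer"

  dat_name <- paste0(record, ".dat")
  # sample-interleaved: s1[1] s2[1] ... then next frame
  interleaved <- as.integer(t(digital))
  con <- file(file.path(dir, dat_name), "wb")
  writeBin(interleaved, con, size = 2L, endian = "little")
  close(con)

  checksums <- vapply(seq_len(n_sig), function(j) {
    s <- sum(as.numeric(digital[, j])) %% 65536
    if (s >= 32768) s <- s - 65536
    as.integer(s)
  }, integer(1))

  hea <- c(
    sprintf("%s %d %s %d", record, n_sig, fmt_full(fs), n_samp),
    sprintf("%s 16 %s(0)/mV 16 0 %d %d 0 %s",
            dat_name, fmt_full(gain), digital[1, ], checksums,
            colnames(signals))
  )
  writeLines(hea, file.path(dir, paste0(record, ".hea")))
  invisible(file.path(dir, record))
}

#' Read a WFDB record written in format 16
#'
#' @param record Path to the record without extension (reads `record.hea`
#'   and the `.dat` file it names).
#' @return A list with `signals` (samples x channels matrix, mV), `fs` and
#'   `gain` (per-channel).
#' @export
read_wfdb <- function(record) {
  hea_path <- paste0(record, ".hea")
  if (!file.exists(hea_path)) {
    stop_typed("bad_header", paste0("no WFDB header at ", hea_path))
  }
  lines <- readLines(hea_path)
  lines <- lines[!grepl("^#", lines)]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 3L) stop_typed("bad_header", "malformed WFDB record line")
  n_sig <- as.integer(top[2])
  fs <- as.numeric(top[3])
  n_samp <- if (length(top) >= 4L) as.integer(top[4]) else NA_integer_

  sig_lines <- lines[2:(1 + n_sig)]
  parse_sig <- function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    fmt <- f[2]
    if (fmt != "16") {
      stop_typed("unsupported_format",
                 paste0("only WFDB format 16 is supported, got ", fmt))
    }
    gain_spec <- f[3]
    gain <- as.numeric(sub("\\(.*", "", sub("/.*", "", gain_spec)))
    baseline <- 0
    if (grepl("\\(", gain_spec)) {
      baseline <- as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_spec))
    }
    list(file = f[1], gain = gain, baseline = baseline,
         checksum = if (length(f) >= 7L) as.integer(f[7]) else NA_integer_,
         name = if (length(f) >= 9L) f[9] else NA_character_)
  }
  info <- lapply(sig_lines, parse_sig)
  dat_files <- unique(vapply(info, `[[`, character(1), "file"))
  if (length(dat_files) != 1L) {
    stop_typed("unsupported_format",
               "multi-file WFDB records are not supported")
  }
  dat_path <- file.path(dirname(hea_path), dat_files)
  raw_n <- file.size(dat_path) / 2L
  con <- file(dat_path, "rb")
  digital <- readBin(con, integer(), n = raw_n, size = 2L, signed = TRUE,
                     endian = "little")
  close(con)
  mat <- matrix(digital, ncol = n_sig, byrow = TRUE)
  if (!is.na(n_samp) && nrow(mat) != n_samp) {
    stop_typed("bad_header",
               sprintf("signal length mismatch: header %d, data %d",
                       n_samp, nrow(mat)))
  }
  for (j in seq_len(n_sig)) {
    cs <- sum(as.numeric(mat[, j])) %% 65536
    if (cs >= 32768) cs <- cs - 65536
    if (!is.na(info[[j]]$checksum) && cs != info[[j]]$checksum) {
      stop_typed("bad_checksum",
                 sprintf("checksum mismatch on signal %d", j))
    }
  }
  gains <- vapply(info, `[[`, numeric(1), "gain")
  baselines <- vapply(info, `[[`, numeric(1), "baseline")
  physical <- sweep(sweep(mat, 2L, baselines, `-`), 2L, gains, `/`)
  colnames(physical) <- vapply(info, `[[`, character(1), "name")
  list(signals = physical, fs = fs, gain = gains)
}
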