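#' Write a recording to the interchange directory format
#'
#' The interchange layout is a directory holding a JSON header
#' (`header.json`: sampling rate, channel names, electrode coordinates) plus
#' the signals in one of two dialects: `"csv"` — a single `signals.csv` with
#' one column per channel, written with 17 significant digits so doubles
#' round-trip bit-exactly — or `"wfdb"` — a WFDB record (`.hea` header and
#' 16-bit binary `.dat`), exact at the declared ADC gain.
#'
#' @param recording A [deep_recording()].
#' @param path Output directory (created if needed).
#' @param format `"csv"` (default, lossless) or `"wfdb"`.
#' @param gain WFDB ADC gain in units per mV (default 1000, i.e. 1 µV
#'   resolution); ignored for CSV.
#' @return `path`, invisibly.
#' @seealso [read_recording()]
#' @export
write_recording <- function(recording, path, format = c("csv", "wfdb"),
                            gain = 1000) {
  format <- match.arg(format)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  header <- list(
    sampling_rate = recording$sampling_rate,
    surface_channels = as.list(colnames(recording$surface)),
    bipolar_channels = as.list(colnames(recording$bipolar)),
    electrode_positions = lapply(colnames(recording$bipolar), function(ch) {
      as.numeric(recording$positions[ch, ])
    }),
    duration = recording$duration,
    signal_format = format
  )
  names(header$electrode_positions) <- colnames(recording$bipolar)
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  all_ch <- cbind(recording$surface, recording$bipolar)
  if (format == "csv") {
    txt <- apply(all_ch, 2L, fmt_full)
    utils::write.table(txt, file.path(path, "signals.csv"),
                       sep = ",", row.names = FALSE,
                       col.names = colnames(all_ch), quote = FALSE)
  } else {
    write_wfdb(all_ch, recording$sampling_rate, path, record = "signals",
               gain = gain)
  }
  invisible(path)
}

#' Read a recording from the interchange directory format
#'
#' Counterpart of [write_recording()]; the dialect is taken from the header
#' (`signal_format`) or detected from the files present. Malformed headers
#' raise an error naming the offending field; a length mismatch between
#' header and signal file is an error.
#'
#' @param path Directory holding `header.json` plus `signals.csv` or a WFDB
#'   record.
#' @return A [deep_recording()].
#' @export
read_recording <- function(path) {
  hpath <- file.path(path, "header.json")
  if (!file.exists(hpath)) {
    stop_typed("bad_header", paste0("no header.json in ", path))
  }
  header <- jsonlite::read_json(hpath, simplifyVector = TRUE)
  for (field in c("sampling_rate", "surface_channels", "bipolar_channels",
                  "electrode_positions", "duration")) {
    if (is.null(header[[field]])) {
      stop_typed("bad_header", paste0("header field missing: ", field))
    }
  }
  fmt <- header$signal_format
  if (is.null(fmt)) {
    fmt <- if (file.exists(file.path(path, "signals.csv"))) "csv" else "wfdb"
  }
  if (fmt == "csv") {
    sig <- as.matrix(utils::read.csv(file.path(path, "signals.csv"),
                                     check.names = FALSE))
  } else {
    w <- read_wfdb(file.path(path, "signals"))
    sig <- w$signals
  }
  surf_names <- unlist(header$surface_channels)
  bip_names <- unlist(header$bipolar_channels)
  missing_ch <- setdiff(c(surf_names, bip_names), colnames(sig))
  if (length(missing_ch) > 0L) {
    stop_typed("bad_header", paste0("channels in header but not in signals: ",
                                    paste(missing_ch, collapse = ", ")))
  }
  if (nrow(sig) != header$duration) {
    stop_typed("bad_header",
               sprintf("duration: header says %d samples but signals have %d",
                       header$duration, nrow(sig)))
  }
  pos <- do.call(rbind, header$electrode_positions[bip_names])
  dimnames(pos) <- list(bip_names, c("x", "y", "z"))
  deep_recording(header$sampling_rate,
                 sig[, surf_names, drop = FALSE],
                 sig[, bip_names, drop = FALSE],
                 pos)
}
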