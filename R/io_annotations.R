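#' Read and write annotation CSV files
#'
#' Annotations are event marks bound to channels: the CSV dialect has
#' columns `channel`, `time_ms`, `label` (e.g. S1/S2/EP/DeEP) and
#' `deep_value_ms` (NA when the mark carries no decrement). Stimulus-event
#' tables and decrement results both travel in this dialect.
#'
#' @param annotations Data.frame with (a subset of) the four columns.
#' @param path CSV file path.
#' @return For the writer, `path` invisibly; for the reader, a data.frame
#'   with exactly the four columns in canonical order.
#' @export
write_annotations <- function(annotations, path) {
  out <- data.frame(
    channel = if ("channel" %in% names(annotations))
      annotations$channel else NA_character_,
    time_ms = if ("time_ms" %in% names(annotations))
      annotations$time_ms else NA_real_,
    label = if ("label" %in% names(annotations))
      annotations$label else NA_character_,
    deep_value_ms = if ("deep_value_ms" %in% names(annotations))
      annotations$deep_value_ms else NA_real_,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) {
    stop_typed("missing_file", paste0("no annotation file at ", path))
  }
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("channel", "time_ms", "label", "deep_value_ms")
  for (col in setdiff(needed, names(ann))) ann[[col]] <- NA
  ann[, needed]
}

#' Write the planted ground truth of a simulation to CSV
#'
#' @param sim A [simulate_recording()] result.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(sim, path) {
  truth <- sim$truth
  stim <- data.frame(channel = "", time_ms = truth$stimulus_times$time_ms,
                     label = truth$stimulus_times$label,
                     deep_value_ms = NA_real_, stringsAsFactors = FALSE)
  deep <- data.frame(channel = names(truth$true_deep),
                     time_ms = NA_real_, label = "DeEP",
                     deep_value_ms = as.numeric(truth$true_deep),
                     stringsAsFactors = FALSE)
  write_annotations(rbind(stim, deep), path)
}
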