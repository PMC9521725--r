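#' Pipeline configuration with namespaced defaults
#'
#' One flat list of namespaced keys (`stimulus.*`, `capture.*`, `ep.*`,
#' `deep.*`, `map.*`, `validate.*`) controls every stage. All values have
#' working defaults; any subset can be overridden by name, or loaded from a
#' JSON document with the same keys.
#'
#' Key defaults (units in key names' stage docs):
#' \describe{
#'   \item{stimulus.threshold_mv}{Pacing-artifact amplitude threshold, 2 mV.}
#'   \item{stimulus.coincidence_ms}{Cross-channel coincidence window, 2 ms.}
#'   \item{stimulus.coincidence_fraction}{Fraction of channels that must see
#'     the artifact, 0.5.}
#'   \item{stimulus.refractory_ms}{Detector dead time, 50 ms.}
#'   \item{stimulus.jitter_fraction}{S1 inter-stimulus jitter band, 0.05.}
#'   \item{stimulus.s2_shortening}{Minimum relative shortening that
#'     identifies the extra-stimulus, 0.10.}
#'   \item{capture.window_ms}{Post-stimulus surface window, c(20, 140).}
#'   \item{capture.threshold}{Per-beat correlation needed for capture, 0.90.}
#'   \item{capture.leads}{Lead names to correlate; NULL = all leads.}
#'   \item{ep.band_hz}{Near-field band limits, c(30, 300) Hz.}
#'   \item{ep.search_start_ms}{EP search start after the stimulus, 10 ms.}
#'   \item{ep.search_fraction}{S1 search end as fraction of the drive cycle
#'     length, 0.9.}
#'   \item{ep.noise_mult}{Detection floor as multiple of the robust noise sd,
#'     3.}
#'   \item{ep.morphology_halfwidth_ms}{Half-width of the morphology/template
#'     window around the peak fiducial, 10 ms.}
#'   \item{ep.blank_ms}{Half-width of the pacing-artifact blanking window, 3 ms.}
#'   \item{ep.stability_sd_ms}{Maximum S1 latency sd called stable, 5 ms.}
#'   \item{ep.stability_corr}{Minimum mean pairwise morphology correlation
#'     called stable, 0.85.}
#'   \item{ep.s2_match_threshold}{Minimum normalized template cross-correlation
#'     accepted as the S2 EP, 0.7.}
#'   \item{deep.display_threshold_ms}{Minimum decrement displayed (strict >),
#'     10 ms.}
#'   \item{map.radius_mm}{Influence radius for voltage interpolation, 10 mm.}
#'   \item{map.idw_power}{Inverse-distance weighting exponent, 2.}
#'   \item{map.sphere.r_min}{Sphere radius offset, 1 mm.}
#'   \item{map.sphere.k}{Sphere radius per ms of decrement, 0.05 mm/ms.}
#'   \item{map.projection_limit_mm}{Maximum electrode-to-mesh projection
#'     distance, 15 mm.}
#'   \item{map.scar_mv, map.border_mv}{Conventional voltage-map colour
#'     thresholds (0.5 / 1.5 mV), exported as metadata only.}
#'   \item{validate.tolerance_ms}{Event-matching tolerance, 10 ms.}
#'   \item{validate.change_tolerance_ms}{Decrement difference separating
#'     "unchanged" from "changed" corrections, 5 ms.}
#' }
#'
#' @param ... Named overrides, e.g. `deep.display_threshold_ms = 0`.
#' @param file Optional path to a JSON config document; values there are
#'   applied before `...` overrides.
#' @return A named list of class `deep_config`.
#' @export
#' @examples
#' cfg <- deep_config(deep.display_threshold_ms = 0)
#' cfg$deep.display_threshold_ms
deep_config <- function(..., file = NULL) {
  cfg <- list(
    stimulus.threshold_mv = 2.0,
    stimulus.coincidence_ms = 2.0,
    stimulus.coincidence_fraction = 0.5,
    stimulus.refractory_ms = 50,
    stimulus.jitter_fraction = 0.05,
    stimulus.s2_shortening = 0.10,
    capture.window_ms = c(20, 140),
    capture.threshold = 0.90,
    capture.leads = NULL,
    ep.band_hz = c(30, 300),
    ep.search_start_ms = 10,
    ep.search_fraction = 0.9,
    ep.noise_mult = 3,
    ep.morphology_halfwidth_ms = 10,
    ep.blank_ms = 3,
    ep.stability_sd_ms = 5,
    ep.stability_corr = 0.85,
    ep.s2_match_threshold = 0.7,
    deep.display_threshold_ms = 10,
    map.radius_mm = 10,
    map.idw_power = 2,
    map.sphere.r_min = 1,
    map.sphere.k = 0.05,
    map.projection_limit_mm = 15,
    map.scar_mv = 0.5,
    map.border_mv = 1.5,
    validate.tolerance_ms = 10,
    validate.change_tolerance_ms = 5
  )
  if (!is.null(file)) {
    loaded <- jsonlite::read_json(file, simplifyVector = TRUE)
    cfg <- apply_overrides(cfg, loaded, source = file)
  }
  dots <- list(...)
  cfg <- apply_overrides(cfg, dots, source = "arguments")
  structure(cfg, class = "deep_config")
}

apply_overrides <- function(cfg, overrides, source) {
  if (length(overrides) == 0L) return(cfg)
  nm <- names(overrides)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop_typed("bad_config", paste0("unnamed config entries in ", source))
  }
  unknown <- setdiff(nm, names(cfg))
  if (length(unknown) > 0L) {
    stop_typed("bad_config",
               paste0("unknown config keys in ", source, ": ",
                      paste(unknown, collapse = ", ")))
  }
  for (k in nm) cfg[[k]] <- overrides[[k]]
  cfg
}

#' @export
print.deep_config <- function(x, ...) {
  cat("deepmapr pipeline configuration\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-32s %s\n", k,
                if (is.null(v)) "NULL" else paste(format(v), collapse = ", ")))
  }
  invisible(x)
}

#' Write a configuration to JSON
#' @param config A `deep_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}
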