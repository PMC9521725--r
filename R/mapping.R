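#' Build a per-vertex bipolar voltage map on the chamber surface
#'
#' Each electrode contributes the peak-to-peak amplitude (mV) of its bipolar
#' electrogram in the window after the last captured S1 stimulus (the
#' conventional bipolar-voltage measurement on a paced beat). Vertex values
#' are inverse-distance-weighted averages of the electrodes within the
#' influence radius; vertices with no electrode in range are `NA` (no-data).
#' A constant field is reproduced exactly: if all electrodes read v, every
#' covered vertex reads v.
#'
#' @param recording A [deep_recording()].
#' @param train A [classify_train()] result.
#' @param mesh A [generate_mesh()] result.
#' @param capture Optional `capture_result` used to pick the last captured
#'   S1 beat; default: last S1 beat.
#' @param config A [deep_config()]; uses `map.radius_mm`, `map.idw_power`.
#' @param window_ms Measurement window after the stimulus, default
#'   `c(0, 200)`.
#' @return A list of class `voltage_map`: `vertex_voltage` (length = number
#'   of vertices, mV, `NA` = no data), `electrode_voltage` (named, mV),
#'   `mesh`, plus colour-threshold metadata `scar_mv`/`border_mv`.
#' @export
build_voltage_map <- function(recording, train, mesh, capture = NULL,
                              config = deep_config(),
                              window_ms = c(0, 200)) {
  fs <- recording$sampling_rate
  s1 <- train$s1_times
  if (!is.null(capture)) {
    cap <- capture$time_ms[capture$label == "S1" & capture$captured]
    if (length(cap) > 0L) s1 <- s1[s1 %in% cap]
  }
  t0 <- utils::tail(s1, 1L)
  i0 <- max(1L, ms_to_idx(t0 + window_ms[1], fs))
  i1 <- min(recording$duration, ms_to_idx(t0 + window_ms[2], fs) - 1L)
  seg <- recording$bipolar[i0:i1, , drop = FALSE]
  ev <- apply(seg, 2L, function(x) max(x) - min(x))

  pos <- recording$positions[colnames(recording$bipolar), , drop = FALSE]
  vv <- idw_interpolate(mesh$vertices, pos, ev,
                        radius = config$map.radius_mm,
                        power = config$map.idw_power)
  if (all(is.na(vv))) {
    warning("no electrode lies within the influence radius of any vertex; ",
            "voltage map is all no-data")
  }
  structure(list(vertex_voltage = vv, electrode_voltage = ev, mesh = mesh,
                 scar_mv = config$map.scar_mv, border_mv = config$map.border_mv),
            class = "voltage_map")
}

# inverse-distance-weighted interpolation from scattered sources to targets;
# targets with no source within `radius` get NA; a target coincident with a
# source gets that source's value exactly
idw_interpolate <- function(targets, sources, values, radius, power = 2) {
  n <- nrow(targets)
  out <- rep(NA_real_, n)
  if (nrow(sources) == 0L) return(out)
  for (i in seq_len(n)) {
    d <- sqrt(rowSums(sweep(sources, 2L, targets[i, ], `-`)^2))
    use <- which(d <= radius)
    if (length(use) == 0L) next
    if (any(d[use] < 1e-9)) {
      out[i] <- mean(values[use[d[use] < 1e-9]])
    } else {
      w <- 1 / d[use]^power
      out[i] <- sum(w * values[use]) / sum(w)
    }
  }
  out
}

#' Place size-scaled decrement spheres on the chamber surface
#'
#' Every displayed decrement point is projected to its nearest mesh vertex
#' and represented by a sphere whose radius grows linearly with the
#' decrement: `radius = r_min + k * deep_ms`, so larger decrements give
#' strictly larger spheres. Points farther from the mesh than the projection
#' limit are excluded with a warning (they cannot be attributed to the
#' mapped surface); non-displayed points yield no sphere.
#'
#' @param points A `deep_points` data.frame with `displayed` computed.
#' @param mesh A [generate_mesh()] result.
#' @param config A [deep_config()]; uses `map.sphere.r_min`, `map.sphere.k`,
#'   `map.projection_limit_mm`.
#' @return A data.frame of class `deep_spheres`: `channel`, `cx`, `cy`,
#'   `cz` (sphere centre = nearest-vertex position, mm), `radius_mm`,
#'   `deep_ms`.
#' @export
place_deep_spheres <- function(points, mesh, config = deep_config()) {
  if (any(is.na(points$displayed))) {
    stop_typed("threshold_not_applied",
               "run apply_display_threshold() before placing spheres")
  }
  shown <- points[points$displayed, , drop = FALSE]
  empty <- data.frame(channel = character(0), cx = numeric(0),
                      cy = numeric(0), cz = numeric(0),
                      radius_mm = numeric(0), deep_ms = numeric(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("deep_spheres", "data.frame")
  if (nrow(shown) == 0L) return(empty)

  pos <- as.matrix(shown[, c("x", "y", "z")])
  nv <- nearest_vertices(mesh, pos)
  ok <- nv$distance <= config$map.projection_limit_mm
  if (any(!ok)) {
    warning(sprintf("excluded %d point(s) farther than %g mm from the mesh: %s",
                    sum(!ok), config$map.projection_limit_mm,
                    paste(shown$channel[!ok], collapse = ", ")))
  }
  shown <- shown[ok, , drop = FALSE]
  centres <- mesh$vertices[nv$index[ok], , drop = FALSE]
  out <- data.frame(channel = shown$channel,
                    cx = centres[, 1], cy = centres[, 2], cz = centres[, 3],
                    radius_mm = config$map.sphere.r_min +
                      config$map.sphere.k * shown$deep_ms,
                    deep_ms = shown$deep_ms,
                    stringsAsFactors = FALSE)
  class(out) <- c("deep_spheres", "data.frame")
  out
}
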