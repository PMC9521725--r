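#' Compute the decrement (DeEP) value for one bipolar electrode
#'
#' The decrement evoked potential value is the extra time, in ms, that the
#' near-field response needs after the premature extra-stimulus compared
#' with the drive train: `deep = s2 latency - latest S1 latency`. Positive
#' values mean decremental conduction (the substrate of interest); a
#' negative value means the S2 response was detected earlier than the S1
#' response, which indicates an upstream detection fault and is therefore
#' retained and flagged rather than clipped to zero.
#'
#' @param s1_ep The latest stable S1 `evoked_potential`.
#' @param s2_ep The extra-stimulus `evoked_potential` on the same channel.
#' @return Numeric decrement in ms, with attribute `"flag"` set to
#'   `"negative"` when below zero.
#' @export
#' @examples
#' s1 <- deepmapr:::new_ep("B1", 0, 40, 0.5, numeric(3))
#' s2 <- deepmapr:::new_ep("B1", 100, 175, 0.5, numeric(3))
#' compute_deep(s1, s2)  # 35 ms
compute_deep <- function(s1_ep, s2_ep) {
  if (!identical(s1_ep$channel, s2_ep$channel)) {
    stop_typed("channel_mismatch",
               sprintf("S1 evoked potential is on %s but S2 on %s",
                       s1_ep$channel, s2_ep$channel))
  }
  v <- s2_ep$latency - s1_ep$latency
  if (is.finite(v) && v < 0) attr(v, "flag") <- "negative"
  v
}

#' Assemble per-electrode decrement points
#'
#' @param channel Character vector of channel names.
#' @param position n x 3 matrix of electrode positions (mm).
#' @param deep_value Numeric decrements (ms).
#' @param status Detection provenance, one of `auto`, `expert_confirmed`,
#'   `expert_changed`, `expert_deleted`, `expert_added`.
#' @param flags Character, e.g. "negative" (default "").
#' @return A data.frame of class `deep_points` with columns `channel`, `x`,
#'   `y`, `z`, `deep_ms`, `displayed` (initially `NA`; set by
#'   [apply_display_threshold()]), `status`, `flags`.
#' @export
deep_points <- function(channel, position, deep_value,
                        status = "auto", flags = "") {
  position <- matrix(as.numeric(position), ncol = 3)
  out <- data.frame(channel = channel,
                    x = position[, 1], y = position[, 2], z = position[, 3],
                    deep_ms = as.numeric(deep_value),
                    displayed = rep(NA, length(channel)),
                    status = rep_len(status, length(channel)),
                    flags = rep_len(flags, length(channel)),
                    stringsAsFactors = FALSE)
  class(out) <- c("deep_points", "data.frame")
  out
}

#' Apply the minimum-decrement display threshold
#'
#' Only decrements of interest are shown on the map; the threshold is
#' strict, so a point exactly at the threshold is hidden. The conventional
#' clinical setting is >10 ms.
#'
#' @param points A `deep_points` data.frame.
#' @param threshold Minimum decrement in ms (>= 0); default 10.
#' @return The same data.frame with the `displayed` flag set:
#'   `displayed == (deep_ms > threshold)`.
#' @export
#' @examples
#' pts <- deep_points("B1", c(0, 0, 0), 10)
#' apply_display_threshold(pts, 10)$displayed  # FALSE: strictly greater only
apply_display_threshold <- function(points, threshold = 10) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0) {
    stop_typed("bad_threshold", "threshold must be a single number >= 0")
  }
  points$displayed <- is.finite(points$deep_ms) & points$deep_ms > threshold
  points
}
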