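#' Confusion counts
#'
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @return A list of class `confusion_counts` with `tp`, `tn`, `fp`, `fn`
#'   and `total`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  v <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(v < 0) || any(v != round(v))) {
    stop_typed("bad_counts", "confusion counts must be non-negative integers")
  }
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 total = tp + tn + fp + fn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion counts (n = %d): TP %d, TN %d, FP %d, FN %d\n",
              x$total, x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

# normalize an annotation set to one row per unit (channel here); a unit is
# "marked" when it carries at least one decrement annotation
annotation_units <- function(set) {
  if (is.data.frame(set)) {
    if (!"channel" %in% names(set)) {
      stop_typed("bad_annotations", "annotation set needs a 'channel' column")
    }
    if (anyDuplicated(set$channel)) {
      stop_typed("duplicate_marks",
                 "overlapping duplicate marks on one unit are not allowed")
    }
    has_mark <- if ("marked" %in% names(set)) as.logical(set$marked)
                else rep(TRUE, nrow(set))
    dv <- if ("deep_value_ms" %in% names(set)) set$deep_value_ms
          else rep(NA_real_, nrow(set))
    data.frame(channel = as.character(set$channel), marked = has_mark,
               deep_value_ms = dv, stringsAsFactors = FALSE)
  } else {
    stop_typed("bad_annotations", "annotation set must be a data.frame")
  }
}

#' Score algorithm annotations against an expert gold standard
#'
#' The scored unit is one potential decrement site (one channel of one
#' pacing train). A unit is a true positive when both the algorithm and the
#' expert mark a decrement there, a true negative when neither does, a
#' false positive when only the algorithm does, and a false negative when
#' only the expert does. Units present in only one set are scored against
#' an implicit "not marked" on the other side, with a warning.
#'
#' @param algorithm,expert Annotation data.frames with columns `channel`,
#'   optionally `marked` (logical; default all `TRUE`) and `deep_value_ms`.
#' @param tolerance Matching tolerance in ms, recorded on matched pairs.
#' @return A list of class `agreement_report`: `counts` (a
#'   [confusion_counts()]), `pairs` (data.frame of matched units with both
#'   decrement values and their difference), `tolerance_ms`.
#' @export
match_annotations <- function(algorithm, expert, tolerance = 10) {
  a <- annotation_units(algorithm)
  e <- annotation_units(expert)
  only_a <- setdiff(a$channel, e$channel)
  only_e <- setdiff(e$channel, a$channel)
  if (length(only_a) + length(only_e) > 0L) {
    warning(sprintf("units present in one set only: %s",
                    paste(c(only_a, only_e), collapse = ", ")))
  }
  units <- union(a$channel, e$channel)
  am <- a$marked[match(units, a$channel)]
  em <- e$marked[match(units, e$channel)]
  am[is.na(am)] <- FALSE
  em[is.na(em)] <- FALSE

  counts <- confusion_counts(tp = sum(am & em), tn = sum(!am & !em),
                             fp = sum(am & !em), fn = sum(!am & em))
  both <- units[am & em]
  pairs <- data.frame(
    channel = both,
    algorithm_ms = a$deep_value_ms[match(both, a$channel)],
    expert_ms = e$deep_value_ms[match(both, e$channel)],
    stringsAsFactors = FALSE
  )
  pairs$difference_ms <- pairs$algorithm_ms - pairs$expert_ms
  pairs$within_tolerance <- !is.na(pairs$difference_ms) &
    abs(pairs$difference_ms) <= tolerance
  structure(list(counts = counts, pairs = pairs, tolerance_ms = tolerance),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  print(x$counts)
  se <- sensitivity(x$counts)
  sp <- specificity(x$counts)
  cat(sprintf("  sensitivity %s, specificity %s\n",
              if (is.na(se)) "undefined" else sprintf("%.1f%%", se),
              if (is.na(sp)) "undefined" else sprintf("%.1f%%", sp)))
  invisible(x)
}

#' Sensitivity (true-positive rate) in percent
#'
#' `100 * tp / (tp + fn)`. Undefined (returned as `NA` with attribute
#' `"undefined"`) when no positive units exist — never coerced to 0 or 100.
#'
#' @param counts A [confusion_counts()].
#' @return Percent, full precision (callers round for display).
#' @export
#' @examples
#' sensitivity(confusion_counts(tp = 1451, tn = 1812, fp = 136, fn = 281))
sensitivity <- function(counts) {
  if (counts$tp + counts$fn == 0L) {
    return(structure(NA_real_, undefined = TRUE))
  }
  100 * counts$tp / (counts$tp + counts$fn)
}

#' Specificity (true-negative rate) in percent
#'
#' `100 * tn / (tn + fp)`; `NA` with attribute `"undefined"` when no
#' negative units exist.
#'
#' @param counts A [confusion_counts()].
#' @return Percent, full precision.
#' @export
specificity <- function(counts) {
  if (counts$tn + counts$fp == 0L) {
    return(structure(NA_real_, undefined = TRUE))
  }
  100 * counts$tn / (counts$tn + counts$fp)
}

#' Cohen's kappa for two binary annotation sets
#'
#' Chance-corrected agreement between two raters labelling the same units
#' as decrement / no-decrement: `kappa = (p_o - p_e) / (1 - p_e)` where
#' `p_o` is the observed agreement fraction and `p_e` the agreement expected
#' from the marginals of the 2x2 cross-tabulation. When `p_e = 1` (both
#' raters degenerate on the same class) kappa is undefined and `NA` is
#' returned with attribute `"undefined"`.
#'
#' @param rater_a,rater_b Either logical vectors over the same units, or
#'   annotation data.frames (see [match_annotations()]) covering identical
#'   unit sets.
#' @return Kappa in [-1, 1], or undefined `NA`.
#' @export
cohen_kappa <- function(rater_a, rater_b) {
  if (is.data.frame(rater_a)) {
    a <- annotation_units(rater_a)
    b <- annotation_units(rater_b)
    if (!setequal(a$channel, b$channel)) {
      stop_typed("unit_mismatch", "raters must annotate the same units")
    }
    units <- a$channel
    la <- a$marked
    lb <- b$marked[match(units, b$channel)]
  } else {
    la <- as.logical(rater_a)
    lb <- as.logical(rater_b)
    if (length(la) != length(lb)) {
      stop_typed("unit_mismatch", "raters must annotate the same units")
    }
  }
  n <- length(la)
  if (n == 0L) stop_typed("unit_mismatch", "no units to compare")
  p_o <- mean(la == lb)
  p_a <- mean(la)
  p_b <- mean(lb)
  p_e <- p_a * p_b + (1 - p_a) * (1 - p_b)
  if (abs(1 - p_e) < .Machine$double.eps * 4) {
    return(structure(NA_real_, undefined = TRUE))
  }
  (p_o - p_e) / (1 - p_e)
}

#' Categorize expert corrections of algorithm detections
#'
#' The expert-corrected set is scored against the raw algorithm output using
#' the four-way taxonomy: a detection is *unchanged* when a corrected mark
#' remains on the same unit with a decrement within `change_tolerance`;
#' *changed* when the corrected decrement differs by more; *deleted* when
#' the expert removed it; marks the expert *added* have no algorithm
#' counterpart. Percentages are over the union total (algorithm detections
#' plus added marks).
#'
#' @param algorithm Annotation data.frame of algorithm detections (columns
#'   `channel`, `deep_value_ms`).
#' @param corrected The expert-corrected annotation data.frame.
#' @param change_tolerance Decrement difference (ms) separating unchanged
#'   from changed; default 5.
#' @return A list of class `correction_breakdown`: integer `counts`
#'   (unchanged/changed/deleted/added), `total`, and `percentages` (one
#'   decimal, sum 100 within rounding).
#' @export
#' @examples
#' alg <- data.frame(channel = c("a", "b", "c"), deep_value_ms = c(20, 30, 40))
#' cor <- data.frame(channel = c("a", "b", "d"), deep_value_ms = c(20, 55, 12))
#' categorize_corrections(alg, cor)
categorize_corrections <- function(algorithm, corrected,
                                   change_tolerance = 5) {
  a <- annotation_units(algorithm)
  cset <- annotation_units(corrected)
  a <- a[a$marked, , drop = FALSE]
  cset <- cset[cset$marked, , drop = FALSE]

  m <- match(a$channel, cset$channel)
  deleted <- sum(is.na(m))
  have <- which(!is.na(m))
  dv <- abs(a$deep_value_ms[have] - cset$deep_value_ms[m[have]])
  dv[is.na(dv)] <- 0   # no value recorded on either side: position kept as-is
  unchanged <- sum(dv <= change_tolerance)
  changed <- sum(dv > change_tolerance)
  added <- sum(!(cset$channel %in% a$channel))

  counts <- c(unchanged = unchanged, changed = changed,
              deleted = deleted, added = added)
  total <- sum(counts)
  structure(list(counts = counts, total = total,
                 percentages = round(100 * counts / total, 1)),
            class = "correction_breakdown")
}

#' @export
print.correction_breakdown <- function(x, ...) {
  cat(sprintf("Correction breakdown over %d detections:\n", x$total))
  for (k in names(x$counts)) {
    cat(sprintf("  %-10s %5d  (%.1f%%)\n", k, x$counts[[k]],
                x$percentages[[k]]))
  }
  invisible(x)
}

#' Histogram of decrement values over half-open bins
#'
#' Bins are `[e_i, e_{i+1})`; values outside the edge range are not
#' counted. Used to profile where corrections concentrate along the
#' decrement axis.
#'
#' @param values Numeric decrement values (ms), or a `deep_points`
#'   data.frame (its `deep_ms` column is used).
#' @param bin_edges Strictly increasing numeric edges.
#' @return Named integer counts, one per bin.
#' @export
#' @examples
#' histogram_by_deep(c(5, 12, 160), c(0, 50, 150, 300))
histogram_by_deep <- function(values, bin_edges) {
  if (is.data.frame(values)) values <- values$deep_ms
  if (length(bin_edges) < 2L || any(diff(bin_edges) <= 0)) {
    stop_typed("bad_edges", "bin edges must be strictly increasing")
  }
  k <- length(bin_edges) - 1L
  counts <- integer(k)
  bin <- findInterval(values, bin_edges, rightmost.closed = FALSE)
  inside <- bin >= 1L & bin <= k & values < bin_edges[k + 1L]
  tab <- table(factor(bin[inside], levels = seq_len(k)))
  counts <- as.integer(tab)
  names(counts) <- sprintf("[%g,%g)", bin_edges[-(k + 1L)], bin_edges[-1L])
  counts
}
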