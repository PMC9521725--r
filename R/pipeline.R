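#' Run the full decrement-detection workflow on one recording
#'
#' Executes the automatic workflow in clinical order: pacing-artifact
#' detection, S1/S2 train classification, capture confirmation on the
#' surface ECG, S1 evoked-potential detection and stability assessment on
#' the last 3 captured drive beats, extra-stimulus evoked-potential
#' detection by template matching, per-electrode decrement computation, the
#' display threshold, and (when a mesh is supplied) voltage-map construction
#' and sphere placement. Early terminations — no extra-stimulus, capture
#' indeterminate, insufficient or unstable S1 responses — are logged with a
#' typed reason and produce no decrement for the affected scope; they are
#' never raised as errors.
#'
#' @param recording A [deep_recording()].
#' @param mesh Optional [generate_mesh()] result; enables the mapping stage.
#' @param config A [deep_config()].
#' @return An object of class `deep_map`: `train`, `capture`, `points`
#'   (a `deep_points` data.frame with the display flag applied), `spheres`
#'   and `voltage_map` (when a mesh was given), `log` (data.frame with
#'   columns stage/scope/decision/reason), `disposition` (the train's single
#'   terminal disposition) and `config`.
#' @seealso [run_pipeline()] for the file-level front end.
#' @export
#' @examples
#' sim <- simulate_recording(sim_config(n_channels = 3, noise_sd = 0,
#'                                      planted_decrement = c(0, 20, 40)))
#' fit <- deep_detect(sim$recording)
#' summary(fit)
deep_detect <- function(recording, mesh = NULL, config = deep_config()) {
  log <- data.frame(stage = character(0), scope = character(0),
                    decision = character(0), reason = character(0),
                    stringsAsFactors = FALSE)
  add_log <- function(stage, scope, decision, reason = "") {
    log[nrow(log) + 1L, ] <<- list(stage, scope, decision, reason)
  }
  finish <- function(disposition, train = NULL, capture = NULL,
                     points = NULL, vmap = NULL, spheres = NULL) {
    if (is.null(points)) {
      points <- apply_display_threshold(
        deep_points(character(0), matrix(numeric(0), ncol = 3), numeric(0)),
        config$deep.display_threshold_ms)
    }
    add_log("train", "train", disposition)
    structure(list(train = train, capture = capture, points = points,
                   voltage_map = vmap, spheres = spheres, log = log,
                   disposition = disposition, config = config),
              class = "deep_map")
  }

  events <- detect_pacing_artifacts(recording, config)
  add_log("stimulus_detection", "train", "events",
          sprintf("%d pacing artifacts detected", nrow(events)))
  if (nrow(events) < 3L) {
    return(finish("too_few_events"))
  }
  train <- classify_train(events, config)
  if (!train$has_s2) {
    add_log("stimulus_detection", "train", "no_s2",
            "no qualifying extra-stimulus interval; no DeEP calculation performed")
    return(finish("no_s2", train = train))
  }
  add_log("stimulus_detection", "train", "s2_found",
          sprintf("S1 interval %.1f ms, coupling %.1f ms",
                  train$s1_interval, train$s2_coupling_interval))

  segments <- extract_beat_segments(recording, train, config)
  capture <- confirm_capture(segments, config)
  if (is_outcome(capture)) {
    add_log("capture_confirmation", "train", capture$type, capture$detail)
    return(finish("capture_indeterminate", train = train))
  }
  usable <- train_usable(capture)
  if (!usable) {
    add_log("capture_confirmation", "train", "capture_indeterminate",
            attr(usable, "reason"))
    return(finish("capture_indeterminate", train = train, capture = capture))
  }
  add_log("capture_confirmation", "train", "captured",
          sprintf("min score over decisive beats %.3f",
                  min(capture$score[capture$captured], na.rm = TRUE)))

  channels <- colnames(recording$bipolar)
  rows <- list()
  for (ch in channels) {
    eps <- detect_s1_eps(recording, train, ch, capture, config)
    if (is_outcome(eps)) {
      add_log("ep_detection", ch, eps$type, eps$detail)
      next
    }
    stab <- assess_stability(eps, config)
    if (!stab$stable) {
      add_log("ep_detection", ch, "unstable_s1",
              sprintf("latency sd %.2f ms, morphology correlation %.3f",
                      stab$latency_sd,
                      stab$mean_pairwise_morphology_correlation))
      next
    }
    s1_last <- eps[[length(eps)]]
    s2_ep <- detect_s2_ep(recording, train, ch, s1_last, config)
    if (is_outcome(s2_ep)) {
      add_log("ep_detection", ch, s2_ep$type, s2_ep$detail)
      next
    }
    if (is.null(s2_ep)) {
      add_log("ep_detection", ch, "s2_ep_absent",
              "no template match above threshold (possible block)")
      next
    }
    dv <- compute_deep(s1_last, s2_ep)
    flag <- attr(dv, "flag")
    add_log("deep_computation", ch, "deep",
            sprintf("%.2f ms%s", dv,
                    if (is.null(flag)) "" else paste0(" [", flag, "]")))
    rows[[ch]] <- deep_points(ch, recording$positions[ch, ],
                              as.numeric(dv),
                              flags = if (is.null(flag)) "" else flag)
  }
  points <- if (length(rows) > 0L) {
    p <- do.call(rbind, rows)
    rownames(p) <- NULL
    class(p) <- c("deep_points", "data.frame")
    p
  } else NULL
  pts <- if (is.null(points)) NULL else
    apply_display_threshold(points, config$deep.display_threshold_ms)

  vmap <- NULL
  spheres <- NULL
  if (!is.null(mesh) && !is.null(pts)) {
    vmap <- build_voltage_map(recording, train, mesh, capture, config)
    spheres <- place_deep_spheres(pts, mesh, config)
    add_log("mapping", "train", "mapped",
            sprintf("%d spheres placed", nrow(spheres)))
  }
  finish("completed", train = train, capture = capture, points = pts,
         vmap = vmap, spheres = spheres)
}

#' @export
print.deep_map <- function(x, ...) {
  cat("Decrement evoked potential detection\n")
  cat(sprintf("  disposition: %s\n", x$disposition))
  if (!is.null(x$train)) print(x$train)
  if (nrow(x$points) > 0L) {
    cat(sprintf("  %d decrement value(s), %d above the %g ms display threshold\n",
                nrow(x$points), sum(x$points$displayed),
                x$config$deep.display_threshold_ms))
  } else {
    cat("  no decrement values computed\n")
  }
  invisible(x)
}

#' @export
summary.deep_map <- function(object, ...) {
  cat("Decrement evoked potential detection - summary\n")
  cat(sprintf("  terminal disposition : %s\n", object$disposition))
  if (!is.null(object$capture)) {
    cat(sprintf("  beats captured       : %d / %d\n",
                sum(object$capture$captured), nrow(object$capture)))
  }
  skip <- object$log[object$log$stage == "ep_detection" &
                       object$log$decision != "deep", , drop = FALSE]
  if (nrow(skip) > 0L) {
    tab <- table(skip$decision)
    cat("  channels skipped     :",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  if (nrow(object$points) > 0L) {
    cat(sprintf("  decrements (ms)      : median %.1f, range [%.1f, %.1f]\n",
                stats::median(object$points$deep_ms),
                min(object$points$deep_ms), max(object$points$deep_ms)))
    cat(sprintf("  displayed (> %g ms)  : %d of %d\n",
                object$config$deep.display_threshold_ms,
                sum(object$points$displayed), nrow(object$points)))
  }
  invisible(object)
}

#' @export
plot.deep_map <- function(x, ...) {
  if (nrow(x$points) == 0L) {
    graphics::plot.new()
    graphics::title("No decrement values computed")
    return(invisible(x))
  }
  p <- x$points[order(x$points$deep_ms), ]
  thr <- x$config$deep.display_threshold_ms
  cols <- ifelse(p$displayed, "firebrick", "grey60")
  graphics::barplot(p$deep_ms, names.arg = p$channel, las = 2,
                    col = cols, border = NA,
                    ylab = "decrement (ms)",
                    main = "Per-electrode decrement evoked potentials", ...)
  graphics::abline(h = thr, lty = 2)
  graphics::mtext(sprintf("display threshold %g ms", thr), side = 3,
                  cex = 0.8)
  invisible(x)
}

#' File-level pipeline: read inputs, run detection, write all outputs
#'
#' Thin orchestration over [deep_detect()]: reads a recording directory and
#' an optional mesh (VTK/PLY as written by [export_map()]), runs the
#' workflow, and writes the decrement results CSV
#' (`channel,x,y,z,deep_ms,displayed,flags`), the map files and a structured
#' run log (one JSON object per line) into `out_dir`. Results files are
#' byte-identical across runs on identical inputs; timestamps live only in
#' the log.
#'
#' @param recording_path Recording interchange directory.
#' @param out_dir Output directory (created if needed).
#' @param mesh Optional `deep_mesh` object (takes precedence), or `NULL`.
#' @param config_path Optional JSON config file.
#' @param map_format `"vtk"` or `"ply"`.
#' @return The `deep_map` object, invisibly.
#' @export
run_pipeline <- function(recording_path, out_dir, mesh = NULL,
                         config_path = NULL, map_format = "vtk") {
  config <- if (is.null(config_path)) deep_config() else
    deep_config(file = config_path)
  recording <- read_recording(recording_path)
  fit <- deep_detect(recording, mesh = mesh, config = config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  utils::write.csv(as.data.frame(fit$points),
                   file.path(out_dir, "deep_results.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(fit$voltage_map)) {
    export_map(fit$voltage_map, fit$spheres, file.path(out_dir, "map"),
               format = map_format)
  }
  log_lines <- vapply(seq_len(nrow(fit$log)), function(i) {
    jsonlite::toJSON(c(as.list(fit$log[i, ]),
                       list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(log_lines, file.path(out_dir, "run_log.jsonl"))
  invisible(fit)
}
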