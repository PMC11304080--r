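#' Run configuration
#'
#' The five required user inputs are the data type, frame rate, length
#' scale, a stiffness source (measured `stiffness` in uN/um, or a `geometry`
#' block with `E`, `a`, `L` and cross-section dimensions), and the tissue
#' depth. Everything else has defaults.
#'
#' @param data_type `"type1"` or `"type2"`.
#' @param fps frame rate, frames/second.
#' @param length_scale um per pixel.
#' @param stiffness pillar stiffness in uN/um (omit if `geometry` given).
#' @param geometry named list with `E`, `a`, `L` and either `w` + `t`
#'   (rectangular) or `D` (circular), plus optional `cross_section`.
#' @param tissue_depth tissue depth in um.
#' @param tissue_width optional manual tissue width in um (used if the
#'   automatic measurement fails).
#' @param split perform the per-beat drift-correcting split?
#' @param drift_tol drift tolerance at valley frames, px.
#' @param irregular_tol relative tolerance for irregular-beat flagging.
#' @param seed integer seed for reproducibility of any randomized step.
#' @return object of class `run_config`.
#' @export
run_config <- function(data_type = c("type1", "type2"), fps, length_scale,
                       stiffness = NULL, geometry = NULL, tissue_depth = NA,
                       tissue_width = NULL, split = FALSE, drift_tol = 0.5,
                       irregular_tol = 0.25, seed = 1L) {
  data_type <- match.arg(data_type)
  stopifnot(fps > 0, length_scale > 0)
  if (is.null(stiffness) == is.null(geometry))
    stop("supply exactly one stiffness source: stiffness, or geometry")
  structure(list(data_type = data_type, fps = fps,
                 length_scale = length_scale, stiffness = stiffness,
                 geometry = geometry, tissue_depth = tissue_depth,
                 tissue_width = tissue_width, split = isTRUE(split),
                 drift_tol = drift_tol, irregular_tol = irregular_tol,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @param ... overrides applied on top of the file values.
#' @return a [run_config()].
#' @export
read_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

config_mechanics <- function(config) {
  if (!is.null(config$stiffness)) {
    mechanics_params(k = config$stiffness, tissue_depth = config$tissue_depth,
                     length_scale = config$length_scale, fps = config$fps)
  } else {
    g <- config$geometry
    mechanics_params(E = g$E, a = g$a, L = g$L, w = g$w, t = g$t, D = g$D,
                     cross_section = g$cross_section %||%
                       if (!is.null(g$D)) "circular" else "rectangular",
                     tissue_depth = config$tissue_depth,
                     length_scale = config$length_scale, fps = config$fps)
  }
}

#' Analyze one microbundle movie end to end
#'
#' Full pipeline: pillar segmentation (or externally supplied masks),
#' Shi-Tomasi marker detection with auto-tuned parameters, pyramidal
#' Lucas-Kanade tracking, valley identification and start adjustment
#' (with a second tracking pass when the movie does not open fully
#' relaxed), drift detection, optional per-beat drift-correcting split,
#' irregular-beat flagging, and conversion of deflections to forces and
#' stresses with per-beat temporal metrics. When `output_dir` is given all
#' artifacts (masks, raw marker positions, traces, metrics, plots, warnings,
#' machine-readable flags) are written under it.
#'
#' @param input a movie path (folder of TIFFs or multi-page TIFF) or a
#'   [frame_stack()].
#' @param config a [run_config()].
#' @param masks optional list of `left`/`right` [pillar_mask()]s to use
#'   instead of automatic segmentation.
#' @param output_dir optional output directory.
#' @return object of class `contractility_result`.
#' @export
run_single <- function(input, config, masks = NULL, output_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  warn_log <- character(0)
  result <- withCallingHandlers(
    run_single_impl(input, config, masks, output_dir),
    pillartrack_warning = function(w) {
      warn_log <<- c(warn_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  result$warnings <- warn_log
  if (!is.null(output_dir)) {
    writeLines(warn_log, file.path(output_dir, "warnings.txt"))
    jsonlite::write_json(
      list(drift_detected = result$beat_segmentation$drift_detected,
           split_applied = result$beat_segmentation$split_applied,
           irregular_beats = which(result$irregular_flags),
           n_complete_beats = result$beat_segmentation$n_complete_beats,
           warnings = warn_log),
      file.path(output_dir, "flags.json"), auto_unbox = TRUE)
  }
  result
}

run_single_impl <- function(input, config, masks, output_dir) {
  stack <- if (inherits(input, "frame_stack")) input
           else read_movie(input, fps = config$fps,
                           length_scale = config$length_scale)
  if (is.na(stack$fps)) stack$fps <- config$fps
  if (is.na(stack$length_scale)) stack$length_scale <- config$length_scale

  frame1 <- get_frame(stack, 1)
  if (is.null(masks))
    masks <- segment_pillars_threshold(frame1, config$data_type)

  tracks <- track_pillars(stack, masks)
  disp <- pillar_displacement(tracks)
  valleys <- find_valleys(disp$contraction)

  adj <- adjust_start(stack, tracks, valleys, masks)
  stack <- adj$stack; tracks <- adj$tracks
  disp <- adj$displacement; valleys <- adj$valleys

  drift <- detect_drift(disp$mean_abs, valleys, tol = config$drift_tol)
  if (drift$drift_detected)
    pt_warn(sprintf(
      "drift detected: valley offset up to %.2f px exceeds tolerance %.2f px",
      max(drift$valley_offsets), config$drift_tol), "pt_drift")

  split_applied <- FALSE
  beat_traces <- NULL
  if (config$split && drift$drift_detected) {
    beat_traces <- split_beats(tracks, valleys)   # errors if < 3 beats
    split_applied <- TRUE
  }
  seg <- beat_segmentation(valleys, n_frames(stack),
                           drift_detected = drift$drift_detected,
                           split_applied = split_applied)

  mech <- config_mechanics(config)
  ls <- config$length_scale
  time_s <- (disp$frame - 1) / config$fps
  disp_um <- data.frame(time = time_s,
                        left = disp$abs_left * ls,
                        right = disp$abs_right * ls,
                        mean = disp$mean_abs * ls)
  force_un <- data.frame(time = time_s,
                         left = force_trace(disp_um$left, mech$k),
                         right = force_trace(disp_um$right, mech$k),
                         mean = force_trace(disp_um$mean, mech$k))

  width_um <- tryCatch(
    measure_tissue_width(get_frame(stack, 1), masks, ls),
    error = function(e) {
      if (!is.null(config$tissue_width)) return(config$tissue_width)
      pt_warn(paste0("tissue width unavailable (", conditionMessage(e),
                     "); stress not computed"), "pt_width")
      NA_real_
    })
  stress <- if (is.finite(width_um) && is.finite(config$tissue_depth)) {
    data.frame(time = time_s,
               mean = stress_trace(force_un$mean, width_um,
                                   config$tissue_depth))
  } else NULL

  # per-beat metrics on the mean deflection trace (um); with the split
  # applied, each beat is measured against its own baseline
  beat_rows <- lapply(seq_len(seg$n_complete_beats), function(b) {
    rng <- valleys[b]:valleys[b + 1L]
    tr <- if (split_applied) beat_traces[[b]]$mean_abs * ls
          else disp_um$mean[rng]
    tm <- temporal_metrics(tr, config$fps)
    if (is.null(tm)) return(NULL)
    data.frame(beat = b, start_frame = valleys[b], end_frame = valleys[b + 1],
               period_s = (valleys[b + 1] - valleys[b]) / config$fps,
               amplitude_um = tm$amplitude,
               peak_force_un = tm$amplitude * mech$k,
               contraction_velocity_um_s = tm$contraction_velocity,
               relaxation_velocity_um_s = tm$relaxation_velocity,
               fwhm_s = tm$fwhm, fw80m_s = tm$fw80m)
  })
  beat_table <- do.call(rbind, beat_rows)
  irregular <- if (!is.null(beat_table) && nrow(beat_table) >= 2) {
    detect_irregular_beats(beat_table$period_s, beat_table$amplitude_um,
                           tol = config$irregular_tol)
  } else logical(0)

  result <- structure(list(
    displacement_px = disp, displacement_um = disp_um, force_un = force_un,
    stress = stress, tissue_width_um = width_um,
    beat_segmentation = seg, beat_table = beat_table,
    irregular_flags = irregular,
    beating_rate_hz = if (seg$n_complete_beats > 0)
      config$fps / mean(diff(valleys)) else NA_real_,
    masks = masks, tracks = tracks, mechanics = mech, config = config
  ), class = "contractility_result")
  if (!is.null(output_dir)) write_result(result, output_dir)
  result
}

#' @export
print.contractility_result <- function(x, ...) {
  bt <- x$beat_table
  cat("<contractility_result>\n")
  cat(sprintf("  beats: %d complete | rate: %.3f Hz | drift: %s | split: %s\n",
              x$beat_segmentation$n_complete_beats, x$beating_rate_hz,
              x$beat_segmentation$drift_detected,
              x$beat_segmentation$split_applied))
  if (!is.null(bt) && nrow(bt) > 0)
    cat(sprintf(
      "  mean peak force: %.3f uN | mean amplitude: %.3f um | mean FWHM: %.3f s\n",
      mean(bt$peak_force_un), mean(bt$amplitude_um), mean(bt$fwhm_s)))
  if (is.finite(x$tissue_width_um))
    cat(sprintf("  tissue width: %.1f um\n", x$tissue_width_um))
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

write_trace_txt <- function(df, path, unit) {
  con <- file(path, "w")
  writeLines(paste0("# units: time s, values ", unit), con)
  write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
}

write_result <- function(result, output_dir) {
  for (d in c("masks", "tracking", "metrics", "plots"))
    dir.create(file.path(output_dir, d), recursive = TRUE,
               showWarnings = FALSE)
  save_mask(result$masks$left, file.path(output_dir, "masks", "mask_left.tif"))
  save_mask(result$masks$right,
            file.path(output_dir, "masks", "mask_right.tif"))
  for (s in c("left", "right")) {
    pos <- result$tracks[[s]]$traj$pos
    write.table(pos[, , 1], file.path(output_dir, "tracking",
                                      paste0("row_positions_", s, ".txt")),
                sep = "\t", row.names = FALSE, col.names = FALSE)
    write.table(pos[, , 2], file.path(output_dir, "tracking",
                                      paste0("col_positions_", s, ".txt")),
                sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  write_trace_txt(result$displacement_um,
                  file.path(output_dir, "metrics", "displacement.txt"), "um")
  write_trace_txt(result$force_un,
                  file.path(output_dir, "metrics", "force.txt"), "uN")
  if (!is.null(result$stress))
    write_trace_txt(result$stress,
                    file.path(output_dir, "metrics", "stress.txt"), "uN/um^2")
  if (!is.null(result$beat_table))
    write.table(result$beat_table,
                file.path(output_dir, "metrics", "beat_metrics.txt"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  plot_trace_png(result$displacement_um, "displacement (um)",
                 file.path(output_dir, "plots", "displacement.png"))
  plot_trace_png(result$force_un, "force (uN)",
                 file.path(output_dir, "plots", "force.png"))
  invisible(output_dir)
}

plot_trace_png <- function(df, ylab, path) {
  grDevices::png(path, width = 900, height = 450)
  on.exit(grDevices::dev.off())
  graphics::plot(df$time, df$mean, type = "l", lwd = 2,
                 xlab = "time (s)", ylab = ylab)
  graphics::lines(df$time, df$left, col = "steelblue")
  graphics::lines(df$time, df$right, col = "firebrick")
  graphics::legend("topright", c("mean", "left", "right"),
                   col = c("black", "steelblue", "firebrick"), lty = 1)
  invisible(path)
}

#' Analyze a batch of movies
#'
#' Every subdirectory of `root` is treated as one movie and analyzed
#' independently with the same configuration; a failure in one movie does
#' not abort the batch. A per-movie summary table (one row per movie:
#' status, beat count and rate, mean peak force, mean FWHM, flags) is
#' returned and optionally written as a tab-delimited file.
#'
#' @param root directory containing one subdirectory per movie.
#' @param config a [run_config()] applied to every movie.
#' @param output_root optional directory receiving per-movie `results/`
#'   folders and the batch `summary.txt`.
#' @return data frame, one row per movie.
#' @export
run_batch <- function(root, config, output_root = NULL) {
  movies <- list.dirs(root, recursive = FALSE)
  if (length(movies) == 0) stop("no movie folders found under ", root)
  movies <- movies[natural_order(basename(movies))]
  rows <- lapply(movies, function(mv) {
    out <- if (is.null(output_root)) NULL
           else file.path(output_root, basename(mv), "results")
    if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)
    res <- tryCatch(run_single(mv, config, output_dir = out),
                    error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(movie = basename(mv), status = "failed",
                 n_beats = NA, beating_rate_hz = NA, mean_peak_force_un = NA,
                 mean_amplitude_um = NA, mean_fwhm_s = NA,
                 drift_detected = NA, irregular_beats = NA,
                 error = conditionMessage(res))
    } else {
      bt <- res$beat_table
      data.frame(movie = basename(mv), status = "ok",
                 n_beats = res$beat_segmentation$n_complete_beats,
                 beating_rate_hz = res$beating_rate_hz,
                 mean_peak_force_un = mean(bt$peak_force_un),
                 mean_amplitude_um = mean(bt$amplitude_um),
                 mean_fwhm_s = mean(bt$fwhm_s),
                 drift_detected = res$beat_segmentation$drift_detected,
                 irregular_beats = sum(res$irregular_flags),
                 error = "")
    }
  })
  summary <- do.call(rbind, rows)
  if (!is.null(output_root)) {
    dir.create(output_root, recursive = TRUE, showWarnings = FALSE)
    write.table(summary, file.path(output_root, "summary.txt"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  summary
}
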