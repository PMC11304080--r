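# Moving average with edge-aware partial windows (centred, width w).
moving_average <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w <= 1L) return(x)
  h <- w %/% 2L
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Dominant period (frames) of a trace from the periodogram peak. The trace
# is first-differenced so a slow baseline drift cannot masquerade as the
# dominant frequency.
dominant_period <- function(x) {
  n <- length(x)
  if (n < 8) return(n)
  s <- diff(x)
  s <- s - mean(s)
  if (sd(s) < 1e-12) return(n)
  m <- length(s)
  p <- Mod(fft(s))^2
  k <- which.max(p[2:(m %/% 2 + 1)])   # harmonic index k -> period m/k
  m / k
}

#' Find valley (fully relaxed) frames in a displacement trace
#'
#' Valleys delimit beats: the tissue is fully relaxed at a valley frame. The
#' trace is smoothed by a moving average of width period/10 (period taken
#' from the dominant periodogram peak); twitch peaks above 30% of the
#' dynamic range are located, and one valley is placed in each inter-peak
#' interval
#' (plus the intervals before the first and after the last peak) at the
#' earliest minimum of the smoothed trace.
#'
#' @param signal per-frame contraction trace (px): any signal that is
#'   minimal when the tissue is fully relaxed, e.g. the mean absolute
#'   displacement or (more robustly under drift or a contracted first
#'   frame) the signed inter-pillar convergence `contraction` from
#'   [pillar_displacement()].
#' @param min_beats minimum number of complete beats required (default 2, so
#'   at least 3 valleys must be found).
#' @return integer vector of 1-based valley frame indices (ascending).
#' @export
find_valleys <- function(signal, min_beats = 2L) {
  n <- length(signal)
  period <- dominant_period(signal)
  sm <- moving_average(signal, round(period / 10))
  base <- min(sm)
  # 30% of the dynamic range: low enough to keep depressed irregular beats
  # (which must still be segmented so they can be flagged), high enough to
  # ignore smoothed noise ripple
  height <- base + 0.3 * (max(sm) - base)
  pk <- pracma::findpeaks(sm, minpeakheight = height)
  if (is.null(pk) || nrow(pk) == 0)
    insufficient_beats("no twitch peaks detectable; fewer than 2 complete beats")
  peaks <- sort(pk[, 2])
  # enforce a minimum separation of half the dominant period
  if (length(peaks) > 1) {
    keep <- peaks[1]
    for (p in peaks[-1]) {
      if (p - tail(keep, 1) >= period / 2) keep <- c(keep, p)
      else if (sm[p] > sm[tail(keep, 1)]) keep[length(keep)] <- p
    }
    peaks <- keep
  }
  bounds <- c(1L, peaks, n)
  valleys <- integer(0)
  for (i in seq_len(length(peaks) + 1L)) {
    seg <- bounds[i]:bounds[i + 1L]
    valleys <- c(valleys, seg[which.min(sm[seg])])   # earliest minimum on ties
  }
  valleys <- sort(unique(valleys))
  # a candidate at the movie edge belonging to a partial beat (trace still
  # far from the relaxed baseline) is not a valley
  valleys <- valleys[sm[valleys] <= base + 0.25 * (max(sm) - base)]
  if (length(valleys) - 1L < min_beats)
    insufficient_beats(sprintf(
      "only %d complete beats detected; at least %d are required",
      length(valleys) - 1L, min_beats))
  valleys
}

#' Beat segmentation of a movie
#'
#' Packages valley frames into half-open beat intervals
#' `[start_valley, end_valley)` with bookkeeping flags.
#'
#' @param valleys ascending 1-based valley frame indices.
#' @param n_frames movie length.
#' @param drift_detected,split_applied flags recorded on the object.
#' @return object of class `beat_segmentation`.
#' @export
beat_segmentation <- function(valleys, n_frames, drift_detected = FALSE,
                              split_applied = FALSE) {
  stopifnot(all(diff(valleys) > 0))
  nb <- length(valleys) - 1L
  beats <- if (nb > 0)
    data.frame(beat = seq_len(nb), start = valleys[-length(valleys)],
               end = valleys[-1])
  else data.frame(beat = integer(0), start = integer(0), end = integer(0))
  structure(list(valleys = as.integer(valleys), beats = beats,
                 n_complete_beats = nb, n_frames = n_frames,
                 drift_detected = drift_detected,
                 split_applied = split_applied),
            class = "beat_segmentation")
}

#' @export
print.beat_segmentation <- function(x, ...) {
  cat(sprintf(
    "<beat_segmentation> %d complete beats | valleys: %s | drift: %s | split: %s\n",
    x$n_complete_beats, paste(x$valleys, collapse = ", "),
    x$drift_detected, x$split_applied))
  invisible(x)
}

#' Re-base a movie to start from its first valley frame
#'
#' If the movie does not open in a fully relaxed state, frames before the
#' first valley are dropped, fiducial markers are re-detected on the new
#' first frame, and the truncated movie is tracked a second time. A movie
#' already starting at a valley passes through untouched.
#'
#' @param stack [frame_stack()].
#' @param tracks result of the initial tracking (internal pillar-track
#'   list as produced by `run_single()`'s pipeline).
#' @param valleys valley frames from [find_valleys()].
#' @param masks list of `left`/`right` [pillar_mask()]s.
#' @param params optional [tracking_params()].
#' @param min_beats minimum complete beats after truncation.
#' @return list with `stack`, `tracks`, `displacement`, `valleys`,
#'   `retracked` (flag).
#' @export
adjust_start <- function(stack, tracks, valleys, masks, params = NULL,
                         min_beats = 2L) {
  if (valleys[1] == 1L) {
    return(list(stack = stack, tracks = tracks,
                displacement = pillar_displacement(tracks),
                valleys = valleys, retracked = FALSE))
  }
  stack2 <- truncate_stack(stack, valleys[1])
  tracks2 <- track_pillars(stack2, masks, params)
  disp2 <- pillar_displacement(tracks2)
  valleys2 <- find_valleys(disp2$contraction, min_beats = min_beats)
  list(stack = stack2, tracks = tracks2, displacement = disp2,
       valleys = valleys2, retracked = TRUE)
}

#' Detect baseline drift at valley frames
#'
#' In a fully relaxed state the displacement should return to 0; residual
#' offsets at valley frames indicate drift (imaging noise accumulation or
#' out-of-plane motion). Drift is flagged when any valley offset strictly
#' exceeds the tolerance.
#'
#' @param signal per-frame mean absolute displacement relative to frame 1.
#' @param valleys valley frame indices.
#' @param tol drift tolerance in px (default 0.5).
#' @return list with `drift_detected` and `valley_offsets`.
#' @export
detect_drift <- function(signal, valleys, tol = 0.5) {
  offsets <- signal[valleys]
  list(drift_detected = any(offsets > tol), valley_offsets = offsets)
}

#' Split trajectories into per-beat traces with per-beat baselines
#'
#' Temporal segmentation for drift correction: each beat's displacements are
#' recomputed relative to the marker positions at that beat's own starting
#' valley frame, so the displacement is exactly 0 at every beat start. The
#' split requires at least 3 complete beats.
#'
#' @param tracks internal pillar-track list (per-pillar trajectories).
#' @param valleys valley frame indices.
#' @return list of per-beat data frames (columns as in
#'   [pillar_displacement()], plus `beat`), with global frame indices.
#' @export
split_beats <- function(tracks, valleys) {
  nb <- length(valleys) - 1L
  if (nb < 3L)
    insufficient_beats(sprintf(
      "drift-correcting split requires at least 3 complete beats; found %d", nb))
  lapply(seq_len(nb), function(b) {
    rng <- valleys[b]:valleys[b + 1L]
    sub <- lapply(tracks, function(tk) {
      tj <- tk$traj
      tj$pos <- tj$pos[, rng, , drop = FALSE]
      tj$n_frames <- length(rng)
      tj
    })
    d <- pillar_displacement(list(left = list(traj = sub$left),
                                  right = list(traj = sub$right)),
                             reference_frame = 1L)
    d$frame <- rng
    d$beat <- b
    d
  })
}

#' Flag irregular beats
#'
#' A beat is irregular when its period or its peak amplitude deviates from
#' the across-beat median by more than a relative tolerance. Irregular beats
#' are only flagged (with a warning); no further action is taken.
#'
#' @param periods per-beat periods (frames or seconds).
#' @param amplitudes per-beat peak amplitudes.
#' @param tol relative tolerance (default 0.25).
#' @param warn emit a warning when any beat is irregular?
#' @return logical vector, one flag per beat.
#' @export
detect_irregular_beats <- function(periods, amplitudes, tol = 0.25,
                                   warn = TRUE) {
  stopifnot(length(periods) == length(amplitudes))
  rel_dev <- function(x) {
    m <- median(x)
    if (m == 0) as.numeric(x != 0) else abs(x - m) / m
  }
  flags <- rel_dev(periods) > tol | rel_dev(amplitudes) > tol
  if (warn && any(flags))
    pt_warn(sprintf("irregular beat(s) detected: %s",
                    paste(which(flags), collapse = ", ")),
            "pt_irregular_beats")
  flags
}
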