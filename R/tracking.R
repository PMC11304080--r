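#' Tracking parameters
#'
#' Parameters for Shi-Tomasi corner detection and pyramidal Lucas-Kanade
#' sparse optical flow. The search window must comfortably exceed the
#' expected inter-frame motion (window 15 px supports motions of a few px
#' per frame at 3 pyramid levels).
#'
#' @param quality corner quality level: keep corners whose minimum
#'   structure-tensor eigenvalue is at least `quality * max(response)`.
#' @param min_distance minimum distance between accepted corners, px.
#' @param block_size side of the square window summing the structure tensor.
#' @param pyramid_levels number of pyramid levels (including the base).
#' @param window side of the square LK integration window, px (odd).
#' @param min_markers target minimum number of corners per pillar; the
#'   quality level is auto-tuned down until this is met.
#' @param max_markers cap on corners kept per pillar.
#' @param max_iter,eps LK iteration limit and convergence threshold (px).
#' @return object of class `tracking_params`.
#' @export
tracking_params <- function(quality = 0.1, min_distance = 5, block_size = 5,
                            pyramid_levels = 3, window = 15,
                            min_markers = 10, max_markers = 200,
                            max_iter = 30, eps = 0.01) {
  stopifnot(window %% 2 == 1, window >= 3, quality > 0, quality <= 1)
  structure(list(quality = quality, min_distance = min_distance,
                 block_size = block_size, pyramid_levels = pyramid_levels,
                 window = window, min_markers = min_markers,
                 max_markers = max_markers, max_iter = max_iter, eps = eps),
            class = "tracking_params")
}

# Shi-Tomasi response: smaller eigenvalue of the block-summed structure
# tensor of the image gradients. Gradients are taken on a lightly smoothed
# copy of the frame so that single-frame sensor noise, which carries no
# trackable structure, does not masquerade as corners.
shi_tomasi_response <- function(frame, block_size = 5) {
  frame <- smooth3(frame)
  nr <- nrow(frame); nc <- ncol(frame)
  gx <- (frame[, c(2:nc, nc)] - frame[, c(1, 1:(nc - 1))]) / 2   # d/dcol
  gy <- (frame[c(2:nr, nr), ] - frame[c(1, 1:(nr - 1)), ]) / 2   # d/drow
  box <- matrix(1, block_size, block_size)
  sxx <- EBImage::filter2(gx * gx, box)
  syy <- EBImage::filter2(gy * gy, box)
  sxy <- EBImage::filter2(gx * gy, box)
  (sxx + syy - sqrt((sxx - syy)^2 + 4 * sxy^2)) / 2
}

# Corner detection without error signalling (used by the auto-tuner).
detect_features_quiet <- function(frame, mask, params) {
  resp <- shi_tomasi_response(frame, params$block_size)
  margin <- max((params$window - 1) / 2, params$block_size) + 1
  nr <- nrow(frame); nc <- ncol(frame)
  ok <- mask > 0
  ok[c(seq_len(min(margin, nr)), seq(max(1, nr - margin + 1), nr)), ] <- FALSE
  ok[, c(seq_len(min(margin, nc)), seq(max(1, nc - margin + 1), nc))] <- FALSE
  if (!any(ok)) return(matrix(numeric(0), 0, 2))
  thr <- params$quality * max(resp[ok])
  cand <- which(ok & resp >= thr & resp > 0, arr.ind = TRUE)
  if (nrow(cand) == 0) return(matrix(numeric(0), 0, 2))
  # deterministic ordering: decreasing response, then row-major position
  o <- order(-resp[cand], cand[, 1], cand[, 2])
  cand <- cand[o, , drop = FALSE]
  sel <- matrix(numeric(0), 0, 2)
  mind2 <- params$min_distance^2
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (nrow(sel) == 0 ||
        min((sel[, 1] - p[1])^2 + (sel[, 2] - p[2])^2) >= mind2) {
      sel <- rbind(sel, p)
      if (nrow(sel) >= params$max_markers) break
    }
  }
  dimnames(sel) <- list(NULL, c("row", "col"))
  sel
}

#' Auto-tune corner detection parameters for a pillar
#'
#' Deterministic fallback rule: start from the default quality level; while
#' fewer than `min_markers` corners are found, halve the quality level down
#' to a floor of `1e-4`. If fewer than 3 corners exist at the floor the
#' pillar cannot be tracked.
#'
#' @param frame grayscale matrix (the reference frame).
#' @param mask [pillar_mask()] restricting the corner search.
#' @param params starting [tracking_params()].
#' @return [tracking_params()] with the tuned quality level.
#' @export
auto_tune_params <- function(frame, mask, params = tracking_params()) {
  q <- params$quality
  repeat {
    tuned <- params
    tuned$quality <- q
    n <- nrow(detect_features_quiet(frame, mask, tuned))
    if (n >= params$min_markers) return(tuned)
    if (q <= 1e-4) {
      if (n < 3)
        tracking_failure(sprintf(
          "only %d trackable corners found in the %s pillar mask at the quality floor",
          n, attr(mask, "side") %||% "given"))
      return(tuned)
    }
    q <- max(q * 0.5, 1e-4)
  }
}

#' Detect Shi-Tomasi fiducial markers inside a pillar mask
#'
#' Corners of the minimum-eigenvalue ("good features to track") criterion,
#' restricted to the pillar mask, thresholded at `quality * max(response)`
#' and non-maximum-suppressed by `min_distance`. Ordering is deterministic,
#' so repeated calls return identical marker sets.
#'
#' @param frame grayscale matrix.
#' @param mask [pillar_mask()].
#' @param params [tracking_params()], typically from [auto_tune_params()].
#' @return numeric matrix of marker positions, columns `row`, `col`.
#' @export
detect_features <- function(frame, mask, params = tracking_params()) {
  sel <- detect_features_quiet(frame, mask, params)
  if (nrow(sel) == 0)
    tracking_failure("no trackable corners found inside the pillar mask")
  sel
}

#' Track fiducial markers across a movie with pyramidal Lucas-Kanade flow
#'
#' Sub-pixel sparse optical flow by iterative pyramidal Lucas-Kanade with
#' symmetric (averaged reference/target) window gradients. Tracking is
#' reference-anchored: every frame is matched against the first-frame
#' template, warm-started from the previous frame's displacement, so
#' per-step increments stay small while frame-to-frame error accumulation
#' is structurally impossible. A marker whose integration window leaves the
#' image or whose normal equations degenerate is flagged invalid and
#' excluded from all aggregated outputs (never interpolated).
#'
#' @param stack a [frame_stack()] (or `rows x cols x n` array).
#' @param markers marker matrix from [detect_features()] (columns row, col),
#'   positions in the first frame of `stack`.
#' @param params [tracking_params()].
#' @return object of class `trajectory`: list with `pos` (array
#'   `markers x frames x 2`, sub-pixel `(row, col)` positions), `valid`
#'   (logical per marker), `n_frames`.
#' @export
track_markers <- function(stack, markers, params = tracking_params()) {
  frames <- if (inherits(stack, "frame_stack")) stack$frames else stack
  stopifnot(length(dim(frames)) == 3)
  if (dim(frames)[3] < 2) stop("need at least 2 frames to track")
  if (!is.matrix(markers) || nrow(markers) == 0)
    tracking_failure("no markers to track")
  res <- .lk_track_stack(frames, cbind(markers[, 1], markers[, 2]) - 1,
                         as.integer(params$pyramid_levels),
                         as.integer((params$window - 1) / 2),
                         as.integer(params$max_iter), params$eps)
  pos <- array(res$pos, dim = c(nrow(markers), dim(frames)[3], 2)) + 1
  valid <- as.logical(res$valid)
  if (mean(valid) < 0.5)
    tracking_failure(sprintf("%d of %d markers lost during tracking",
                             sum(!valid), length(valid)))
  structure(list(pos = pos, valid = valid, n_frames = dim(frames)[3]),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d markers (%d valid) x %d frames\n",
              dim(x$pos)[1], sum(x$valid), x$n_frames))
  invisible(x)
}

#' Mean pillar displacement per frame
#'
#' Mean over valid markers of the signed row and column displacements
#' relative to a reference frame, and the mean Euclidean displacement
#' magnitude, in pixels.
#'
#' @param traj a `trajectory` from [track_markers()].
#' @param reference_frame frame index the displacements are measured from.
#' @return data frame with columns `frame`, `mean_drow`, `mean_dcol`,
#'   `mean_abs`.
#' @export
mean_displacement <- function(traj, reference_frame = 1L) {
  stopifnot(inherits(traj, "trajectory"))
  v <- traj$valid
  if (!any(v)) stop("no valid markers to aggregate")
  p <- traj$pos[v, , , drop = FALSE]
  m <- sum(v)
  rows <- matrix(p[, , 1], nrow = m)
  cols <- matrix(p[, , 2], nrow = m)
  dr <- sweep(rows, 1, rows[, reference_frame])
  dc <- sweep(cols, 1, cols[, reference_frame])
  data.frame(frame = seq_len(traj$n_frames),
             mean_drow = colMeans(dr),
             mean_dcol = colMeans(dc),
             mean_abs = colMeans(sqrt(dr^2 + dc^2)))
}

# Detect + track both pillars; returns per-pillar params and trajectories.
track_pillars <- function(stack, masks, params = NULL) {
  frame1 <- get_frame(stack, 1)
  out <- lapply(c("left", "right"), function(s) {
    p <- if (is.null(params)) auto_tune_params(frame1, masks[[s]])
         else auto_tune_params(frame1, masks[[s]], params)
    mk <- detect_features(frame1, masks[[s]], p)
    list(params = p, markers = mk, traj = track_markers(stack, mk, p))
  })
  names(out) <- c("left", "right")
  out
}

# Combined per-frame displacement table for the two pillars (px), relative
# to `reference_frame`; `mean_abs` averages the two pillars' mean absolute
# displacements. `contraction` is the signed inter-pillar convergence
# (dcol_left - dcol_right): it grows as the pillars move toward each other,
# is invariant to common-mode drift, and is negative when the reference
# frame itself is contracted -- which makes it the robust timing signal for
# valley detection (it is never used for force, which follows the
# per-pillar deflection convention).
pillar_displacement <- function(tracks, reference_frame = 1L) {
  dl <- mean_displacement(tracks$left$traj, reference_frame)
  dr <- mean_displacement(tracks$right$traj, reference_frame)
  data.frame(frame = dl$frame,
             drow_left = dl$mean_drow, dcol_left = dl$mean_dcol,
             abs_left = dl$mean_abs,
             drow_right = dr$mean_drow, dcol_right = dr$mean_dcol,
             abs_right = dr$mean_abs,
             mean_abs = (dl$mean_abs + dr$mean_abs) / 2,
             contraction = dl$mean_dcol - dr$mean_dcol)
}
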