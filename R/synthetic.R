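#' Twitch waveform: per-frame pillar deflection with exact zeros at valleys
#'
#' Builds a pulse train of raised-cosine twitches. Each beat rises over
#' `contraction_frac` of its period and relaxes over `relaxation_frac`; the
#' remainder of the period (if any) is an exact-zero diastolic interval. The
#' sampled peak of every beat is rescaled to exactly `peak_amplitude_px`.
#' The full width at half maximum of a raised-cosine pulse is half its base
#' width.
#'
#' @param n_frames number of frames to generate.
#' @param period_frames beat period in frames (>= 4).
#' @param peak_amplitude_px peak deflection in pixels (>= 0).
#' @param contraction_frac,relaxation_frac fractions of the period spent
#'   contracting / relaxing; their sum must lie in (0, 1].
#' @param start_phase fraction of a period in `[0, 1)` by which the movie
#'   starts after a valley; 0 means the movie opens fully relaxed.
#' @param amp_mult,period_mult optional per-beat multipliers (recycled) used
#'   to create irregular beats.
#' @return numeric vector of length `n_frames` with attributes:
#'   `valleys` (1-based beat-start frame indices falling inside the movie),
#'   `beat_periods` and `beat_amplitudes` (per generated beat).
#' @export
make_waveform <- function(n_frames, period_frames, peak_amplitude_px,
                          contraction_frac = 0.5, relaxation_frac = 0.5,
                          start_phase = 0, amp_mult = NULL,
                          period_mult = NULL) {
  if (period_frames < 4) stop("period_frames must be >= 4 (waveform unresolvable)")
  stopifnot(n_frames >= 1, peak_amplitude_px >= 0,
            start_phase >= 0, start_phase < 1)
  base_frac <- contraction_frac + relaxation_frac
  if (base_frac <= 0 || base_frac > 1)
    stop("contraction_frac + relaxation_frac must lie in (0, 1]")

  offset <- round(start_phase * period_frames)
  total <- offset + n_frames
  # generate whole beats until the movie is covered
  w <- numeric(0)
  starts <- integer(0)          # 0-based global beat-start frames
  periods <- integer(0)
  amps <- numeric(0)
  j <- 0L
  while (length(w) < total + 1L) {
    j <- j + 1L
    pm <- if (is.null(period_mult)) 1 else period_mult[(j - 1L) %% length(period_mult) + 1L]
    am <- if (is.null(amp_mult)) 1 else amp_mult[(j - 1L) %% length(amp_mult) + 1L]
    P <- max(4L, as.integer(round(period_frames * pm)))
    A <- peak_amplitude_px * am
    tt <- seq_len(P) - 1
    cp <- contraction_frac * P
    rp <- relaxation_frac * P
    pulse <- ifelse(tt <= cp, A / 2 * (1 - cos(pi * tt / cp)),
             ifelse(tt <= cp + rp, A / 2 * (1 + cos(pi * (tt - cp) / rp)), 0))
    if (A > 0 && max(pulse) > 0) pulse <- pulse * (A / max(pulse))
    starts <- c(starts, length(w))
    periods <- c(periods, P)
    amps <- c(amps, A)
    w <- c(w, pulse)
  }
  out <- w[offset + seq_len(n_frames)]
  v <- starts - offset                       # 0-based local valley frames
  v <- v[v >= 0 & v <= n_frames - 1L]
  structure(out, valleys = as.integer(v + 1L),
            beat_periods = periods, beat_amplitudes = amps)
}

#' Specification of a synthetic two-pillar microbundle movie
#'
#' Describes a stylized brightfield movie of a cardiac microbundle suspended
#' between two elastomeric pillars: two textured pillar caps (rectangular for
#' "type1" devices, circular for "type2") on a darker background, joined by a
#' low-contrast tissue band, with the caps translating horizontally toward
#' each other during each twitch. The rendered motion is exactly known, so
#' every downstream stage can be validated against ground truth.
#'
#' @param image_shape `(rows, cols)` in pixels.
#' @param data_type `"type1"` (rectangular caps) or `"type2"` (circular caps).
#' @param centers 2 x 2 matrix of pillar-cap centers `(row, col)`, left then
#'   right.
#' @param half_size `(half-height, half-width)` of rectangular caps in px.
#' @param radius radius of circular caps in px (`type2`).
#' @param period_frames,peak_amplitude_px,contraction_frac,relaxation_frac,start_phase,amp_mult,period_mult
#'   passed to [make_waveform()].
#' @param n_frames number of frames.
#' @param noise_sigma standard deviation of additive Gaussian sensor noise,
#'   as a fraction of the full gray-value range.
#' @param drift_per_frame `(row, col)` baseline drift in px/frame applied to
#'   both pillars (emulates stage creep / out-of-plane motion).
#' @param texture_seed integer seed for the speckle texture and noise.
#' @param tissue_band render the tissue band between the pillars?
#' @param band_half_width half the vertical extent of the tissue band, px.
#' @param fps,length_scale acquisition metadata stored in the stack.
#' @return an object of class `synthetic_movie_spec`.
#' @export
synthetic_movie_spec <- function(image_shape = c(160L, 256L),
                                 data_type = c("type1", "type2"),
                                 centers = rbind(c(80, 64), c(80, 192)),
                                 half_size = c(16, 12), radius = 14,
                                 period_frames = 30L, peak_amplitude_px = 4,
                                 contraction_frac = 0.5,
                                 relaxation_frac = 0.5, start_phase = 0,
                                 amp_mult = NULL, period_mult = NULL,
                                 n_frames = 95L, noise_sigma = 0.01,
                                 drift_per_frame = c(0, 0),
                                 texture_seed = 42L, tissue_band = TRUE,
                                 band_half_width = 20,
                                 fps = 30, length_scale = 1) {
  data_type <- match.arg(data_type)
  spec <- list(image_shape = as.integer(image_shape), data_type = data_type,
               centers = centers, half_size = half_size, radius = radius,
               period_frames = period_frames,
               peak_amplitude_px = peak_amplitude_px,
               contraction_frac = contraction_frac,
               relaxation_frac = relaxation_frac, start_phase = start_phase,
               amp_mult = amp_mult, period_mult = period_mult,
               n_frames = as.integer(n_frames), noise_sigma = noise_sigma,
               drift_per_frame = drift_per_frame,
               texture_seed = as.integer(texture_seed),
               tissue_band = tissue_band, band_half_width = band_half_width,
               fps = fps, length_scale = length_scale)
  class(spec) <- "synthetic_movie_spec"
  validate_spec_geometry(spec)
  spec
}

# Pillar footprints must stay inside the image at maximum deflection and the
# two pillars must never overlap.
validate_spec_geometry <- function(spec) {
  max_defl <- spec$peak_amplitude_px * max(1, abs(c(spec$amp_mult, 1))) +
    sum(abs(spec$drift_per_frame)) * (spec$n_frames - 1)
  fp <- lapply(1:2, function(i) footprint_bbox(spec, i))
  for (i in 1:2) {
    lo_r <- fp[[i]][1] - abs(spec$drift_per_frame[1]) * (spec$n_frames - 1)
    hi_r <- fp[[i]][2] + abs(spec$drift_per_frame[1]) * (spec$n_frames - 1)
    lo_c <- fp[[i]][3] - max_defl
    hi_c <- fp[[i]][4] + max_defl
    if (lo_r < 2 || lo_c < 2 || hi_r > spec$image_shape[1] - 1 ||
        hi_c > spec$image_shape[2] - 1)
      stop("pillar geometry leaves the image at maximum deflection")
  }
  gap <- (fp[[2]][3] - max_defl) - (fp[[1]][4] + max_defl)
  if (gap <= 0) stop("pillar regions overlap at maximum deflection")
  invisible(spec)
}

footprint_bbox <- function(spec, i) {
  ctr <- spec$centers[i, ]
  if (spec$data_type == "type1") {
    c(ctr[1] - spec$half_size[1], ctr[1] + spec$half_size[1],
      ctr[2] - spec$half_size[2], ctr[2] + spec$half_size[2])
  } else {
    c(ctr[1] - spec$radius, ctr[1] + spec$radius,
      ctr[2] - spec$radius, ctr[2] + spec$radius)
  }
}

footprint_mask <- function(spec, i) {
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  ctr <- spec$centers[i, ]
  if (spec$data_type == "type1") {
    r <- abs(seq_len(nr) - ctr[1]) <= spec$half_size[1]
    c <- abs(seq_len(nc) - ctr[2]) <= spec$half_size[2]
    outer(r, c)
  } else {
    rr <- outer(seq_len(nr) - ctr[1], rep(1, nc))
    cc <- outer(rep(1, nr), seq_len(nc) - ctr[2])
    rr^2 + cc^2 <= spec$radius^2
  }
}

# Backward bilinear sampling of `m` rigidly translated by (dr, dc); pixels
# sampled from outside the matrix are 0. Integer shifts are exact, so a
# shifted frame equals a rolled copy of the template.
bilinear_shift <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  sr <- seq_len(nr) - dr; sc <- seq_len(nc) - dc
  r0 <- floor(sr); fr <- sr - r0
  c0 <- floor(sc); fc <- sc - c0
  grab <- function(ri, ci) {
    ok_r <- ri >= 1 & ri <= nr
    ok_c <- ci >= 1 & ci <= nc
    mm <- m[pmin(pmax(ri, 1L), nr), pmin(pmax(ci, 1L), nc), drop = FALSE]
    if (any(!ok_r)) mm[!ok_r, ] <- 0
    if (any(!ok_c)) mm[, !ok_c] <- 0
    mm
  }
  (1 - fr) * (t(t(grab(r0, c0)) * (1 - fc)) + t(t(grab(r0, c0 + 1)) * fc)) +
    fr * (t(t(grab(r0 + 1, c0)) * (1 - fc)) + t(t(grab(r0 + 1, c0 + 1)) * fc))
}

# Per-column horizontal backward shift (used for the stretching tissue band),
# followed by a global vertical shift.
warp_band <- function(m, u_per_col, vr) {
  nr <- nrow(m); nc <- ncol(m)
  src <- seq_len(nc) - u_per_col
  c0 <- floor(src); fc <- src - c0
  ok0 <- c0 >= 1 & c0 <= nc
  ok1 <- (c0 + 1) >= 1 & (c0 + 1) <= nc
  m0 <- m[, pmin(pmax(c0, 1L), nc), drop = FALSE]
  m1 <- m[, pmin(pmax(c0 + 1L, 1L), nc), drop = FALSE]
  if (any(!ok0)) m0[, !ok0] <- 0
  if (any(!ok1)) m1[, !ok1] <- 0
  out <- t(t(m0) * (1 - fc)) + t(t(m1) * fc)
  if (vr != 0) out <- bilinear_shift(out, vr, 0) else out
}

smooth3 <- function(m) {
  k <- matrix(1 / 9, 3, 3)
  EBImage::filter2(m, k)
}

#' Render a synthetic two-pillar movie with known ground truth
#'
#' Draws a static high-contrast speckle texture for each pillar cap and a
#' low-contrast tissue band, then renders each frame by bilinear resampling
#' of these templates under the ground-truth motion: both caps translate
#' horizontally toward the tissue center following the twitch waveform
#' (mirror-signed), the band stretches linearly between the two cap centers,
#' and an optional common-mode baseline drift plus i.i.d. Gaussian sensor
#' noise are added. Gray values are quantized to the 16-bit grid.
#'
#' @param spec a [synthetic_movie_spec()].
#' @return a list with elements
#'   `stack` ([frame_stack()]),
#'   `ground_truth` (data frame: `frame`, and per pillar `drow`, `dcol` true
#'   deflection in px relative to the rest position),
#'   `valley_frames` (1-based indices of fully relaxed beat-start frames),
#'   `beat_periods`, `beat_amplitudes`,
#'   `masks` (list of two reference [pillar_mask()]s: the pillar footprints
#'   at frame 1).
#' @export
render_movie <- function(spec) {
  stopifnot(inherits(spec, "synthetic_movie_spec"))
  validate_spec_geometry(spec)
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  nf <- spec$n_frames

  w <- make_waveform(nf, spec$period_frames, spec$peak_amplitude_px,
                     spec$contraction_frac, spec$relaxation_frac,
                     spec$start_phase, spec$amp_mult, spec$period_mult)

  set.seed(spec$texture_seed)
  fp1 <- footprint_mask(spec, 1); fp2 <- footprint_mask(spec, 2)
  tex <- function() {
    t0 <- matrix(runif(nr * nc, 0.50, 0.90), nr, nc)
    pmin(pmax(smooth3(t0), 0), 1)
  }
  t1 <- tex(); t2 <- tex()
  a1 <- fp1 * 1.0; a2 <- fp2 * 1.0

  band <- NULL
  if (isTRUE(spec$tissue_band)) {
    rows <- abs(seq_len(nr) - mean(spec$centers[, 1])) <= spec$band_half_width
    cols <- seq_len(nc) >= spec$centers[1, 2] & seq_len(nc) <= spec$centers[2, 2]
    ab <- outer(rows, cols) * 1.0
    tb <- pmin(pmax(smooth3(matrix(runif(nr * nc, 0.44, 0.52), nr, nc)), 0), 1)
    band <- list(alpha = ab, tex = tb)
  }

  bg <- 0.35
  drift <- spec$drift_per_frame
  wv <- as.numeric(w)
  gt <- data.frame(frame = seq_len(nf),
                   drow1 = drift[1] * (seq_len(nf) - 1),
                   dcol1 = wv + drift[2] * (seq_len(nf) - 1),
                   drow2 = drift[1] * (seq_len(nf) - 1),
                   dcol2 = -wv + drift[2] * (seq_len(nf) - 1))

  # linear interpolation of horizontal motion between the two cap centers
  ramp <- pmin(pmax((seq_len(nc) - spec$centers[1, 2]) /
                      (spec$centers[2, 2] - spec$centers[1, 2]), 0), 1)

  frames <- array(0, c(nr, nc, nf))
  for (f in seq_len(nf)) {
    img <- matrix(bg, nr, nc)
    if (!is.null(band)) {
      u <- gt$dcol1[f] * (1 - ramp) + gt$dcol2[f] * ramp
      aW <- warp_band(band$alpha, u, gt$drow1[f])
      tW <- warp_band(band$tex * band$alpha, u, gt$drow1[f])
      img <- img * (1 - aW) + tW
    }
    for (i in 1:2) {
      dr <- gt[[paste0("drow", i)]][f]; dc <- gt[[paste0("dcol", i)]][f]
      a <- if (i == 1) a1 else a2
      tx <- if (i == 1) t1 else t2
      aW <- bilinear_shift(a, dr, dc)
      tW <- bilinear_shift(tx * a, dr, dc)
      img <- img * (1 - aW) + tW
    }
    if (spec$noise_sigma > 0)
      img <- img + matrix(rnorm(nr * nc, sd = spec$noise_sigma), nr, nc)
    frames[, , f] <- round(pmin(pmax(img, 0), 1) * 65535) / 65535
  }

  m1 <- bilinear_shift(a1, gt$drow1[1], gt$dcol1[1]) > 0.5
  m2 <- bilinear_shift(a2, gt$drow2[1], gt$dcol2[1]) > 0.5
  list(stack = frame_stack(frames, fps = spec$fps,
                           length_scale = spec$length_scale),
       ground_truth = gt,
       valley_frames = attr(w, "valleys"),
       beat_periods = attr(w, "beat_periods"),
       beat_amplitudes = attr(w, "beat_amplitudes"),
       masks = list(left = pillar_mask(m1, side = "left"),
                    right = pillar_mask(m2, side = "right")))
}

#' Write a rendered synthetic movie to disk as a test fixture
#'
#' Writes numbered 16-bit TIFF frames (`frame_0000.tif`, ...) into a
#' `frames/` subdirectory (so the movie folder holds nothing but frames),
#' the two reference masks as 0/1 TIFFs, and a plain-text ground-truth
#' table (one row per frame: frame index and per-pillar true `drow`,
#' `dcol` deflections).
#'
#' @param movie result of [render_movie()].
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_synthetic_movie <- function(movie, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_movie(movie$stack, file.path(dir, "frames"))
  save_mask(movie$masks$left, file.path(dir, "mask_left.tif"))
  save_mask(movie$masks$right, file.path(dir, "mask_right.tif"))
  write.table(movie$ground_truth, file.path(dir, "ground_truth.txt"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(as.character(movie$valley_frames),
             file.path(dir, "valley_frames.txt"))
  invisible(dir)
}
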