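#' Cantilever mechanics parameters
#'
#' Either the pillar spring constant `k` (uN/um) is supplied directly (as
#' measured experimentally), or it is derived from linear beam theory using
#' the elastic modulus `E` and the cantilever geometry; exactly one of the
#' two routes must be given. The derived stiffness for a force applied at
#' height `a` on a cantilever of length `L` is `k = 6 E I / (a^2 (3L - a))`,
#' with second moment of area `I = w t^3 / 12` (rectangular cross-section of
#' width `w` and thickness `t`) or `I = pi D^4 / 64` (circular
#' cross-section of diameter `D`).
#'
#' @param k pillar stiffness, uN/um (optional).
#' @param E elastic modulus, in pressure units consistent with the lengths
#'   (uN/um^2 with lengths in um yields k in uN/um).
#' @param a force application height along the cantilever, `0 < a <= L`.
#' @param L cantilever length.
#' @param w,t width and thickness (rectangular cross-section).
#' @param D diameter (circular cross-section).
#' @param cross_section `"rectangular"` or `"circular"`.
#' @param tissue_depth tissue depth, um.
#' @param length_scale spatial calibration, um/pixel.
#' @param fps frame rate, frames/second.
#' @return object of class `mechanics_params` with `k` resolved.
#' @export
mechanics_params <- function(k = NULL, E = NULL, a = NULL, L = NULL,
                             w = NULL, t = NULL, D = NULL,
                             cross_section = c("rectangular", "circular"),
                             tissue_depth = NA_real_, length_scale = 1,
                             fps = NA_real_) {
  cross_section <- match.arg(cross_section)
  has_k <- !is.null(k)
  has_geom <- !is.null(E)
  if (has_k == has_geom)
    stop("supply exactly one stiffness source: k, or E plus cantilever geometry")
  p <- list(k = k, E = E, a = a, L = L, w = w, t = t, D = D,
            cross_section = cross_section, tissue_depth = tissue_depth,
            length_scale = length_scale, fps = fps)
  class(p) <- "mechanics_params"
  if (has_geom) p$k <- pillar_stiffness(p)
  if (p$k <= 0) stop("pillar stiffness must be positive")
  p
}

#' Second moment of area of the pillar cross-section
#'
#' `I = w t^3 / 12` for a rectangular cross-section, `I = pi D^4 / 64` for a
#' circular one.
#'
#' @param params [mechanics_params()], or a list with the geometry fields.
#' @return second moment of area in the fourth power of the length unit.
#' @export
moment_of_inertia <- function(params) {
  if (params$cross_section == "rectangular") {
    if (is.null(params$w) || is.null(params$t))
      stop("rectangular cross-section requires w and t")
    params$w * params$t^3 / 12
  } else {
    if (is.null(params$D))
      stop("circular cross-section requires D")
    pi * params$D^4 / 64
  }
}

#' Pillar bending stiffness from cantilever beam theory
#'
#' `k = 6 E I / (a^2 (3 L - a))` for a force applied at height `a` of a
#' cantilever of length `L`; at `a = L` this reduces to the textbook
#' end-loaded cantilever stiffness `3 E I / L^3`.
#'
#' @param params [mechanics_params()] carrying `E`, `a`, `L` and geometry.
#' @return stiffness `k` in force/length units consistent with `E`.
#' @export
pillar_stiffness <- function(params) {
  E <- params$E; a <- params$a; L <- params$L
  if (is.null(E) || is.null(a) || is.null(L))
    stop("stiffness derivation requires E, a and L")
  if (a <= 0 || L <= 0) stop("a and L must be positive")
  if (a > L) stop("force application height a cannot exceed cantilever length L")
  I <- moment_of_inertia(params)
  6 * E * I / (a^2 * (3 * L - a))
}

#' Twitch force from pillar deflection (Hooke's law)
#'
#' `F = k * delta`, where `delta` is the mean tracked deflection of one
#' pillar from its rest position, in um. Note the convention: force is
#' computed per pillar from each pillar's own deflection and reported per
#' pillar and as the mean of the two -- never from the inter-pillar distance
#' change, which would report forces and stresses twice as high.
#'
#' @param displacement_um deflection trace in um.
#' @param k pillar stiffness in uN/um.
#' @return force trace in uN.
#' @export
force_trace <- function(displacement_um, k) {
  if (k <= 0) stop("stiffness k must be positive")
  k * displacement_um
}

#' Measure the tissue width on a valley frame
#'
#' The tissue band spans the gap between the two pillars; its width (extent
#' perpendicular to the inter-pillar axis) is measured on the fully relaxed
#' (valley) frame by Otsu-thresholding the inter-pillar region and taking
#' the median per-column count of foreground pixels over the central half of
#' the gap.
#'
#' @param frame grayscale matrix at the first valley frame.
#' @param masks list of `left`/`right` [pillar_mask()]s.
#' @param length_scale um per pixel.
#' @return tissue width in um.
#' @export
measure_tissue_width <- function(frame, masks, length_scale = 1) {
  lcol <- max(which(colSums(masks$left) > 0))
  rcol <- min(which(colSums(masks$right) > 0))
  if (rcol - lcol < 4) stop("no inter-pillar gap to measure the tissue in")
  span <- rcol - lcol
  cols <- (lcol + round(span * 0.25)):(rcol - round(span * 0.25))
  sub <- frame[, cols, drop = FALSE]
  if (sd(sub) < 1e-8)
    stop("no tissue region detected between the pillars; supply the width manually")
  thr <- EBImage::otsu(sub, range = c(0, 1))
  counts <- colSums(sub > thr)
  width_px <- median(counts)
  if (width_px < 2)
    stop("no tissue region detected between the pillars; supply the width manually")
  width_px * length_scale
}

#' Tissue stress from pillar force
#'
#' Stress = force / (tissue width x tissue depth), in uN/um^2 (numerically
#' equal to MPa).
#'
#' @param force_un force trace in uN.
#' @param width_um,depth_um tissue cross-section dimensions in um.
#' @return stress trace in uN/um^2.
#' @export
stress_trace <- function(force_un, width_um, depth_um) {
  if (!is.finite(width_um) || !is.finite(depth_um) ||
      width_um <= 0 || depth_um <= 0)
    stop("tissue cross-sectional area must be positive")
  force_un / (width_um * depth_um)
}

#' Temporal contractility metrics of a single beat
#'
#' Computes, for one beat trace (displacement in um or force in uN, sampled
#' at `fps`): the peak amplitude above the beat-start baseline; contraction
#' velocity (maximum positive central-difference derivative on the rising
#' phase) and relaxation velocity (maximum magnitude of the negative
#' derivative on the falling phase), per second; and the full widths at 50%
#' (FWHM) and 80% (FW80M) of the peak, in seconds, from linearly
#' interpolated threshold crossings. `FW80M <= FWHM` for any unimodal beat.
#'
#' @param trace beat trace; the first sample is the beat-start valley.
#' @param fps sampling rate, frames/second.
#' @return list with `amplitude`, `peak_index`, `contraction_velocity`,
#'   `relaxation_velocity`, `fwhm`, `fw80m`, or `NULL` (with a warning) for
#'   a flat beat.
#' @export
temporal_metrics <- function(trace, fps) {
  stopifnot(fps > 0, length(trace) >= 3)
  rel <- trace - trace[1]
  pk <- which.max(rel)
  amp <- rel[pk]
  if (amp <= 0 || pk == 1L || pk == length(rel)) {
    pt_warn("flat or clipped beat: temporal metrics undefined, beat skipped",
            "pt_flat_beat")
    return(NULL)
  }
  n <- length(rel)
  d <- c(rel[2] - rel[1],
         (rel[3:n] - rel[1:(n - 2)]) / 2,
         rel[n] - rel[n - 1]) * fps
  contraction <- max(d[1:pk])
  relaxation <- max(-d[pk:n])

  cross <- function(frac) {
    y <- frac * amp
    up <- which(rel[1:(pk - 1)] <= y & rel[2:pk] > y)
    dn <- which(rel[pk:(n - 1)] >= y & rel[(pk + 1):n] < y)
    if (length(up) == 0 || length(dn) == 0) return(NA_real_)
    i <- max(up)                      # last upward crossing before the peak
    t_up <- i + (y - rel[i]) / (rel[i + 1] - rel[i])
    j <- pk - 1L + min(dn)            # first downward crossing after it
    t_dn <- j + (y - rel[j]) / (rel[j + 1] - rel[j])
    (t_dn - t_up) / fps
  }
  fwhm <- cross(0.5)
  fw80 <- cross(0.8)
  list(amplitude = amp, peak_index = pk,
       contraction_velocity = contraction, relaxation_velocity = relaxation,
       fwhm = fwhm, fw80m = fw80)
}
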