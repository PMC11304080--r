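#' Binary pillar mask
#'
#' A pillar mask is a logical matrix of the same shape as a movie frame in
#' which the pillar domain is `TRUE` (stored as 1 on disk) and the background
#' is `FALSE` (0). A valid mask has exactly one connected component of at
#' least `min_area` pixels.
#'
#' @param bin logical (or 0/1) matrix.
#' @param side `"left"` or `"right"` (by centroid column).
#' @param min_area minimum pixel count.
#' @return object of class `pillar_mask` (a logical matrix with attributes
#'   `side` and `area`).
#' @export
pillar_mask <- function(bin, side = c("left", "right"), min_area = 50L) {
  side <- match.arg(side)
  bin <- bin > 0
  area <- sum(bin)
  if (area == 0) stop("empty pillar mask")
  if (area < min_area)
    stop(sprintf("pillar mask area %d px is below the minimum of %d px",
                 area, min_area))
  structure(bin, side = side, area = area, class = c("pillar_mask", "matrix"))
}

#' @export
print.pillar_mask <- function(x, ...) {
  ctr <- mask_centroid(x)
  cat(sprintf("<pillar_mask> side = %s | %d px | centroid (%.1f, %.1f)\n",
              attr(x, "side"), attr(x, "area"), ctr[1], ctr[2]))
  invisible(x)
}

mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(mean(idx[, 1]), mean(idx[, 2]))
}

# Jaccard overlap of two binary masks.
mask_jaccard <- function(a, b) {
  sum(a & b) / sum(a | b)
}

# --- local Otsu thresholding -------------------------------------------------

# Block-grid local Otsu: thresholds are computed on overlapping windows
# centred on a coarse grid and bilinearly interpolated to the pixel grid.
# Each local threshold is floored at the global Otsu threshold, which keeps
# windows that lie entirely in flat background from splitting sensor noise.
local_otsu_threshold <- function(img, window_radius) {
  nr <- nrow(img); nc <- ncol(img)
  g <- max(4L, as.integer(round(window_radius)))
  t_global <- EBImage::otsu(img, range = c(0, 1))
  rc <- unique(pmin(seq(1L, nr, by = g) + g %/% 2L, nr))
  cc <- unique(pmin(seq(1L, nc, by = g) + g %/% 2L, nc))
  tm <- matrix(t_global, length(rc), length(cc))
  for (i in seq_along(rc)) {
    rs <- max(1L, rc[i] - g):min(nr, rc[i] + g)
    for (j in seq_along(cc)) {
      cs <- max(1L, cc[j] - g):min(nc, cc[j] + g)
      sub <- img[rs, cs]
      if (sd(sub) > 1e-8)
        tm[i, j] <- max(EBImage::otsu(sub, range = c(0, 1)), t_global)
    }
  }
  interp_grid(tm, rc, cc, nr, nc)
}

# Bilinear interpolation of a coarse value grid to full image size.
interp_grid <- function(vals, rc, cc, nr, nc) {
  row_interp <- apply(vals, 2, function(v) {
    if (length(rc) == 1) rep(v, nr)
    else stats::approx(rc, v, xout = seq_len(nr), rule = 2)$y
  })
  row_interp <- matrix(row_interp, nr, ncol(vals))
  out <- t(apply(row_interp, 1, function(v) {
    if (length(cc) == 1) rep(v, nc)
    else stats::approx(cc, v, xout = seq_len(nc), rule = 2)$y
  }))
  matrix(out, nr, nc)
}

# Connected-component candidates after binary cleanup. Returns a list of
# data about each component large enough and clear of the image border.
mask_candidates <- function(bin, min_area, border_tol = 0L) {
  bin <- EBImage::fillHull(bin * 1)
  lab <- EBImage::bwlabel(bin)
  nlab <- max(lab)
  if (nlab == 0) return(list())
  nr <- nrow(bin); nc <- ncol(bin)
  out <- list()
  for (l in seq_len(nlab)) {
    idx <- which(lab == l, arr.ind = TRUE)
    if (nrow(idx) < min_area) next
    touches <- min(idx[, 1]) <= 1 + border_tol ||
      min(idx[, 2]) <= 1 + border_tol ||
      max(idx[, 1]) >= nr - border_tol || max(idx[, 2]) >= nc - border_tol
    if (touches) next
    out[[length(out) + 1L]] <- list(
      mask = lab == l, area = nrow(idx),
      centroid = c(mean(idx[, 1]), mean(idx[, 2]))
    )
  }
  out
}

#' Segment the two pillar regions from the first movie frame
#'
#' Threshold-based segmentation pipeline: local Otsu thresholding, hole
#' filling, small-object removal, and selection of the two candidate
#' components flanking the tissue (leftmost and rightmost valid components).
#' Both contrast polarities (pillars brighter / darker than background) are
#' tried, and if the first threshold merges the pillars with the tissue band
#' a second Otsu threshold computed on the foreground intensities separates
#' the high-contrast pillar caps. Both platform designs ("type1" strain-gauge
#' devices and "type2" fiber-matrix cantilevers) have pillars flanking the
#' tissue laterally, so the same placement rule serves both.
#'
#' @param frame 2-D grayscale matrix, values in `[0, 1]`.
#' @param data_type `"type1"` or `"type2"`.
#' @param window_radius local Otsu window radius in px; default is 1/8 of the
#'   smaller image dimension.
#' @param min_area minimum component area in px.
#' @return list with elements `left` and `right`, each a [pillar_mask()].
#' @export
segment_pillars_threshold <- function(frame,
                                      data_type = c("type1", "type2"),
                                      window_radius = NULL, min_area = 50L) {
  data_type <- match.arg(data_type)
  stopifnot(is.matrix(frame))
  if (sd(frame) < 1e-8)
    segmentation_failure("frame has no intensity variance; nothing to threshold")
  if (is.null(window_radius)) window_radius <- min(dim(frame)) / 8

  try_polarity <- function(img) {
    thr <- local_otsu_threshold(img, window_radius)
    bin <- img > thr
    cand <- mask_candidates(bin, min_area)
    if (length(cand) == 1 && sd(img[bin]) > 1e-8) {
      # pillars merged with the tissue band into one blob: re-threshold the
      # foreground intensities to isolate the high-contrast caps
      t2 <- EBImage::otsu(matrix(img[bin]), range = c(0, 1))
      cand <- mask_candidates(bin & img > t2, min_area)
    }
    cand
  }

  for (img in list(frame, max(frame) - frame)) {
    cand <- try_polarity(img)
    if (length(cand) >= 2) {
      cols <- vapply(cand, function(x) x$centroid[2], numeric(1))
      li <- which.min(cols); ri <- which.max(cols)
      if (li != ri)
        return(list(left = pillar_mask(cand[[li]]$mask, "left", min_area),
                    right = pillar_mask(cand[[ri]]$mask, "right", min_area)))
    }
  }
  segmentation_failure(paste(
    "automatic segmentation could not find two valid pillar regions;",
    "please supply externally generated binary masks"))
}

#' Load an externally generated binary pillar mask
#'
#' Accepts a single-page TIFF (0/1 or 0/255 values) or a plain-text 0/1
#' matrix. If the mask holds several connected components, only the largest
#' is kept and a warning is issued.
#'
#' @param path mask file.
#' @param side `"left"` or `"right"`.
#' @param frame_shape optional `(rows, cols)`; a mismatch is an error.
#' @return a [pillar_mask()].
#' @export
load_external_mask <- function(path, side = c("left", "right"),
                               frame_shape = NULL) {
  side <- match.arg(side)
  if (!file.exists(path)) stop("no such mask file: ", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    m <- as_gray(tiff::readTIFF(path))
  } else {
    m <- as.matrix(read.table(path))
    dimnames(m) <- NULL
  }
  vals <- unique(round(as.vector(m), 6))
  if (!all(vals %in% c(0, 1) | abs(vals - 1) < 1e-3))
    stop("mask is not binary: values other than 0/1 found in ", path)
  bin <- m > 0.5
  if (!is.null(frame_shape) && !all(dim(bin) == frame_shape))
    stop(sprintf("mask shape (%d x %d) does not match frame shape (%d x %d)",
                 nrow(bin), ncol(bin), frame_shape[1], frame_shape[2]))
  if (sum(bin) == 0) stop("mask is empty (no pillar region): ", path)
  lab <- EBImage::bwlabel(bin * 1)
  if (max(lab) > 1) {
    sizes <- tabulate(lab[lab > 0])
    keep <- which.max(sizes)
    pt_warn(sprintf(
      "mask %s has %d connected components; keeping the largest (%d px)",
      basename(path), max(lab), sizes[keep]), "pt_mask_warning")
    bin <- lab == keep
  }
  pillar_mask(bin, side)
}

#' Save a pillar mask as a 0/1 single-page TIFF
#'
#' @param mask a [pillar_mask()] (or logical matrix).
#' @param path output file.
#' @export
save_mask <- function(mask, path) {
  tiff::writeTIFF((mask > 0) * 1, path, bits.per.sample = 8L)
  invisible(path)
}

#' Morphologically perturb a pillar mask (sensitivity analysis)
#'
#' Erodes or dilates a mask with a 5x5 square structuring element applied
#' `iterations` times, the perturbation used to probe how sensitive tracked
#' displacements are to the exact mask outline.
#'
#' @param mask a [pillar_mask()].
#' @param mode `"erode"` or `"dilate"`.
#' @param iterations number of times the kernel is applied (1 or 4 in the
#'   standard protocol).
#' @param kernel_size side of the square structuring element (default 5).
#' @param min_area erosion below this area is an error.
#' @return the perturbed [pillar_mask()].
#' @export
perturb_mask <- function(mask, mode = c("erode", "dilate"), iterations = 1L,
                         kernel_size = 5L, min_area = 50L) {
  mode <- match.arg(mode)
  kern <- EBImage::makeBrush(kernel_size, shape = "box")
  bin <- (mask > 0) * 1
  f <- if (mode == "erode") EBImage::erode else EBImage::dilate
  for (i in seq_len(iterations)) bin <- f(bin, kern)
  if (mode == "erode" && sum(bin) < min_area)
    stop(sprintf("erosion reduced the mask below %d px; cannot perturb further",
                 min_area))
  pillar_mask(bin > 0, side = attr(mask, "side") %||% "left",
              min_area = if (mode == "erode") min_area else 50L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
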