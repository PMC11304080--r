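#' Frame stack: an ordered grayscale image sequence
#'
#' The raw input container of the package: a `rows x cols x n_frames` numeric
#' array of gray values in `[0, 1]` plus acquisition metadata (frame rate and
#' length scale). All pixel coordinates in the package are 1-based
#' `(row, col)` with the origin at the top-left corner.
#'
#' @param frames numeric array `rows x cols x n_frames`, values in `[0, 1]`.
#' @param fps frame rate in frames per second.
#' @param length_scale spatial calibration in micrometres per pixel.
#' @return an object of class `frame_stack`.
#' @export
frame_stack <- function(frames, fps = NA_real_, length_scale = NA_real_) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  if (anyNA(frames)) stop("frames contain NA values")
  structure(
    list(frames = frames, fps = fps, length_scale = length_scale),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<frame_stack> %d frames of %d x %d px | fps = %s | length scale = %s um/px\n",
    d[3], d[1], d[2], format(x$fps), format(x$length_scale)
  ))
  invisible(x)
}

#' @export
length.frame_stack <- function(x) dim(x$frames)[3]

n_frames <- function(stack) dim(stack$frames)[3]
frame_dim <- function(stack) dim(stack$frames)[1:2]
get_frame <- function(stack, i) stack$frames[, , i]

# Keep frames from `from` (inclusive) onward.
truncate_stack <- function(stack, from) {
  stopifnot(from >= 1, from <= n_frames(stack))
  frame_stack(stack$frames[, , from:n_frames(stack), drop = FALSE],
              fps = stack$fps, length_scale = stack$length_scale)
}

# Natural (numeric-aware) filename ordering: "f2.tif" sorts before "f10.tif".
natural_order <- function(x) {
  toks <- regmatches(x, gregexpr("[0-9]+|[^0-9]+", x))
  keys <- vapply(toks, function(tt) {
    tt <- vapply(tt, function(s) {
      if (grepl("^[0-9]+$", s)) sprintf("%020.0f", as.numeric(s)) else s
    }, character(1))
    paste(tt, collapse = "")
  }, character(1))
  order(keys)
}

as_gray <- function(img) {
  if (length(dim(img)) == 3L) {
    img <- apply(img[, , seq_len(min(3L, dim(img)[3])), drop = FALSE],
                 c(1, 2), mean)
    message("pillartrack: RGB frame converted to grayscale (channel mean)")
  }
  img
}

#' Read a movie as a frame stack
#'
#' Reads either a folder of single-frame TIFF files (ordered by natural sort
#' of filenames, so `frame_2.tif` precedes `frame_10.tif`) or one multi-page
#' TIFF file. RGB frames are converted to grayscale by channel averaging.
#'
#' @param path folder of `.tif`/`.tiff` files, or one multi-page TIFF file.
#' @param fps,length_scale acquisition metadata attached to the stack.
#' @return a [frame_stack()].
#' @export
read_movie <- function(path, fps = NA_real_, length_scale = NA_real_) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                        full.names = TRUE)
    if (length(files) < 2L)
      stop("movie folder must contain at least 2 TIFF frames: ", path)
    files <- files[natural_order(basename(files))]
    imgs <- lapply(files, function(f) as_gray(tiff::readTIFF(f)))
  } else if (file.exists(path)) {
    imgs <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(imgs)) imgs <- list(imgs)
    if (length(imgs) < 2L) stop("movie must contain at least 2 frames: ", path)
    imgs <- lapply(imgs, as_gray)
  } else {
    stop("no such file or directory: ", path)
  }
  dims <- vapply(imgs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent frame shapes in ", path)
  frames <- array(unlist(imgs, use.names = FALSE),
                  c(dims[1, 1], dims[2, 1], length(imgs)))
  frame_stack(frames, fps = fps, length_scale = length_scale)
}

#' Write a frame stack as numbered 16-bit TIFF files
#'
#' @param stack a [frame_stack()].
#' @param dir output directory (created if missing).
#' @param prefix filename prefix; frames are written as `prefix_0000.tif`, ...
#' @return invisibly, the written file paths.
#' @export
write_movie <- function(stack, dir, prefix = "frame") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(n_frames(stack))
  for (i in seq_len(n_frames(stack))) {
    paths[i] <- file.path(dir, sprintf("%s_%04d.tif", prefix, i - 1L))
    tiff::writeTIFF(get_frame(stack, i), paths[i], bits.per.sample = 16L)
  }
  invisible(paths)
}
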