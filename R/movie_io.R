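#' Movie stack container
#'
#' Bundles an ordered list of grayscale frames with acquisition metadata.
#' Frames are numeric matrices (row, col) with identical dimensions and
#' finite, non-negative intensities (TIFF input is scaled to `[0, 1]`).
#'
#' @param frames list of numeric matrices, all the same dimension.
#' @param fps acquisition rate in frames per second, or `NULL`.
#' @param scale physical length per pixel in micrometers, or `NULL`.
#' @return An object of class `movie_stack`.
#' @export
movie_stack <- function(frames, fps = NULL, scale = NULL) {
  if (length(frames) < 1) bt_error("a movie needs at least one frame", "bt_format")
  dims <- dim(frames[[1]])
  for (f in frames) {
    if (!is.matrix(f) || !identical(dim(f), dims))
      bt_error("all frames must be matrices of identical shape", "bt_shape")
    if (!all(is.finite(f)) || any(f < 0))
      bt_error("frame intensities must be finite and non-negative", "bt_format")
  }
  structure(list(frames = frames, fps = fps, scale = scale),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("movie_stack: %d frames of %d x %d px", length(x$frames), d[1], d[2]))
  if (!is.null(x$fps)) cat(sprintf(", %g fps", x$fps))
  if (!is.null(x$scale)) cat(sprintf(", %g um/px", x$scale))
  cat("\n")
  invisible(x)
}

#' @export
length.movie_stack <- function(x) length(x$frames)

# ITU-R 601 luminance for RGB(A) planes stored as row x col x channel arrays.
to_grayscale <- function(a) {
  if (is.matrix(a)) return(a)
  if (length(dim(a)) == 3) {
    if (dim(a)[3] >= 3)
      return(0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3])
    return(a[, , 1])
  }
  bt_error("unsupported frame layout", "bt_format")
}

#' Load a movie from TIFF input
#'
#' Reads either a single multi-page TIFF or a directory of single-frame TIFF
#' files ordered lexicographically by file name. RGB input is converted to
#' ITU-R 601 luminance. Intensities are returned on the `[0, 1]` scale used
#' by [tiff::readTIFF()].
#'
#' @param path a multi-page TIFF file or a directory of per-frame TIFFs.
#' @inheritParams movie_stack
#' @return A [movie_stack].
#' @export
load_movie <- function(path, fps = NULL, scale = NULL) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0) bt_error("no TIFF files found in directory", "bt_format")
    frames <- lapply(files, function(f) to_grayscale(read_tiff_checked(f)[[1]]))
  } else {
    if (!file.exists(path)) bt_error("movie file not found", "bt_format")
    frames <- lapply(read_tiff_checked(path, all = TRUE), to_grayscale)
  }
  movie_stack(frames, fps = fps, scale = scale)
}

read_tiff_checked <- function(path, all = FALSE) {
  out <- tryCatch(tiff::readTIFF(path, all = all, info = FALSE),
                  error = function(e) bt_error(
                    sprintf("could not read TIFF '%s': %s", path, conditionMessage(e)),
                    "bt_format"))
  if (!all) out <- list(out)
  out
}

#' Write a movie as a 16-bit multi-page TIFF
#'
#' Intensities are clamped to `[0, 1]` and quantized to 16 bits, so a stack
#' already on the 16-bit grid round-trips exactly through [load_movie()].
#'
#' @param stack a [movie_stack].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(stack, path) {
  frames <- lapply(stack$frames, function(f) pmin(pmax(f, 0), 1))
  tiff::writeTIFF(frames, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' Drop leading frames from a movie
#'
#' Used to correct movies that begin in a contracted state: trimming to the
#' first relaxed frame restores a valley-referenced analysis.
#'
#' @param stack a [movie_stack].
#' @param n number of leading frames to drop (`n = 0` is a no-op).
#' @return A [movie_stack] with `length(stack) - n` frames; metadata kept.
#' @export
trim_leading_frames <- function(stack, n) {
  if (n < 0 || n >= length(stack$frames))
    bt_error("cannot trim that many frames", "bt_range")
  if (n == 0) return(stack)
  movie_stack(stack$frames[-seq_len(n)], fps = stack$fps, scale = stack$scale)
}

#' Per-frame blur screening
#'
#' Flags frames whose sharpness statistic -- the variance of the Laplacian
#' normalized by the squared mean intensity -- falls below `threshold`.
#' Blurred frames defeat corner detection and therefore tracking.
#'
#' @param stack a [movie_stack].
#' @param threshold normalized Laplacian-variance below which a frame is
#'   flagged (default `1e-4`).
#' @return Logical vector of flags (one per frame) with the per-frame
#'   statistic attached as attribute `"sharpness"`. Emits a warning when any
#'   frame is flagged.
#' @export
detect_blur <- function(stack, threshold = 1e-4) {
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3, byrow = TRUE)
  stat <- vapply(stack$frames, function(f) {
    m <- mean(f)
    if (m <= 0) return(0)
    stats::var(as.vector(conv3(f, lap))) / m^2
  }, numeric(1))
  flags <- stat < threshold
  if (any(flags))
    bt_warning(sprintf("%d blurred frame(s) detected (sharpness below %g)",
                       sum(flags), threshold), "bt_blur_warning")
  structure(flags, sharpness = stat)
}
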