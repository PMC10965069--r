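#' Marker trajectory container
#'
#' Per-marker sub-pixel (row, col) positions over frames. Markers whose
#' tracking fails anywhere in the movie (window leaving the image,
#' ill-conditioned integration window, divergence) are flagged invalid for
#' the whole movie and excluded from all derived outputs.
#'
#' @param row,col M x N numeric matrices of positions (markers x frames).
#' @param valid logical vector of length M.
#' @return An object of class `marker_traj`.
#' @export
marker_traj <- function(row, col, valid = rep(TRUE, nrow(row))) {
  stopifnot(is.matrix(row), is.matrix(col), identical(dim(row), dim(col)),
            length(valid) == nrow(row))
  structure(list(row = row, col = col, valid = valid), class = "marker_traj")
}

#' @export
print.marker_traj <- function(x, ...) {
  cat(sprintf("marker_traj: %d markers (%d valid) x %d frames\n",
              nrow(x$row), sum(x$valid), ncol(x$row)))
  invisible(x)
}

#' @export
dim.marker_traj <- function(x) dim(x$row)

# effective (odd) integration window
odd_win <- function(w) as.integer(w + (w %% 2 == 0))

#' Track markers with pyramidal Lucas-Kanade optical flow
#'
#' For each consecutive frame pair, each marker's displacement solves the
#' local constant-flow least-squares problem over its integration window,
#' refined coarse-to-fine over an image pyramid with iterative updates until
#' the step falls below `eps` pixels (or `max_iter` iterations). Positions
#' accumulate sub-pixel estimates frame to frame.
#'
#' @param stack a [movie_stack].
#' @param markers matrix of starting positions (`row`, `col`) on frame 1.
#' @param params a [tracking_params]; `win_size` is forced odd.
#' @param max_iter,eps inner-iteration cap and convergence tolerance.
#' @param min_eig minimum normalized eigenvalue of the spatial-gradient
#'   matrix (per window pixel, for unit-scale intensities) below which a
#'   window is considered textureless: such windows are skipped at coarse
#'   pyramid levels and invalidate the marker at full resolution.
#' @return A [marker_traj].
#' @export
track_markers <- function(stack, markers, params = tracking_params(),
                          max_iter = 30, eps = 0.01, min_eig = 1e-5) {
  n <- length(stack$frames)
  m <- nrow(markers)
  if (m < 1) bt_error("no markers to track", "bt_no_features")
  win <- odd_win(params$win_size)
  row_pos <- matrix(NA_real_, m, n)
  col_pos <- matrix(NA_real_, m, n)
  row_pos[, 1] <- markers[, "row"]
  col_pos[, 1] <- markers[, "col"]
  valid <- rep(TRUE, m)
  pyr_prev <- .build_pyramid(stack$frames[[1]], params$pyramid_levels)
  pts <- cbind(markers[, "row"] - 1, markers[, "col"] - 1)  # 0-based for C++
  for (t in seq_len(n - 1)) {
    pyr_next <- .build_pyramid(stack$frames[[t + 1]], params$pyramid_levels)
    res <- .lk_step(pyr_prev, pyr_next, pts, win, as.integer(max_iter), eps, min_eig)
    valid <- valid & res$status
    pts <- res$pts
    row_pos[, t + 1] <- pts[, 1] + 1
    col_pos[, t + 1] <- pts[, 2] + 1
    pyr_prev <- pyr_next
  }
  if (!any(valid))
    bt_error("tracking failed for every marker", "bt_tracking_failure")
  marker_traj(row_pos, col_pos, valid)
}

#' Auto-tune the Lucas-Kanade window size
#'
#' The integration window must be larger than the largest per-frame marker
#' motion. Starting at `win_size = 5`, a preliminary full tracking pass is
#' run; if the maximum absolute per-frame displacement (largest axis
#' component between consecutive frames, over valid markers) exceeds the
#' window size, the window grows by 5 and the pass repeats, up to
#' `max_iter` passes.
#'
#' @inheritParams track_markers
#' @param max_iter maximum number of enlargement passes (default 15).
#' @return List with `params` (tuned [tracking_params]), `traj` (the final
#'   preliminary [marker_traj], reusable as the tracking result) and
#'   `max_displacement` (pixels).
#' @export
tune_window_size <- function(stack, markers, params = tracking_params(),
                             max_iter = 15) {
  if (length(stack$frames) < 2) bt_error("need at least 2 frames", "bt_range")
  params$win_size <- 5L
  for (iter in seq_len(max_iter)) {
    traj <- track_markers(stack, markers, params)
    dr <- abs(diff(t(traj$row[traj$valid, , drop = FALSE])))
    dc <- abs(diff(t(traj$col[traj$valid, , drop = FALSE])))
    dmax <- max(dr, dc)
    if (dmax <= params$win_size || iter == max_iter) break
    params$win_size <- params$win_size + 5L
  }
  list(params = params, traj = traj, max_displacement = dmax)
}

#' Mean absolute displacement time series
#'
#' The value at frame t is the mean, over valid markers, of the Euclidean
#' norm of the marker displacement relative to the reference frame.
#'
#' @param traj a [marker_traj].
#' @param reference_frame frame index used as the zero-displacement
#'   reference (default 1).
#' @return Numeric vector, one value per frame (in pixels).
#' @export
mean_absolute_displacement <- function(traj, reference_frame = 1) {
  r <- traj$row[traj$valid, , drop = FALSE]
  c_ <- traj$col[traj$valid, , drop = FALSE]
  if (nrow(r) == 0) bt_error("no valid markers", "bt_tracking_failure")
  dr <- r - r[, reference_frame]
  dc <- c_ - c_[, reference_frame]
  colMeans(sqrt(dr^2 + dc^2))
}
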