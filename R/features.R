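#' Tracking parameter set
#'
#' Parameters governing Shi-Tomasi corner detection and Lucas-Kanade
#' tracking. `quality_level` is the corner-quality fraction in (0, 1]:
#' corners scoring below `quality_level` times the best corner score are
#' rejected. `min_distance` (pixels) is the minimum separation between
#' accepted corners. `win_size` is the integration-window side length in
#' pixels (forced odd when the window is built). `pyramid_levels` is the
#' number of coarse-to-fine image pyramid levels.
#'
#' @param quality_level corner-quality fraction in (0, 1].
#' @param min_distance minimum corner separation in pixels (>= 1).
#' @param win_size integration window side in pixels (>= 5).
#' @param pyramid_levels number of pyramid levels (>= 1).
#' @return An object of class `tracking_params`.
#' @export
tracking_params <- function(quality_level = 0.1, min_distance = 3,
                            win_size = 5, pyramid_levels = 3) {
  if (quality_level <= 0 || quality_level > 1)
    bt_error("quality_level must be in (0, 1]", "bt_value")
  if (min_distance < 1) bt_error("min_distance must be >= 1", "bt_value")
  if (win_size < 5) bt_error("win_size must be >= 5", "bt_value")
  if (pyramid_levels < 1) bt_error("pyramid_levels must be >= 1", "bt_value")
  structure(list(quality_level = quality_level,
                 min_distance = as.integer(min_distance),
                 win_size = as.integer(win_size),
                 pyramid_levels = as.integer(pyramid_levels)),
            class = "tracking_params")
}

#' @export
print.tracking_params <- function(x, ...) {
  cat(sprintf(
    "tracking_params: quality_level = %.4g, min_distance = %d, win_size = %d, pyramid_levels = %d\n",
    x$quality_level, x$min_distance, x$win_size, x$pyramid_levels))
  invisible(x)
}

# Shi-Tomasi corner response: smaller eigenvalue of the 2x2 structure
# tensor, gradients by Sobel, tensor averaged over a block x block window.
shi_tomasi_response <- function(img, block = 3) {
  g <- sobel_gradients(img)
  box <- matrix(1 / (block * block), block, block)
  a <- conv3(g$gr * g$gr, box)
  b <- conv3(g$gr * g$gc, box)
  c_ <- conv3(g$gc * g$gc, box)
  0.5 * ((a + c_) - sqrt((a - c_)^2 + 4 * b^2))
}

#' Detect Shi-Tomasi corner features inside the tissue mask
#'
#' Corners are pixels whose minimum structure-tensor eigenvalue is a local
#' 3x3 maximum and at least `quality_level` times the best masked corner
#' score. Accepted corners are greedily thinned in descending score order
#' so that any two are at least `min_distance` pixels apart.
#'
#' @param frame grayscale matrix.
#' @param mask a [tissue_mask].
#' @param params a [tracking_params].
#' @return Numeric matrix with columns `row`, `col` (marker positions).
#' @export
detect_features <- function(frame, mask, params = tracking_params()) {
  resp <- shi_tomasi_response(frame)
  keep <- mask_logical(mask)
  # exclude a 1-px image border where the gradient stencil is padded
  keep[c(1, nrow(keep)), ] <- FALSE
  keep[, c(1, ncol(keep))] <- FALSE
  resp[!keep] <- -Inf
  best <- max(resp)
  if (!is.finite(best) || best <= 0)
    bt_error("no trackable features found in the mask", "bt_no_features")
  # 3x3 non-maximum suppression
  is_max <- resp >= -Inf
  for (i in -1:1) for (j in -1:1) {
    if (i == 0 && j == 0) next
    is_max <- is_max & (resp >= img_shift(resp, i, j))
  }
  cand <- which(is_max & resp >= params$quality_level * best & is.finite(resp))
  if (length(cand) == 0)
    bt_error("no trackable features found in the mask", "bt_no_features")
  ord <- cand[order(resp[cand], decreasing = TRUE)]
  rows <- (ord - 1L) %% nrow(resp) + 1L
  cols <- (ord - 1L) %/% nrow(resp) + 1L
  n <- length(ord)
  kr <- numeric(n); kc <- numeric(n); nk <- 0L
  md2 <- params$min_distance^2
  for (i in seq_len(n)) {
    if (nk > 0L) {
      dr <- kr[seq_len(nk)] - rows[i]
      dc <- kc[seq_len(nk)] - cols[i]
      if (any(dr * dr + dc * dc < md2)) next
    }
    nk <- nk + 1L
    kr[nk] <- rows[i]; kc[nk] <- cols[i]
  }
  cbind(row = kr[seq_len(nk)], col = kc[seq_len(nk)])
}

#' Marker coverage report
#'
#' Coverage is the mean number of mask pixels per tracked marker (mask area
#' divided by marker count). Local coverage is the same ratio computed on
#' 20x20-pixel tiles anchored at the mask bounding-box origin; tiles with no
#' mask pixels are skipped, and tiles containing mask pixels but no markers
#' report their full mask-pixel count.
#'
#' @param mask a [tissue_mask].
#' @param markers matrix of marker positions (`row`, `col`).
#' @param tile tile side length in pixels (default 20).
#' @return List with elements `coverage` and `local_coverage`.
#' @export
coverage_report <- function(mask, markers, tile = 20) {
  m <- mask_logical(mask)
  area <- sum(m)
  coverage <- area / nrow(markers)
  idx <- which(m, arr.ind = TRUE)
  r0 <- min(idx[, 1]); c0 <- min(idx[, 2])
  tr <- (idx[, 1] - r0) %/% tile
  tc <- (idx[, 2] - c0) %/% tile
  key <- paste(tr, tc)
  mask_px <- table(key)
  mr <- floor((markers[, "row"] - r0) / tile)
  mc <- floor((markers[, "col"] - c0) / tile)
  mkey <- paste(mr, mc)
  cnt <- table(mkey)
  local <- vapply(names(mask_px), function(k) {
    n <- if (k %in% names(cnt)) as.integer(cnt[[k]]) else 0L
    as.numeric(mask_px[[k]]) / max(n, 1L)
  }, numeric(1))
  list(coverage = coverage, local_coverage = unname(local))
}

#' Auto-tune feature-detection parameters by coverage
#'
#' Starting from `quality_level = 0.1` and `min_distance = 3`, iterates up
#' to `max_iter` times: while the coverage (mask pixels per marker) exceeds
#' `coverage_target`, `quality_level` is decreased geometrically (factor
#' `10^(-1/10)` per step, so more markers are admitted); within the first
#' two iterations `min_distance` is additionally incremented by 1 while the
#' three largest local-coverage values are all at most `local_target`. Both
#' parameters are adjusted simultaneously.
#'
#' @param frame grayscale matrix (normally movie frame 1).
#' @param mask a [tissue_mask].
#' @param coverage_target stop once coverage is at or below this (default 40
#'   mask pixels per marker).
#' @param local_target local-coverage ceiling used by the `min_distance`
#'   increment rule (default 50).
#' @param max_iter iteration cap (default 15).
#' @param quality_factor per-iteration multiplier for `quality_level`.
#' @return List with elements `params` (a [tracking_params]) and `report`
#'   (a [coverage_report()] for the final parameter set).
#' @export
tune_feature_params <- function(frame, mask, coverage_target = 40,
                                local_target = 50, max_iter = 15,
                                quality_factor = 10^(-1 / 10)) {
  quality <- 0.1
  min_dist <- 3L
  params <- tracking_params(quality, min_dist)
  markers <- detect_features(frame, mask, params)
  report <- coverage_report(mask, markers)
  for (iter in seq_len(max_iter)) {
    if (report$coverage <= coverage_target) break
    quality <- quality * quality_factor
    if (iter <= 2) {
      top3 <- head(sort(report$local_coverage, decreasing = TRUE), 3)
      if (all(top3 <= local_target)) min_dist <- min_dist + 1L
    }
    params <- tracking_params(quality, min_dist)
    markers <- detect_features(frame, mask, params)
    report <- coverage_report(mask, markers)
  }
  if (nrow(markers) == 0)
    bt_error("no trackable features found after parameter tuning", "bt_no_features")
  list(params = params, report = report)
}
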