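#' Rotation specification
#'
#' A center of rotation and the tissue direction that should map to the
#' image horizontal (column) axis.
#'
#' @param center numeric (row, col) pixel coordinates.
#' @param axis unit 2-vector (row, col) giving the desired horizontal
#'   direction.
#' @return An object of class `rotation_spec`.
#' @export
rotation_spec <- function(center, axis) {
  nrm <- sqrt(sum(axis^2))
  if (abs(nrm - 1) > 1e-8) {
    if (nrm == 0) bt_error("axis must be a non-zero vector", "bt_value")
    axis <- axis / nrm
  }
  structure(list(center = as.numeric(center), axis = as.numeric(axis)),
            class = "rotation_spec")
}

#' @export
print.rotation_spec <- function(x, ...) {
  cat(sprintf("rotation_spec: center (%.2f, %.2f), axis (%.4f, %.4f)\n",
              x$center[1], x$center[2], x$axis[1], x$axis[2]))
  invisible(x)
}

rotation_matrix <- function(spec) {
  a <- spec$axis  # R %*% axis = (0, 1): maps the axis onto the column direction
  matrix(c(a[2], a[1], -a[1], a[2]), 2, 2)
}

#' Rigidly rotate tracked trajectories
#'
#' Marker coordinates are rotated exactly (no resampling) about the
#' specified center so that the specified axis maps onto the column
#' (horizontal) direction. Rotation is applied after tracking so image
#' interpolation never degrades the tracked positions.
#'
#' @param traj a [marker_traj].
#' @param spec a [rotation_spec].
#' @return The rotated [marker_traj].
#' @export
rotate_trajectories <- function(traj, spec) {
  R <- rotation_matrix(spec)
  dr <- traj$row - spec$center[1]
  dc <- traj$col - spec$center[2]
  marker_traj(spec$center[1] + R[1, 1] * dr + R[1, 2] * dc,
              spec$center[2] + R[2, 1] * dr + R[2, 2] * dc,
              traj$valid)
}

#' Rotate a single frame for visualization
#'
#' Inverse-mapped rigid rotation with bilinear resampling. Intended for
#' display only; quantitative results use [rotate_trajectories()], which is
#' exact.
#'
#' @param frame grayscale matrix.
#' @param spec a [rotation_spec].
#' @return The resampled matrix (same shape).
#' @export
rotate_image <- function(frame, spec) {
  R <- rotation_matrix(spec)
  nr <- nrow(frame); nc <- ncol(frame)
  g <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  dr <- g$row - spec$center[1]
  dc <- g$col - spec$center[2]
  # inverse map: transpose of R
  src_r <- spec$center[1] + R[1, 1] * dr + R[2, 1] * dc
  src_c <- spec$center[2] + R[1, 2] * dr + R[2, 2] * dc
  matrix(bilinear_sample(frame, src_r, src_c), nr, nc)
}

#' Interpolate marker displacements to query points
#'
#' Piecewise-linear interpolation on the Delaunay triangulation of the
#' marker positions; affine displacement fields are reproduced exactly
#' inside the convex hull. Queries outside the hull receive the value of
#' the nearest marker and are flagged.
#'
#' @param positions M x 2 matrix (`row`, `col`) of marker positions.
#' @param displacements M x 2 matrix of per-marker displacement vectors.
#' @param query_points Q x 2 matrix of query positions.
#' @return List with `displacements` (Q x 2 matrix) and `extrapolated`
#'   (logical vector flagging outside-hull queries).
#' @export
interpolate_displacements <- function(positions, displacements, query_points) {
  if (nrow(positions) < 3)
    bt_error("need at least 3 markers for interpolation", "bt_geometry")
  interp_one <- function(z) {
    tryCatch(
      interp::interp(x = positions[, 2], y = positions[, 1], z = z,
                     xo = query_points[, 2], yo = query_points[, 1],
                     output = "points", method = "linear")$z,
      error = function(e) bt_error(
        sprintf("interpolation failed (collinear markers?): %s",
                conditionMessage(e)), "bt_geometry"))
  }
  ur <- interp_one(displacements[, 1])
  uc <- interp_one(displacements[, 2])
  outside <- !is.finite(ur) | !is.finite(uc)
  if (any(outside)) {
    for (q in which(outside)) {
      d2 <- (positions[, 1] - query_points[q, 1])^2 +
            (positions[, 2] - query_points[q, 2])^2
      nn <- which.min(d2)
      ur[q] <- displacements[nn, 1]
      uc[q] <- displacements[nn, 2]
    }
  }
  list(displacements = cbind(row = ur, col = uc), extrapolated = outside)
}

#' Define a rectangular subdomain grid
#'
#' Subdomain tiles are laid out row-major inside rectangular extents and
#' labeled letter-row/number-column (A1, A2, ..., B1, ...). Extents are
#' either supplied directly or derived from a tissue mask as the bounding
#' box of rows/columns whose longest foreground run exceeds half the
#' maximum run (this clips the pillar attachment regions at the tissue
#' ends). Tiles are sized either by target counts or by target pixel
#' dimensions; remainder pixels become margins that center the grid. A
#' subdomain side length of 30-40 px is recommended: large enough to hold
#' enough markers for a stable least-squares fit, small enough not to
#' average away heterogeneous deformation.
#'
#' @param extents `c(row_min, row_max, col_min, col_max)` in pixels, or
#'   `NULL` to derive from `mask`.
#' @param mask a [tissue_mask] (used when `extents` is `NULL`).
#' @param n_tiles `c(n_rows, n_cols)` target tile counts, or `NULL`.
#' @param tile_size `c(height, width)` target tile size in pixels, or
#'   `NULL`. Exactly one of `n_tiles`, `tile_size` must be given.
#' @return An object of class `subdomain_grid`: list with `extents` and
#'   `tiles` (data frame with label, bounds, and center coordinates).
#' @export
define_subdomains <- function(extents = NULL, mask = NULL, n_tiles = NULL,
                              tile_size = NULL) {
  if (is.null(extents)) {
    if (is.null(mask)) bt_error("either extents or mask must be given", "bt_value")
    extents <- mask_clip_extents(mask)
  }
  h <- extents[2] - extents[1] + 1
  w <- extents[4] - extents[3] + 1
  if (h <= 0 || w <= 0) bt_error("extents have non-positive area", "bt_value")
  if (is.null(n_tiles) == is.null(tile_size))
    bt_error("give exactly one of n_tiles or tile_size", "bt_value")
  if (!is.null(tile_size)) {
    if (tile_size[1] > h || tile_size[2] > w)
      bt_error("tile larger than extents", "bt_value")
    th <- as.integer(tile_size[1]); tw <- as.integer(tile_size[2])
    nr <- h %/% th; nc <- w %/% tw
  } else {
    nr <- as.integer(n_tiles[1]); nc <- as.integer(n_tiles[2])
    if (nr < 1 || nc < 1 || nr > h || nc > w)
      bt_error("tile larger than extents", "bt_value")
    th <- h %/% nr; tw <- w %/% nc
  }
  top <- extents[1] + (h - nr * th) %/% 2
  left <- extents[3] + (w - nc * tw) %/% 2
  tiles <- do.call(rbind, lapply(seq_len(nr), function(i) {
    do.call(rbind, lapply(seq_len(nc), function(j) {
      r0 <- top + (i - 1) * th; c0 <- left + (j - 1) * tw
      data.frame(label = paste0(LETTERS[i], j),
                 row_min = r0, row_max = r0 + th - 1,
                 col_min = c0, col_max = c0 + tw - 1,
                 center_row = r0 + (th - 1) / 2,
                 center_col = c0 + (tw - 1) / 2,
                 stringsAsFactors = FALSE)
    }))
  }))
  structure(list(extents = extents, tiles = tiles,
                 tile_dim = c(th, tw), n_tiles = c(nr, nc)),
            class = "subdomain_grid")
}

# Extents from a mask: bounding box of rows/cols whose longest foreground
# run exceeds 50% of the maximum run over rows/cols respectively.
mask_clip_extents <- function(mask) {
  m <- mask_logical(mask)
  longest_run <- function(v) {
    r <- rle(v)
    runs <- r$lengths[r$values]
    if (length(runs) == 0) 0L else max(runs)
  }
  row_runs <- apply(m, 1, longest_run)
  col_runs <- apply(m, 2, longest_run)
  rows <- which(row_runs > 0.5 * max(row_runs))
  cols <- which(col_runs > 0.5 * max(col_runs))
  c(min(rows), max(rows), min(cols), max(cols))
}

#' @export
print.subdomain_grid <- function(x, ...) {
  cat(sprintf("subdomain_grid: %d x %d tiles of %d x %d px in extents [%d:%d, %d:%d]\n",
              x$n_tiles[1], x$n_tiles[2], x$tile_dim[1], x$tile_dim[2],
              x$extents[1], x$extents[2], x$extents[3], x$extents[4]))
  invisible(x)
}

#' Average deformation gradient of a marker set by pairwise least squares
#'
#' All unordered marker pairs define reference difference vectors (columns
#' of a 2 x n matrix L0) and current difference vectors (L). The average
#' deformation gradient mapping reference onto current vectors is the
#' normal-equation solution `F = L L0' (L0 L0')^-1` of the over-determined
#' system `F L0 = L`. When the current positions are an affine image of the
#' reference positions the recovery is exact; duplicating pairs (ordered
#' pairs) leaves the solution unchanged.
#'
#' @param ref_positions M x 2 matrix (`row`, `col`) at the reference frame.
#' @param cur_positions M x 2 matrix at the current frame (same markers).
#' @return 2 x 2 deformation gradient in (row, col) axes: `F[1,1]` = F_rr,
#'   `F[2,2]` = F_cc.
#' @export
compute_F_avg <- function(ref_positions, cur_positions) {
  m <- nrow(ref_positions)
  if (m < 3) bt_error("need at least 3 markers in the subdomain", "bt_degenerate_subdomain")
  pr <- combn(m, 2)
  L0 <- rbind(ref_positions[pr[1, ], 1] - ref_positions[pr[2, ], 1],
              ref_positions[pr[1, ], 2] - ref_positions[pr[2, ], 2])
  L <- rbind(cur_positions[pr[1, ], 1] - cur_positions[pr[2, ], 1],
             cur_positions[pr[1, ], 2] - cur_positions[pr[2, ], 2])
  G <- L0 %*% t(L0)
  if (rcond(G) < 1e-12)
    bt_error("collinear markers: subdomain deformation gradient is degenerate",
             "bt_degenerate_subdomain")
  (L %*% t(L0)) %*% solve(G)
}

#' Green-Lagrange strain from a deformation gradient
#'
#' `E = (F'F - I) / 2`. E is symmetric, zero for any rigid motion, and its
#' components follow the image axes: `E_rr` row-row (vertical), `E_cc`
#' col-col (horizontal), `E_cr` shear.
#'
#' @param F_mat 2 x 2 deformation gradient in (row, col) axes.
#' @return 2 x 2 strain tensor with named components in attribute
#'   `"components"` (E_rr, E_cc, E_cr).
#' @export
green_lagrange <- function(F_mat) {
  E <- 0.5 * (t(F_mat) %*% F_mat - diag(2))
  attr(E, "components") <- c(E_rr = E[1, 1], E_cc = E[2, 2], E_cr = E[1, 2])
  E
}

#' Per-subdomain deformation and strain time series for one beat
#'
#' Valid markers are assigned to tiles by their position at the beat's
#' first (reference, most relaxed) frame; membership is fixed within the
#' beat. For every tile and frame the average deformation gradient and the
#' Green-Lagrange strain are computed. Tiles with fewer than 3 markers or
#' a collinear marker arrangement are excluded with a warning.
#'
#' @param beat_traj a per-beat [marker_traj] (from [split_per_beat()]).
#' @param grid a subdomain grid from [define_subdomains()].
#' @return An object of class `strain_series`: list with `tiles` (info for
#'   included tiles), `F` and `E` (lists of 2 x 2 x frames arrays, by tile
#'   label), `E_cc` (frames x tiles matrix), and `excluded` (labels).
#' @export
subdomain_strain_series <- function(beat_traj, grid) {
  nfr <- ncol(beat_traj$row)
  vr <- beat_traj$row[beat_traj$valid, , drop = FALSE]
  vc <- beat_traj$col[beat_traj$valid, , drop = FALSE]
  Fs <- list(); Es <- list(); excluded <- character(0)
  for (k in seq_len(nrow(grid$tiles))) {
    tl <- grid$tiles[k, ]
    inside <- vr[, 1] >= tl$row_min & vr[, 1] <= tl$row_max &
              vc[, 1] >= tl$col_min & vc[, 1] <= tl$col_max
    if (sum(inside) < 3) {
      excluded <- c(excluded, tl$label)
      next
    }
    ref <- cbind(vr[inside, 1], vc[inside, 1])
    Fa <- array(NA_real_, c(2, 2, nfr))
    Ea <- array(NA_real_, c(2, 2, nfr))
    ok <- TRUE
    for (t in seq_len(nfr)) {
      cur <- cbind(vr[inside, t], vc[inside, t])
      Ft <- tryCatch(compute_F_avg(ref, cur), bt_degenerate_subdomain = function(e) NULL)
      if (is.null(Ft)) { ok <- FALSE; break }
      Fa[, , t] <- Ft
      Ea[, , t] <- green_lagrange(Ft)
    }
    if (!ok) {
      excluded <- c(excluded, tl$label)
      next
    }
    Fs[[tl$label]] <- Fa
    Es[[tl$label]] <- Ea
  }
  if (length(excluded) > 0)
    bt_warning(sprintf("subdomain(s) excluded (too few or collinear markers): %s",
                       paste(excluded, collapse = ", ")), "bt_subdomain_warning")
  ecc <- if (length(Es)) sapply(Es, function(a) a[2, 2, ]) else
    matrix(numeric(0), nfr, 0)
  if (is.null(dim(ecc))) ecc <- matrix(ecc, nrow = nfr)
  structure(list(tiles = grid$tiles[grid$tiles$label %in% names(Fs), ],
                 F = Fs, E = Es, E_cc = ecc, excluded = excluded),
            class = "strain_series")
}

#' @export
print.strain_series <- function(x, ...) {
  cat(sprintf("strain_series: %d tiles x %d frames", length(x$F),
              if (length(x$F)) dim(x$F[[1]])[3] else 0))
  if (length(x$excluded)) cat(sprintf(" (%d excluded)", length(x$excluded)))
  cat("\n")
  invisible(x)
}

#' Beat-level summary metrics
#'
#' Beat period (mean peak-to-peak gap over fps), frequency, mean amplitude
#' (mean over beats of peak minus beat-start displacement) and tissue width
#' at the center column of the extents. Values are converted to seconds,
#' Hz, and micrometers when `fps` and `scale` are supplied; otherwise they
#' remain in frames and pixels and a notice is attached.
#'
#' @param series mean absolute displacement series (pixels).
#' @param seg a [segment_beats()] result.
#' @param mask a [tissue_mask].
#' @param fps frames per second, or `NULL`.
#' @param scale micrometers per pixel, or `NULL`.
#' @param extents optional extents used to pick the center column; derived
#'   from the mask when `NULL`.
#' @return List of metrics with a `units` element describing each.
#' @export
beat_metrics <- function(series, seg, mask, fps = NULL, scale = NULL,
                         extents = NULL) {
  gaps <- diff(seg$peaks)
  period_frames <- mean(gaps)
  amps <- vapply(seq_len(nrow(seg$beats)), function(k) {
    idx <- seg$beats[k, "start"]:seg$beats[k, "end"]
    max(series[idx]) - series[seg$beats[k, "start"]]
  }, numeric(1))
  m <- mask_logical(mask)
  if (is.null(extents)) {
    idx <- which(m, arr.ind = TRUE)
    center_col <- round(mean(range(idx[, 2])))
  } else center_col <- round((extents[3] + extents[4]) / 2)
  width_px <- sum(m[, center_col])
  has_fps <- !is.null(fps); has_scale <- !is.null(scale)
  period <- if (has_fps) period_frames / fps else period_frames
  amp <- if (has_scale) mean(amps) * scale else mean(amps)
  width <- if (has_scale) width_px * scale else width_px
  notice <- NULL
  if (!has_fps || !has_scale)
    notice <- "fps and/or scale missing: time in frames, lengths in pixels"
  list(period = period, frequency = 1 / period, mean_amplitude = amp,
       tissue_width_center = width,
       units = list(period = if (has_fps) "s" else "frames",
                    frequency = if (has_fps) "Hz" else "1/frames",
                    mean_amplitude = if (has_scale) "um" else "px",
                    tissue_width_center = if (has_scale) "um" else "px"),
       notice = notice)
}
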