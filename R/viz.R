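# Visualization: per-beat time-series plots and frame-sequence movies.

#' Subdomain strain heat-map matrix
#'
#' Builds a full-frame matrix in which every subdomain tile is filled with
#' its E_cc value at the requested frame of the requested beat (NA
#' elsewhere). This is the raster behind the strain heat-map rendering.
#'
#' @param result an `mb_analysis`.
#' @param beat beat number.
#' @param frame frame index within the beat.
#' @return Numeric matrix of the frame shape.
#' @export
strain_heatmap_matrix <- function(result, beat = 1, frame = NULL) {
  ss <- result$strains[[beat]]
  if (is.null(frame)) { # frame of maximum |E_cc| within the beat
    frame <- if (ncol(ss$E_cc)) which.max(apply(abs(ss$E_cc), 1, max)) else 1L
  }
  out <- matrix(NA_real_, result$frame_shape[1], result$frame_shape[2])
  for (lab in names(ss$E)) {
    tl <- ss$tiles[ss$tiles$label == lab, ]
    out[tl$row_min:tl$row_max, tl$col_min:tl$col_max] <- ss$E_cc[frame, lab]
  }
  out
}

plot_frame_raster <- function(m, zlim = NULL, col = grDevices::hcl.colors(64),
                              main = "") {
  if (is.null(zlim)) zlim <- range(m, na.rm = TRUE)
  if (!all(is.finite(zlim)) || diff(zlim) <= 0)
    zlim <- c(zlim[1], zlim[1] + 1e-9)  # degenerate (e.g. zero-motion) range
  # image() draws x right / y up; flip rows so row 1 is on top
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)),
                  z = t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  zlim = zlim, col = col, useRaster = TRUE, asp = 1,
                  xlab = "col", ylab = "row (flipped)", main = main)
}

#' Render figures and frame-sequence movies for a completed run
#'
#' Writes, under `dir`: one `beat{k}_timeseries.png` per beat (mean
#' absolute displacement and per-tile E_cc), a `displacement_movie/`
#' directory of PNG frames showing markers colored by displacement
#' magnitude, and a `strain_movie/` directory of PNG frames of the
#' subdomain E_cc heat map. Movies are written as ordered PNG frame
#' sequences.
#'
#' @param result an `mb_analysis`.
#' @param dir output directory.
#' @param stack the analyzed [movie_stack] (for image backgrounds);
#'   optional.
#' @param every render every `every`-th frame in the movies (default picks
#'   about 60 frames).
#' @return `dir`, invisibly.
#' @export
render_outputs <- function(result, dir, stack = NULL, every = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(result$beats)) {
    frames <- attr(result$beats[[k]], "frames")
    ss <- result$strains[[k]]
    grDevices::png(file.path(dir, sprintf("beat%d_timeseries.png", k)),
                   width = 900, height = 500)
    tryCatch({
      old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
      graphics::plot(frames, result$series[frames], type = "l",
                     xlab = "frame", ylab = "mean |displacement| (px)",
                     main = sprintf("beat %d displacement", k))
      if (ncol(ss$E_cc) > 0)
        graphics::matplot(frames, ss$E_cc, type = "l", lty = 1,
                          xlab = "frame", ylab = "E_cc",
                          main = sprintf("beat %d subdomain E_cc", k))
      graphics::par(old)
    }, finally = grDevices::dev.off())
  }

  sel <- result$traj$valid
  r <- result$traj$row[sel, , drop = FALSE]
  c_ <- result$traj$col[sel, , drop = FALSE]
  n <- ncol(r)
  if (is.null(every)) every <- max(1L, n %/% 60L)
  shot <- seq(1L, n, by = every)
  mag <- sqrt((r - r[, 1])^2 + (c_ - c_[, 1])^2)
  zmax <- max(mag)
  if (zmax <= 0) zmax <- 1e-9
  pal <- grDevices::hcl.colors(64, "viridis")
  disp_dir <- file.path(dir, "displacement_movie")
  dir.create(disp_dir, showWarnings = FALSE)
  for (j in shot) {
    grDevices::png(file.path(disp_dir, sprintf("frame%04d.png", j)),
                   width = 600, height = 600)
    tryCatch({
      if (!is.null(stack))
        plot_frame_raster(stack$frames[[j]],
                          col = grDevices::gray.colors(64, 0, 1),
                          main = sprintf("frame %d", j))
      else
        graphics::plot(NA, xlim = c(1, result$frame_shape[2]),
                       ylim = c(1, result$frame_shape[1]),
                       xlab = "col", ylab = "row (flipped)",
                       main = sprintf("frame %d", j))
      cidx <- pmax(1L, ceiling(mag[, j] / zmax * 64))
      graphics::points(c_[, j], result$frame_shape[1] + 1 - r[, j],
                       col = pal[cidx], pch = 19, cex = 0.5)
    }, finally = grDevices::dev.off())
  }

  strain_dir <- file.path(dir, "strain_movie")
  dir.create(strain_dir, showWarnings = FALSE)
  all_ecc <- unlist(lapply(result$strains, function(s) s$E_cc))
  zlim <- if (length(all_ecc)) range(all_ecc) else c(0, 1e-9)
  for (k in seq_along(result$beats)) {
    frames <- attr(result$beats[[k]], "frames")
    local_shot <- seq(1L, length(frames), by = every)
    for (f in local_shot) {
      grDevices::png(file.path(strain_dir,
                               sprintf("frame%04d.png", frames[f])),
                     width = 600, height = 600)
      tryCatch({
        hm <- strain_heatmap_matrix(result, beat = k, frame = f)
        plot_frame_raster(hm, zlim = zlim,
                          col = grDevices::hcl.colors(64, "Blue-Red 2"),
                          main = sprintf("E_cc, beat %d frame %d", k, frames[f]))
      }, finally = grDevices::dev.off())
    }
  }
  invisible(dir)
}
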