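#' Run the full microbundle analysis pipeline
#'
#' Orchestrates the standard workflow: mask creation (or loading), feature
#' and window auto-tuning, preliminary tracking, temporal segmentation into
#' beats, quality checks, per-beat splitting with drift correction,
#' optional rotation, subdomain strain analysis, and beat metrics. Every
#' number in the outputs is reproducible by calling the module functions
#' directly; given the same inputs the run is deterministic.
#'
#' @param input a [movie_stack], or a path accepted by [load_movie()].
#' @param output_dir directory for text outputs (see [write_outputs()]);
#'   `NULL` skips writing.
#' @param fps,scale acquisition metadata (override the stack's).
#' @param mask a [tissue_mask], a path to a `tissue_mask.txt`, or `NULL`
#'   for automatic segmentation.
#' @param mask_method,projection passed to [generate_mask()].
#' @param rotate `FALSE`, `TRUE` (auto-rotate so the mask principal axis is
#'   horizontal before strain analysis), or a [rotation_spec].
#' @param extents,n_tiles,tile_size subdomain layout (see
#'   [define_subdomains()]); defaults to 32 x 32 px tiles over the
#'   mask-derived extents.
#' @return An object of class `mb_analysis`.
#' @export
run_pipeline <- function(input, output_dir = NULL, fps = NULL, scale = NULL,
                         mask = NULL, mask_method = "threshold",
                         projection = "min", rotate = FALSE,
                         extents = NULL, n_tiles = NULL, tile_size = NULL) {
  stack <- if (inherits(input, "movie_stack")) input else
    load_movie(input, fps = fps, scale = scale)
  if (is.null(fps)) fps <- stack$fps
  if (is.null(scale)) scale <- stack$scale
  frame_shape <- dim(stack$frames[[1]])
  if (is.character(mask)) mask <- load_external_mask(mask, frame_shape)
  if (is.null(mask)) mask <- generate_mask(stack, method = mask_method,
                                           projection = projection)

  tuned <- tune_feature_params(stack$frames[[1]], mask)
  markers <- detect_features(stack$frames[[1]], mask, tuned$params)
  tw <- tune_window_size(stack, markers, tuned$params)
  traj <- tw$traj
  params <- tw$params
  series <- mean_absolute_displacement(traj)
  seg <- segment_beats(series)
  warn_msgs <- quality_checks(stack, series, seg, traj)

  rot_spec <- NULL
  if (inherits(rotate, "rotation_spec")) rot_spec <- rotate
  else if (isTRUE(rotate)) rot_spec <- suppressWarnings(mask_principal_axis(mask))
  if (!is.null(rot_spec)) {
    traj <- rotate_trajectories(traj, rot_spec)
    rot_mask <- rotate_image(unclass(mask) * 1, rot_spec) > 0.5
    if (any(rot_mask)) mask <- postprocess_mask(rot_mask)
  }

  if (is.null(n_tiles) && is.null(tile_size)) tile_size <- c(32, 32)
  grid <- define_subdomains(extents = extents, mask = mask,
                            n_tiles = n_tiles, tile_size = tile_size)
  beats <- split_per_beat(traj, seg)
  strains <- lapply(beats, subdomain_strain_series, grid = grid)
  metrics <- beat_metrics(series, seg, mask, fps = fps, scale = scale,
                          extents = grid$extents)

  result <- structure(
    list(n_frames = length(stack$frames), frame_shape = frame_shape,
         fps = fps, scale = scale, mask = mask, params = params,
         coverage = tuned$report, traj = traj, series = series, seg = seg,
         beats = beats, grid = grid, strains = strains, metrics = metrics,
         warnings = warn_msgs, rotation = rot_spec),
    class = "mb_analysis")
  if (!is.null(output_dir)) write_outputs(result, output_dir)
  result
}

#' Write pipeline outputs as plain-text files
#'
#' Per beat: `beat{k}_row_pos.txt` and `beat{k}_col_pos.txt`, each an
#' M x N whitespace-delimited array (M valid markers, N frames in the
#' beat), and `beat{k}_subdomain_F.txt` with one row per subdomain per
#' frame: label, center_row, center_col, frame, F_rr, F_rc, F_cr, F_cc.
#' Also writes `tissue_mask.txt`, `warnings.txt` and `metrics.json`.
#'
#' @param result an `mb_analysis`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(result$beats)) {
    bt <- result$beats[[k]]
    v <- bt$valid
    write.table(bt$row[v, , drop = FALSE],
                file.path(dir, sprintf("beat%d_row_pos.txt", k)),
                row.names = FALSE, col.names = FALSE)
    write.table(bt$col[v, , drop = FALSE],
                file.path(dir, sprintf("beat%d_col_pos.txt", k)),
                row.names = FALSE, col.names = FALSE)
    ss <- result$strains[[k]]
    frames <- attr(bt, "frames")
    rows <- do.call(rbind, lapply(names(ss$F), function(lab) {
      tl <- ss$tiles[ss$tiles$label == lab, ]
      Fa <- ss$F[[lab]]
      data.frame(label = lab, center_row = tl$center_row,
                 center_col = tl$center_col, frame = frames,
                 F_rr = Fa[1, 1, ], F_rc = Fa[1, 2, ],
                 F_cr = Fa[2, 1, ], F_cc = Fa[2, 2, ])
    }))
    write.table(rows, file.path(dir, sprintf("beat%d_subdomain_F.txt", k)),
                row.names = FALSE, quote = FALSE)
  }
  write_external_mask(result$mask, file.path(dir, "tissue_mask.txt"))
  writeLines(result$warnings, file.path(dir, "warnings.txt"))
  jsonlite::write_json(result$metrics[c("period", "frequency",
                                        "mean_amplitude",
                                        "tissue_width_center")],
                       file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.mb_analysis <- function(x, ...) {
  cat(sprintf("mb_analysis: %d frames of %d x %d px\n", x$n_frames,
              x$frame_shape[1], x$frame_shape[2]))
  cat(sprintf("  markers: %d valid / %d tracked (coverage %.1f px/marker)\n",
              sum(x$traj$valid), nrow(x$traj$row), x$coverage$coverage))
  cat(sprintf("  beats: %d (peaks at %s)\n", nrow(x$seg$beats),
              paste(x$seg$peaks, collapse = ", ")))
  cat(sprintf("  period: %.4g %s, mean amplitude: %.4g %s\n",
              x$metrics$period, x$metrics$units$period,
              x$metrics$mean_amplitude, x$metrics$units$mean_amplitude))
  if (length(x$warnings))
    cat("  warnings:\n", paste0("   - ", x$warnings, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
summary.mb_analysis <- function(object, ...) {
  peak_ecc <- vapply(object$strains, function(ss) {
    if (ncol(ss$E_cc) == 0) return(NA_real_)
    m <- abs(ss$E_cc)
    ss$E_cc[which.max(m)]
  }, numeric(1))
  out <- list(metrics = object$metrics,
              n_beats = nrow(object$seg$beats),
              n_markers = sum(object$traj$valid),
              peak_displacement = max(object$series),
              peak_E_cc_per_beat = peak_ecc,
              warnings = object$warnings)
  class(out) <- "summary.mb_analysis"
  out
}

#' @export
print.summary.mb_analysis <- function(x, ...) {
  cat("Microbundle analysis summary\n")
  cat(sprintf("  beats: %d, valid markers: %d\n", x$n_beats, x$n_markers))
  cat(sprintf("  peak mean displacement: %.3f px\n", x$peak_displacement))
  cat(sprintf("  beat period: %.4g %s (frequency %.4g %s)\n",
              x$metrics$period, x$metrics$units$period,
              x$metrics$frequency, x$metrics$units$frequency))
  cat(sprintf("  mean beat amplitude: %.4g %s\n", x$metrics$mean_amplitude,
              x$metrics$units$mean_amplitude))
  cat(sprintf("  tissue width at center: %.4g %s\n",
              x$metrics$tissue_width_center,
              x$metrics$units$tissue_width_center))
  cat(sprintf("  peak E_cc by beat: %s\n",
              paste(sprintf("%.4f", x$peak_E_cc_per_beat), collapse = ", ")))
  if (length(x$warnings))
    cat("  warnings:\n", paste0("   - ", x$warnings, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
plot.mb_analysis <- function(x, ...) {
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(seq_along(x$series), x$series, type = "l",
                 xlab = "frame", ylab = "mean |displacement| (px)",
                 main = "mean absolute displacement")
  graphics::points(x$seg$peaks, x$series[x$seg$peaks], col = "red", pch = 19)
  graphics::abline(v = x$seg$valleys, col = "grey60", lty = 2)
  ss <- x$strains[[1]]
  frames <- attr(x$beats[[1]], "frames")
  if (ncol(ss$E_cc) > 0) {
    graphics::matplot(frames, ss$E_cc, type = "l", lty = 1,
                      xlab = "frame", ylab = "E_cc",
                      main = "subdomain E_cc (beat 1)")
    graphics::legend("bottomleft", legend = colnames(ss$E_cc),
                     col = seq_len(ncol(ss$E_cc)), lty = 1, cex = 0.7,
                     ncol = 4, bty = "n")
  }
  invisible(x)
}
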