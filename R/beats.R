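#' Find peaks in a 1-D series by topographic prominence
#'
#' Re-implementation of the classic signal-processing peak finder used for
#' beat detection. Local maxima are strictly greater than their immediate
#' neighbors; flat plateaus are resolved to their midpoint. The topographic
#' prominence of a peak is its height minus the higher of the two base
#' levels, where each base is the minimum of the series between the peak
#' and the nearest position (per side) with a strictly greater value (or
#' the series end). Peaks with prominence below `prominence` are dropped;
#' among surviving peaks closer than `distance` samples, lower-prominence
#' peaks are removed iteratively, highest kept first.
#'
#' @param series numeric vector (length >= 3).
#' @param distance minimum peak spacing in samples (>= 1).
#' @param prominence minimum topographic prominence (series units).
#' @return Integer vector of peak indices (sorted), with the matching
#'   prominences attached as attribute `"prominence"`. May be empty.
#' @export
find_peaks <- function(series, distance = 1, prominence = 0) {
  n <- length(series)
  if (n < 3) bt_error("series too short for peak finding", "bt_range")
  # local maxima with plateau midpoints
  peaks <- integer(0)
  i <- 2L
  while (i < n) {
    if (series[i - 1] < series[i]) {
      j <- i
      while (j < n && series[j + 1] == series[i]) j <- j + 1L
      if (j < n && series[j + 1] < series[i]) {
        peaks <- c(peaks, (i + j) %/% 2L)
        i <- j
      }
    }
    i <- i + 1L
  }
  if (length(peaks) == 0)
    return(structure(integer(0), prominence = numeric(0)))
  prom <- vapply(peaks, function(p) peak_prominence(series, p), numeric(1))
  keep <- prom >= prominence
  peaks <- peaks[keep]; prom <- prom[keep]
  if (length(peaks) > 1 && distance > 1) {
    ord <- order(-prom, -series[peaks], peaks)
    alive <- rep(TRUE, length(peaks))
    for (k in ord) {
      if (!alive[k]) next
      close <- abs(peaks - peaks[k]) < distance & seq_along(peaks) != k
      alive[close & alive & (prom < prom[k] | (prom == prom[k] & seq_along(peaks) > k))] <- FALSE
    }
    peaks <- peaks[alive]; prom <- prom[alive]
  }
  o <- order(peaks)
  structure(peaks[o], prominence = prom[o])
}

peak_prominence <- function(series, p) {
  h <- series[p]
  left <- if (p > 1) {
    j <- p - 1L
    lm <- h
    while (j >= 1 && series[j] <= h) { lm <- min(lm, series[j]); j <- j - 1L }
    lm
  } else h
  right <- if (p < length(series)) {
    j <- p + 1L
    rm_ <- h
    n <- length(series)
    while (j <= n && series[j] <= h) { rm_ <- min(rm_, series[j]); j <- j + 1L }
    rm_
  } else h
  h - max(left, right)
}

#' Auto-tune peak-finding parameters from the displacement series
#'
#' Prominence is held at 0.1 (series units, i.e. pixels of mean absolute
#' displacement). Distance is 1.5 times the horizontal gap between the
#' first two consecutive intersection points of the series with its mean
#' (crossings located by linear interpolation), rounded and floored at 1.
#'
#' @param series numeric displacement series.
#' @return List with `distance` (integer) and `prominence` (0.1).
#' @export
tune_peak_params <- function(series) {
  m <- mean(series)
  x <- series - m
  # sign changes between consecutive non-zero samples; exact zeros are
  # skipped so flat stretches on the mean do not count as crossings
  cross <- numeric(0)
  last_sign <- 0
  last_idx <- 0L
  for (i in seq_along(x)) {
    si <- sign(x[i])
    if (si == 0) next
    if (last_sign != 0 && si != last_sign) {
      cross <- c(cross, last_idx +
                   x[last_idx] / (x[last_idx] - x[i]) * (i - last_idx))
      if (length(cross) >= 2) break
    }
    last_sign <- si
    last_idx <- i
  }
  if (length(cross) < 2)
    bt_error("series does not cross its mean twice; movie unsuitable for beat segmentation",
             "bt_segmentation_failure")
  distance <- max(1L, as.integer(round(1.5 * (cross[2] - cross[1]))))
  list(distance = distance, prominence = 0.1)
}

#' Temporal segmentation of the displacement series into beats
#'
#' Peaks (full contractions) are found with auto-tuned parameters; valleys
#' (most relaxed states) are the floor-midpoints of consecutive peaks, and
#' each beat spans consecutive valleys (the shared boundary valley belongs
#' to both adjacent beats, so each beat is self-contained). A minimum of 3
#' peaks, hence one complete beat, is required.
#'
#' @param series mean absolute displacement series from preliminary
#'   tracking.
#' @param distance,prominence optional overrides; tuned with
#'   [tune_peak_params()] when `NULL`.
#' @return An object of class `beat_seg`: list with `peaks`, `valleys`,
#'   `beats` (two-column matrix `start`, `end` of valley frame indices),
#'   `distance`, `prominence`.
#' @export
segment_beats <- function(series, distance = NULL, prominence = NULL) {
  if (is.null(distance) || is.null(prominence)) {
    tuned <- tune_peak_params(series)
    if (is.null(distance)) distance <- tuned$distance
    if (is.null(prominence)) prominence <- tuned$prominence
  }
  peaks <- find_peaks(series, distance = distance, prominence = prominence)
  if (length(peaks) < 3)
    bt_error("a minimum of 3 beats should be present in any movie to enable automatic analysis",
             "bt_too_few_beats")
  valleys <- (peaks[-length(peaks)] + peaks[-1]) %/% 2L
  beats <- cbind(start = valleys[-length(valleys)], end = valleys[-1])
  structure(list(peaks = as.integer(peaks), valleys = as.integer(valleys),
                 beats = beats, distance = distance, prominence = prominence),
            class = "beat_seg")
}

#' @export
print.beat_seg <- function(x, ...) {
  cat(sprintf("beat_seg: %d peaks, %d valleys, %d beats (distance = %d, prominence = %g)\n",
              length(x$peaks), length(x$valleys), nrow(x$beats),
              x$distance, x$prominence))
  invisible(x)
}

#' Split trajectories into per-beat pieces with drift correction
#'
#' Slices the trajectory arrays at beat boundaries. Within each beat the
#' first frame becomes the displacement reference, so per-beat displacement
#' at each beat's first frame is identically zero; this cancels the slow
#' tracking drift that accumulates over a whole movie.
#'
#' @param traj a [marker_traj].
#' @param seg a [segment_beats()] result.
#' @return List of [marker_traj] objects, one per beat, each carrying the
#'   movie frame indices it spans as attribute `"frames"`.
#' @export
split_per_beat <- function(traj, seg) {
  lapply(seq_len(nrow(seg$beats)), function(k) {
    idx <- seg$beats[k, "start"]:seg$beats[k, "end"]
    out <- marker_traj(traj$row[, idx, drop = FALSE],
                       traj$col[, idx, drop = FALSE], traj$valid)
    attr(out, "frames") <- idx
    attr(out, "beat") <- k
    out
  })
}

#' Movie suitability checks
#'
#' Screens for the three conditions that degrade tracking fidelity:
#' (a) blurred frames (via [detect_blur()]); (b) a movie that starts from a
#' contracted position, detected when the frame-1 displacement relative to
#' the first valley exceeds `contracted_frac` of the first beat amplitude;
#' (c) motion that is entirely sub-pixel, detected from the maximum
#' per-marker displacement when trajectories are supplied (falling back to
#' the series maximum otherwise), which inflates relative tracking errors.
#'
#' @param stack a [movie_stack].
#' @param series mean absolute displacement series (frame-1 reference).
#' @param seg a [segment_beats()] result.
#' @param traj optional [marker_traj] for the per-marker sub-pixel check.
#' @param blur_threshold passed to [detect_blur()].
#' @param contracted_frac contracted-start threshold as a fraction of the
#'   first beat amplitude (default 0.5).
#' @return Character vector of warning messages (empty when clean); each is
#'   also raised as an R warning.
#' @export
quality_checks <- function(stack, series, seg, traj = NULL,
                           blur_threshold = 1e-4, contracted_frac = 0.5) {
  msgs <- character(0)
  flags <- suppressWarnings(detect_blur(stack, threshold = blur_threshold))
  if (any(flags))
    msgs <- c(msgs, sprintf("blur: %d frame(s) appear blurred; corner detection may fail",
                            sum(flags)))
  v1 <- seg$valleys[1]
  beat1 <- seg$beats[1, "start"]:seg$beats[1, "end"]
  amp1 <- max(series[beat1]) - series[v1]
  # Two signals for a contracted start: a large frame-1 offset relative to
  # the first valley, and time asymmetry -- when the reference frame is a
  # contracted state the series dwells near its maximum (the relaxed state)
  # instead of near zero, so its mean exceeds the midrange.
  midrange <- 0.5 * (max(series) + min(series))
  if ((amp1 > 0 && series[v1] > contracted_frac * amp1) ||
      (max(series) > 0 && mean(series) > midrange))
    msgs <- c(msgs, "contracted start: the movie appears to begin in a contracted state; consider trimming leading frames to the first relaxed (valley) frame")
  peak_motion <- if (!is.null(traj)) {
    r <- traj$row[traj$valid, , drop = FALSE]
    c_ <- traj$col[traj$valid, , drop = FALSE]
    max(sqrt((r - r[, 1])^2 + (c_ - c_[, 1])^2))
  } else max(series)
  if (peak_motion < 1)
    msgs <- c(msgs, "sub-pixel motion: all tracked displacement is below one pixel; relative errors may be large")
  for (m in msgs) bt_warning(m, "bt_quality_warning")
  msgs
}
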