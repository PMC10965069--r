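test_that("find_peaks handles monotone series, triangles and the raised cosine", {
  expect_length(find_peaks(1:50), 0)
  tri <- c(rep(0, 5), 0.5, 1, 0.5, rep(0, 5))
  p <- find_peaks(tri)
  expect_equal(as.integer(p), 7L)
  expect_equal(attr(p, "prominence"), 1)
  t <- 0:199
  s <- 1 - cos(2 * pi * t / 40)
  p2 <- find_peaks(s, distance = 20, prominence = 0.1)
  expect_equal(as.integer(p2), c(21L, 61L, 101L, 141L, 181L))  # t = 20, 60, ...
})

test_that("find_peaks agrees with the brute-force prominence oracle", {
  set.seed(11)
  cases <- c(
    lapply(1:6, function(k) cumsum(rnorm(sample(20:200, 1)))),
    lapply(1:4, function(k) sin(seq(0, 6 * pi, length.out = 150)) +
             0.3 * rnorm(150)),
    list(rep(0, 50), c(0, 1, 1, 1, 0, 2, 2, 0), round(runif(100) * 4))
  )
  for (s in cases) {
    for (params in list(c(1, 0), c(5, 0.5), c(12, 0.2))) {
      got <- as.integer(find_peaks(s, params[1], params[2]))
      want <- as.integer(oracle_find_peaks(s, params[1], params[2]))
      expect_identical(got, want)
    }
  }
})

test_that("peak parameter tuning follows the mean-crossing rule", {
  t <- 0:199
  s <- 1 - cos(2 * pi * t / 40)
  tuned <- tune_peak_params(s)
  expect_equal(tuned$distance, 30L)  # 1.5 x 20-frame half-period gap
  expect_equal(tuned$prominence, 0.1)
  expect_error(tune_peak_params(rep(1, 50)), class = "bt_segmentation_failure")
  set.seed(3)
  noisy <- 1 - cos(2 * pi * (0:159) / 80) + 0.05 * rnorm(160)
  # brute-force: scan for the first two sign changes of the centered series
  x <- noisy - mean(noisy)
  cross <- which(x[-1] * x[-length(x)] < 0)[1:2]
  expect_lte(abs(tune_peak_params(noisy)$distance - 1.5 * diff(cross)), 2)
})

test_that("beat segmentation places valleys at peak midpoints", {
  t <- 0:199
  s <- 1 - cos(2 * pi * t / 40)
  seg <- segment_beats(s)
  expect_equal(seg$peaks, c(21L, 61L, 101L, 141L, 181L))
  expect_equal(seg$valleys, c(41L, 81L, 121L, 161L))
  expect_equal(unname(seg$beats[, "start"]), c(41L, 81L, 121L))
  expect_equal(unname(seg$beats[, "end"]), c(81L, 121L, 161L))
  expect_length(seg$valleys, length(seg$peaks) - 1)
  expect_equal(nrow(seg$beats), length(seg$valleys) - 1)
  # two peaks only: too few beats
  s2 <- 1 - cos(2 * pi * (0:79) / 40)
  expect_error(segment_beats(s2), class = "bt_too_few_beats")
  expect_error(segment_beats(s2), "minimum of 3 beats")
})

test_that("synthetic beat period is recovered within a frame", {
  res <- small_pipeline()
  period_frames <- mean(diff(res$seg$peaks))
  expect_lte(abs(period_frames - 30), 1)
})

test_that("per-beat splitting resets the reference and keeps the shared endpoint", {
  res <- small_pipeline()
  beats <- split_per_beat(res$traj, res$seg)
  expect_length(beats, nrow(res$seg$beats))
  for (k in seq_along(beats)) {
    b <- beats[[k]]
    expect_equal(ncol(b$row),
                 unname(res$seg$beats[k, "end"] - res$seg$beats[k, "start"] + 1))
    mad <- mean_absolute_displacement(b)
    expect_identical(mad[1], 0)
  }
  # shared boundary: last frame of beat k is first frame of beat k+1
  expect_identical(beats[[1]]$row[, ncol(beats[[1]]$row)], beats[[2]]$row[, 1])
})

test_that("drift correction bounds per-beat growth under constant drift", {
  n <- 121
  t <- 0:(n - 1)
  base <- 2 * (0.5 * (1 - cos(2 * pi * t / 30)))^2
  m <- 5
  drift <- 0.05
  row <- matrix(rep(50 + base, each = m), m, n) +
    matrix(rep(drift * t, each = m), m, n)
  col <- matrix(60, m, n)
  traj <- marker_traj(row, col)
  seg <- segment_beats(mean_absolute_displacement(traj))
  beats <- split_per_beat(traj, seg)
  peaks <- vapply(beats, function(b) max(mean_absolute_displacement(b)),
                  numeric(1))
  beat_len <- ncol(beats[[1]]$row)
  expect_lt(abs(peaks[length(peaks)] - peaks[1]), drift * beat_len)
  # without the reset the apparent peak grows without bound across beats
  global <- mean_absolute_displacement(traj)
  glob_peaks <- global[seg$peaks]
  expect_gt(glob_peaks[length(glob_peaks)] - glob_peaks[1],
            drift * 30 * (length(glob_peaks) - 2))
})

test_that("quality checks flag sub-pixel and contracted-start movies only", {
  res <- small_pipeline()
  expect_length(res$warnings, 0)  # clean super-pixel movie

  sub <- generate_movie(small_cfg(peak_amplitude = 0.4))
  mask <- generate_mask(sub$stack)
  pts <- detect_features(sub$stack$frames[[1]], mask)
  traj <- track_markers(sub$stack, pts)
  series <- mean_absolute_displacement(traj)
  seg <- segment_beats(series)
  msgs <- suppressWarnings(quality_checks(sub$stack, series, seg, traj))
  expect_true(any(grepl("sub-pixel", msgs)))
  expect_false(any(grepl("contracted", msgs)))
})

test_that("a movie started at peak contraction is flagged and fixed by trimming", {
  mv <- small_movie()
  shifted <- trim_leading_frames(mv$stack, 15)  # starts at full contraction
  res <- suppressWarnings(run_pipeline(shifted, n_tiles = c(2, 2)))
  expect_true(any(grepl("contracted", res$warnings)))
  # trim to the first relaxed frame (first series peak = relaxation here)
  fixed <- trim_leading_frames(shifted, res$seg$peaks[1] - 1)
  res2 <- suppressWarnings(run_pipeline(fixed, n_tiles = c(2, 2)))
  expect_false(any(grepl("contracted", res2$warnings)))
})
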