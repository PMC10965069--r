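test_that("trajectory rotation follows the closed form and preserves distances", {
  m <- 6; n <- 4
  set.seed(5)
  traj <- marker_traj(matrix(runif(m * n, 10, 90), m, n),
                      matrix(runif(m * n, 10, 90), m, n))
  # axis already horizontal: identity
  id <- rotate_trajectories(traj, rotation_spec(c(50, 50), c(0, 1)))
  expect_lt(max(abs(id$row - traj$row)), 1e-12)
  expect_lt(max(abs(id$col - traj$col)), 1e-12)
  # 90 degrees: relative (r, c) maps to (-c, r)
  rot <- rotate_trajectories(traj, rotation_spec(c(50, 50), c(1, 0)))
  expect_equal(rot$row - 50, -(traj$col - 50), tolerance = 1e-12)
  expect_equal(rot$col - 50, traj$row - 50, tolerance = 1e-12)
  # arbitrary angle: isometry on a random point cloud
  spec <- rotation_spec(c(40, 60), c(sin(0.4), cos(0.4)))
  rr <- rotate_trajectories(traj, spec)
  d0 <- dist(cbind(traj$row[, 1], traj$col[, 1]))
  d1 <- dist(cbind(rr$row[, 1], rr$col[, 1]))
  expect_lt(max(abs(d0 - d1)), 1e-9)
  # the axis itself maps onto the column direction
  p <- rbind(spec$center, spec$center + 10 * spec$axis)
  tr <- marker_traj(cbind(p[, 1]), cbind(p[, 2]))
  out <- rotate_trajectories(tr, spec)
  expect_equal(out$row[2, 1] - out$row[1, 1], 0, tolerance = 1e-9)
  expect_equal(out$col[2, 1] - out$col[1, 1], 10, tolerance = 1e-9)
})

test_that("displacement interpolation reproduces affine fields and flags hull exits", {
  set.seed(9)
  pos <- cbind(row = runif(40, 10, 90), col = runif(40, 10, 90))
  A <- matrix(c(0.02, -0.01, 0.005, 0.03), 2, 2)
  disp <- pos %*% t(A) + rep(c(0.5, -0.2), each = 40)
  # at a marker: exact
  out <- interpolate_displacements(pos, disp, pos[3, , drop = FALSE])
  expect_lt(max(abs(out$displacements - disp[3, ])), 1e-9)
  # interior points: affine reproduction
  q <- cbind(row = runif(30, 30, 70), col = runif(30, 30, 70))
  want <- q %*% t(A) + rep(c(0.5, -0.2), each = 30)
  got <- interpolate_displacements(pos, disp, q)
  expect_false(any(got$extrapolated))
  expect_lt(max(abs(got$displacements - want)), 1e-9)
  # outside the hull: nearest marker value, flagged
  far <- cbind(row = 500, col = 500)
  nn <- which.max(-((pos[, 1] - 500)^2 + (pos[, 2] - 500)^2))
  out2 <- interpolate_displacements(pos, disp, far)
  expect_true(out2$extrapolated[1])
  expect_equal(unname(out2$displacements[1, ]), unname(disp[nn, ]))
  # collinear markers: geometry error
  coll <- cbind(row = 1:5, col = 2 * (1:5))
  expect_error(interpolate_displacements(coll, coll * 0.1, far),
               class = "bt_geometry")
})

test_that("subdomain layout matches the arithmetic contract", {
  g <- define_subdomains(extents = c(1, 90, 1, 90), n_tiles = c(2, 2))
  expect_equal(g$tiles$label, c("A1", "A2", "B1", "B2"))
  expect_equal(g$tile_dim, c(45, 45))
  expect_equal(g$tiles$row_min, c(1, 1, 46, 46))
  expect_equal(g$tiles$col_min, c(1, 46, 1, 46))
  # 95 px extents with 30 px tiles: 3x3 grid, margins 2 and 3
  g2 <- define_subdomains(extents = c(1, 95, 1, 95), tile_size = c(30, 30))
  expect_equal(g2$n_tiles, c(3L, 3L))
  expect_equal(min(g2$tiles$row_min), 3)   # 2-px top margin
  expect_equal(max(g2$tiles$row_max), 92)  # 3-px bottom margin
  expect_error(define_subdomains(extents = c(1, 90, 1, 90),
                                 tile_size = c(200, 200)),
               class = "bt_value")
  # tiles are disjoint and inside the extents
  for (g_ in list(g, g2)) {
    hit <- matrix(0, 95, 95)
    for (k in seq_len(nrow(g_$tiles)))
      hit[g_$tiles$row_min[k]:g_$tiles$row_max[k],
          g_$tiles$col_min[k]:g_$tiles$col_max[k]] <-
        hit[g_$tiles$row_min[k]:g_$tiles$row_max[k],
            g_$tiles$col_min[k]:g_$tiles$col_max[k]] + 1
    expect_lte(max(hit), 1)
  }
})

test_that("mask-derived extents clip the attachment regions by the run rule", {
  m <- matrix(0L, 60, 100)
  m[20:40, 10:90] <- 1L      # main band: 81-px runs
  m[10:50, 5:12] <- 1L       # left pillar blob: 8-px wide
  g <- define_subdomains(mask = tissue_mask(m), n_tiles = c(2, 2))
  expect_equal(g$extents[1], 20)
  expect_equal(g$extents[2], 40)
  expect_gte(g$extents[3], 5)
})

test_that("F recovery is exact for affine maps and matches the lsq oracle", {
  ref <- cbind(c(0, 10, 0, 10), c(0, 0, 10, 10)) + 20
  expect_equal(compute_F_avg(ref, ref), diag(2), tolerance = 1e-14)
  # scale 1.1 in col, 0.9 in row
  ctr <- colMeans(ref)
  cur <- sweep(sweep(ref, 2, ctr), 2, c(0.9, 1.1), `*`)
  F1 <- compute_F_avg(ref, cur)
  expect_equal(F1, diag(c(0.9, 1.1)), tolerance = 1e-12)
  # random affine + noise, any marker count: matches the stacked lsq oracle
  set.seed(21)
  for (m in c(3, 5, 12)) {
    refm <- cbind(runif(m, 0, 30), runif(m, 0, 30))
    A <- matrix(c(1.05, 0.03, -0.02, 0.95), 2, 2)
    curm <- refm %*% t(A) + 0.05 * matrix(rnorm(2 * m), m, 2)
    expect_lt(max(abs(compute_F_avg(refm, curm) - oracle_F_lsq(refm, curm))),
              1e-10)
    # exact affine: machine-precision recovery
    expect_lt(max(abs(compute_F_avg(refm, refm %*% t(A)) - A)), 1e-10)
  }
  # ordered (duplicated) pairs leave the solution unchanged
  m <- 6
  refm <- cbind(runif(m, 0, 30), runif(m, 0, 30))
  curm <- refm %*% t(matrix(c(1.02, 0.01, 0, 0.97), 2, 2))
  expect_equal(compute_F_avg(rbind(refm, refm), rbind(curm, curm)),
               compute_F_avg(refm, curm), tolerance = 1e-9)
  # collinear markers: degenerate
  coll <- cbind(1:5, 2 * (1:5))
  expect_error(compute_F_avg(coll, coll), class = "bt_degenerate_subdomain")
})

test_that("Green-Lagrange strain follows the closed forms", {
  expect_equal(green_lagrange(diag(2)), diag(0, 2),
               tolerance = 1e-15, ignore_attr = TRUE)
  E <- green_lagrange(diag(c(1.0, 1.1)))  # 1.1 stretch along col
  expect_equal(E[2, 2], 0.105, tolerance = 1e-12)
  expect_equal(E[1, 1], 0)
  expect_equal(E[1, 2], 0)
  comps <- attr(E, "components")
  expect_equal(unname(comps["E_cc"]), 0.105, tolerance = 1e-12)
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_lt(max(abs(green_lagrange(R))), 1e-12)
  # rigid-body indifference: E(RF) = E(F)
  F1 <- matrix(c(1.04, 0.02, -0.01, 0.93), 2, 2)
  expect_equal(green_lagrange(R %*% F1), green_lagrange(F1),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("homogeneous strain series matches the global closed form per tile", {
  cfg <- small_cfg()
  truth <- synthetic_truth(cfg)
  frames <- 31:61  # one beat, valley to valley
  grid <- define_subdomains(extents = c(25, 104, 25, 104), n_tiles = c(2, 2))
  # exact trajectories sampled from the analytic (affine) field
  X <- as.matrix(expand.grid(row = seq(27, 102, by = 5),
                             col = seq(27, 102, by = 5)))
  pos <- lapply(frames, function(j) X + truth$field(X, j - 1))
  traj <- marker_traj(
    do.call(cbind, lapply(pos, `[`, , 1)),
    do.call(cbind, lapply(pos, `[`, , 2)))
  attr(traj, "frames") <- frames
  ss <- subdomain_strain_series(traj, grid)
  expect_length(ss$excluded, 0)
  # closed form: col stretch 1 - a A / half_c relative to the beat reference
  lc <- 1 - (activation(frames - 1, cfg$period, cfg$sharpness) *
               cfg$peak_amplitude) / ((cfg$dim[2] - 1) / 2)
  ecc_true <- 0.5 * ((lc / lc[1])^2 - 1)
  for (lab in colnames(ss$E_cc))
    expect_lt(max(abs(ss$E_cc[, lab] - ecc_true)), 1e-3)
  # frame 1 of the beat: identically zero strain
  for (lab in names(ss$E))
    expect_equal(ss$E[[lab]][, , 1], matrix(0, 2, 2), tolerance = 1e-12)

  # the same comparison through the tracked pipeline stays within 5e-3
  res <- small_pipeline()
  beats <- split_per_beat(res$traj, res$seg)
  fr2 <- attr(beats[[1]], "frames")
  ss2 <- subdomain_strain_series(beats[[1]], grid)
  lc2 <- 1 - (activation(fr2 - 1, cfg$period, cfg$sharpness) *
                cfg$peak_amplitude) / ((cfg$dim[2] - 1) / 2)
  ecc2 <- 0.5 * ((lc2 / lc2[1])^2 - 1)
  for (lab in colnames(ss2$E_cc))
    expect_lt(max(abs(ss2$E_cc[, lab] - ecc2)), 5e-3)
})

test_that("an inclusion suppresses strain in the central tile", {
  res <- inclusion_pipeline()
  ss <- res$strains[[1]]
  expect_true(all(c("B1", "B2", "B3") %in% colnames(ss$E_cc)))
  peak_by_tile <- apply(abs(ss$E_cc), 2, max)
  expect_lt(peak_by_tile["B2"], min(peak_by_tile[c("B1", "B3")]))
})

test_that("beat metrics convert frames and pixels to physical units", {
  s <- 1 - cos(2 * pi * (0:199) / 30)
  seg <- segment_beats(s)
  mask <- full_mask(100, border = 20)
  m <- beat_metrics(s, seg, mask, fps = 30, scale = 4)
  expect_equal(m$period, 1.0, tolerance = 1e-9)
  expect_equal(m$frequency, 1.0, tolerance = 1e-9)
  expect_equal(m$units$period, "s")
  expect_equal(m$tissue_width_center, 60 * 4)
  # amplitude conversion: series amplitude x scale
  amp_px <- mean(sapply(seq_len(nrow(seg$beats)), function(k) {
    idx <- seg$beats[k, 1]:seg$beats[k, 2]
    max(s[idx]) - s[seg$beats[k, 1]]
  }))
  expect_equal(m$mean_amplitude, amp_px * 4, tolerance = 1e-9)
  m2 <- beat_metrics(s, seg, mask)
  expect_equal(m2$units$mean_amplitude, "px")
  expect_false(is.null(m2$notice))
})
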