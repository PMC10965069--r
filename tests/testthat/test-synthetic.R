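test_that("activation pulse hits its boundary values", {
  expect_equal(activation(0, 40), 0)
  expect_equal(activation(20, 40, sharpness = 1), 1)
  expect_equal(activation(20, 40, sharpness = 2), 1)
  expect_equal(activation(40, 40), 0)
  s <- activation(0:199, 40)
  expect_length(find_peaks(s, distance = 20, prominence = 0.1), 5)
  expect_true(all(s >= 0 & s <= 1))
})

test_that("the analytic field obeys its symmetries", {
  cfg <- synthetic_config(seed = 0)
  mid <- (256 + 1) / 2
  # zero activation: zero field
  u0 <- displacement_field(cbind(100, 100), 0, cfg)
  expect_equal(unname(u0), cbind(0, 0))
  # midline: zero horizontal displacement
  um <- displacement_field(cbind(50, mid), 20, cfg)
  expect_equal(unname(um[1, 2]), 0)
  # domain edge at peak activation: |u_col| equals the peak amplitude
  ue <- displacement_field(cbind(mid, 256), 20, cfg)
  expect_equal(abs(unname(ue[1, 2])), 2.5, tolerance = 1e-12)
  # inclusion center: fully suppressed
  cfgi <- synthetic_config(seed = 0, variant = "inclusion")
  ui <- displacement_field(rbind(cfgi$inclusion_center), 20, cfgi)
  expect_equal(max(abs(ui)), 0)
})

test_that("homography estimation is exact on constructions", {
  src <- cbind(c(10, 10, 60, 60, 20, 50, 30, 44),
               c(10, 60, 10, 60, 35, 25, 52, 18))
  H_id <- estimate_projective(src[1:4, ], src[1:4, ])
  expect_equal(H_id, diag(3), tolerance = 1e-9)
  H_tr <- estimate_projective(src[1:4, ], src[1:4, ] +
                                rep(c(3, 4), each = 4))
  expect_equal(H_tr[1, 3], 3, tolerance = 1e-9)
  expect_equal(H_tr[2, 3], 4, tolerance = 1e-9)
  expect_equal(H_tr[1:2, 1:2], diag(2), tolerance = 1e-9)
  # random homography, 8 points: recovered to 1e-8 after normalization
  set.seed(2)
  H <- matrix(c(1.1, 0.05, 2, -0.03, 0.95, -1, 1e-4, -2e-4, 1), 3, 3,
              byrow = TRUE)
  dst <- apply_projective(H, src)
  H_hat <- estimate_projective(src, dst)
  expect_lt(max(abs(H_hat - H)), 1e-8)
  expect_error(estimate_projective(cbind(1:4, 2 * (1:4)), src[1:4, ]),
               class = "bt_geometry")
})

test_that("cellwise warping matches roll and global-affine oracles", {
  texture <- analytic_texture(96)$img
  # zero field: bit-for-bit identity
  w0 <- warp_frame(texture, function(p) cbind(0 * p[, 1], 0 * p[, 2]))
  expect_identical(w0, texture)
  # uniform translation by (3, 0): equals the rolled texture in the interior
  w1 <- warp_frame(texture, function(p) cbind(rep(3, nrow(p)), rep(0, nrow(p))))
  roll <- rbind(texture[c(1, 1, 1), ], texture[1:93, ])
  expect_lt(max(abs(w1[10:90, 5:90] - roll[10:90, 5:90])), 1e-6)
  # affine field: equals one global affine warp (continuity across cells)
  A <- matrix(c(-0.02, 0.004, 0.006, -0.03), 2, 2)
  aff_field <- function(p) p %*% t(A)
  w2 <- warp_frame(texture, aff_field, warp_cell = 16)
  # oracle: invert the global affine map exactly and resample the texture
  # with a textbook bilinear interpolation written out longhand
  Ainv <- solve(diag(2) + A)
  g <- as.matrix(expand.grid(row = 10:85, col = 10:85))
  src <- g %*% t(Ainv)
  r0 <- floor(src[, 1]); c0 <- floor(src[, 2])
  fr <- src[, 1] - r0; fc <- src[, 2] - c0
  direct <- (1 - fr) * (1 - fc) * texture[cbind(r0, c0)] +
    (1 - fr) * fc * texture[cbind(r0, c0 + 1)] +
    fr * (1 - fc) * texture[cbind(r0 + 1, c0)] +
    fr * fc * texture[cbind(r0 + 1, c0 + 1)]
  expect_lt(max(abs(w2[cbind(g[, 1], g[, 2])] - direct)), 1e-3)
})

test_that("Perlin noise respects its amplitude bound and determinism", {
  frame <- analytic_texture(80)$img
  expect_identical(add_perlin_noise(frame, 0, 40, 1), frame)
  n1 <- add_perlin_noise(frame, 0.12, 40, 3)
  n2 <- add_perlin_noise(frame, 0.12, 40, 3)
  expect_identical(n1, n2)
  n3 <- add_perlin_noise(frame, 0.12, 40, 4)
  expect_false(identical(n1, n3))
  pert <- n1 - frame
  expect_equal(max(abs(pert)), 0.12 * diff(range(frame)), tolerance = 1e-9)
  # noise addition is a pure function: the input frame is untouched
  expect_identical(frame, analytic_texture(80)$img)
})

test_that("generated movies honor their configuration", {
  # zero amplitude: all frames identical, truth series identically zero
  cfg0 <- synthetic_config(dim = c(64, 64), period = 16, n_frames = 49,
                           peak_amplitude = 0, seed = 2)
  mv0 <- generate_movie(cfg0)
  expect_true(all(vapply(mv0$stack$frames,
                         identical, logical(1), mv0$stack$frames[[1]])))
  expect_true(all(mv0$truth$series == 0))
  # default config: truth series has one equal-height peak per beat
  mv <- small_movie()
  pk <- find_peaks(mv$truth$series, distance = 15, prominence = 0.01)
  expect_length(pk, 5)
  expect_lt(diff(range(mv$truth$series[pk])), 1e-9)
  # truth series is periodic with the configured period
  s <- mv$truth$series
  expect_lt(max(abs(s[1:30] - s[31:60])), 1e-12)
  # invalid configurations are rejected
  expect_error(synthetic_config(n_frames = 50, period = 40), class = "bt_value")
  expect_error(synthetic_config(warp_cell = 2), class = "bt_value")
})

test_that("truth subdomain strain on a dense lattice converges to the closed form", {
  cfg <- small_cfg()
  truth <- synthetic_truth(cfg)
  t_peak <- 15
  lc <- 1 - activation(t_peak, cfg$period, cfg$sharpness) *
    cfg$peak_amplitude / ((cfg$dim[2] - 1) / 2)
  ecc_closed <- 0.5 * (lc^2 - 1)
  errs <- sapply(c(9, 3), function(spacing) {
    X <- as.matrix(expand.grid(row = seq(40, 88, by = spacing),
                               col = seq(40, 88, by = spacing)))
    p_ref <- X + truth$field(X, 0)
    p_cur <- X + truth$field(X, t_peak)
    abs(green_lagrange(compute_F_avg(p_ref, p_cur))[2, 2] - ecc_closed)
  })
  # affine field: exact at any lattice density
  expect_lt(max(errs), 1e-12)
  # inclusion variant: non-affine, so refinement must reduce the error
  cfgi <- small_cfg(variant = "inclusion", inclusion_radius = 30)
  truthi <- synthetic_truth(cfgi)
  errs_i <- sapply(c(16, 8, 2), function(spacing) {
    X <- as.matrix(expand.grid(row = seq(33, 97, by = spacing),
                               col = seq(33, 97, by = spacing)))
    p_ref <- X + truthi$field(X, 0)
    p_cur <- X + truthi$field(X, t_peak)
    green_lagrange(compute_F_avg(p_ref, p_cur))[2, 2]
  })
  expect_lt(abs(errs_i[3] - errs_i[2]), abs(errs_i[3] - errs_i[1]) + 1e-15)
})

test_that("validation comparison computes peak errors and R2 as defined", {
  truth <- list(activation(0:40, 40), activation(0:40, 40))
  self <- validation_compare(truth, truth)
  expect_equal(self$worst_peak_pct_error, 0)
  expect_equal(self$min_r2, 1)
  # a 10% bump exactly at the peak frame
  bumped <- lapply(truth, function(s) {
    s[which.max(s)] <- s[which.max(s)] * 1.1
    s
  })
  vc <- validation_compare(bumped, truth)
  expect_equal(vc$worst_peak_pct_error, 10, tolerance = 1e-9)
  # white noise: R2 matches 1 - sigma^2/var(truth) in expectation
  set.seed(8)
  long <- activation(0:3999, 40)
  sigma <- 0.05
  noisy <- long + rnorm(4000, sd = sigma)
  vc2 <- validation_compare(list(noisy), list(long))
  expect_equal(vc2$min_r2, 1 - sigma^2 / stats::var(long), tolerance = 0.02)
  expect_error(validation_compare(list(rep(1, 5)), list(rep(1, 5))),
               class = "bt_zero_variance")
})

test_that("write_synthetic_movie round-trips movie and truth text", {
  cfg <- synthetic_config(dim = c(64, 64), period = 16, n_frames = 49,
                          peak_amplitude = 1, seed = 3)
  mv <- generate_movie(cfg)
  d <- withr::local_tempdir()
  write_synthetic_movie(mv, d)
  re <- load_movie(file.path(d, "movie.tif"))
  expect_identical(re$frames, mv$stack$frames)
  cfg_back <- jsonlite::read_json(file.path(d, "config.json"))
  expect_equal(cfg_back$period, 16)
  tt <- read.table(file.path(d, "truth_frame0009.txt"), header = TRUE)
  u <- mv$truth$field(as.matrix(tt[, c("row", "col")]), 8)
  expect_equal(tt$u_col, unname(u[, 2]), tolerance = 1e-9)
})
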