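#' Configuration for synthetic beating-movie generation
#'
#' Describes a textured tissue band undergoing periodic in-plane
#' contraction toward its vertical midline with transverse (Poisson-like)
#' bulging, rendered by piecewise-projective warping of a speckle texture.
#' The defaults reproduce the package's reference validation condition:
#' a 256 x 256 speckle texture, 40-frame beat period, 5 complete beats
#' (201 frames) and a 2.5 px super-pixel peak amplitude. Ground truth is
#' analytic, so tracked output can be compared against exact displacement
#' and strain fields.
#'
#' @param dim image size `c(rows, cols)`.
#' @param n_frames number of frames (default `5 * period + 1`).
#' @param period beat period in frames.
#' @param peak_amplitude peak horizontal edge displacement in pixels
#'   (>= 1 is the super-pixel regime, < 1 sub-pixel).
#' @param variant `"homogeneous"` or `"inclusion"` (a passive circular
#'   inclusion at the tissue center that locally suppresses contraction).
#' @param inclusion_center,inclusion_radius inclusion geometry in pixels
#'   (defaults: image center, radius 30).
#' @param nu transverse-to-axial displacement ratio (bulging), default 0.3.
#' @param sharpness activation pulse sharpness exponent, default 2.
#' @param warp_cell projective warping cell size in pixels, default 16.
#' @param noise_magnitude_ratio Perlin noise amplitude as a fraction of the
#'   frame intensity range (0 disables noise).
#' @param noise_octaves Perlin base lattice frequency: number of lattice
#'   periods across the longer image side.
#' @param tissue_rows `c(first, last)` rows of the textured tissue band.
#' @param texture optional user texture matrix (speckle is generated when
#'   `NULL`).
#' @param fps,scale acquisition metadata attached to the generated stack.
#' @param seed integer RNG seed for texture and noise.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(dim = c(256, 256), period = 40,
                             n_frames = 5 * period + 1,
                             peak_amplitude = 2.5,
                             variant = c("homogeneous", "inclusion"),
                             inclusion_center = (dim + 1) / 2,
                             inclusion_radius = 30, nu = 0.3, sharpness = 2,
                             warp_cell = 16, noise_magnitude_ratio = 0,
                             noise_octaves = 40,
                             tissue_rows = NULL, texture = NULL,
                             fps = 30, scale = NULL, seed = 0) {
  variant <- match.arg(variant)
  if (period < 4) bt_error("period must be >= 4 frames", "bt_value")
  if (n_frames < 3 * period)
    bt_error("n_frames must cover at least 3 beat periods", "bt_value")
  if (peak_amplitude < 0) bt_error("peak_amplitude must be >= 0", "bt_value")
  if (warp_cell < 4) bt_error("warp_cell must be >= 4", "bt_value")
  if (is.null(tissue_rows)) {
    mid <- (dim[1] + 1) / 2
    tissue_rows <- c(floor(mid - dim[1] / 4), floor(mid + dim[1] / 4))
  }
  structure(list(dim = as.integer(dim), period = period,
                 n_frames = as.integer(n_frames),
                 peak_amplitude = peak_amplitude, variant = variant,
                 inclusion_center = inclusion_center,
                 inclusion_radius = inclusion_radius, nu = nu,
                 sharpness = sharpness, warp_cell = as.integer(warp_cell),
                 noise_magnitude_ratio = noise_magnitude_ratio,
                 noise_octaves = noise_octaves, tissue_rows = tissue_rows,
                 texture = texture, fps = fps, scale = scale,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Periodic activation pulse
#'
#' Raised-cosine pulse train `a(t) = (0.5 * (1 - cos(2 pi frac(t /
#' period))))^sharpness` on `[0, 1]`, zero at every beat boundary and 1 at
#' mid-beat. `t` is a 0-based frame time (frame j of a movie corresponds
#' to `t = j - 1`).
#'
#' @param t frame time(s), 0-based.
#' @param period beat period in frames.
#' @param sharpness pulse sharpness exponent (>= 1).
#' @return Activation value(s) in `[0, 1]`.
#' @export
activation <- function(t, period, sharpness = 2) {
  (0.5 * (1 - cos(2 * pi * (t %% period) / period)))^sharpness
}

#' Analytic tissue displacement field
#'
#' Horizontal contraction toward the vertical midline with transverse
#' bulging: `u_col = -a(t) A (col - col_mid) / half_width`,
#' `u_row = nu a(t) A (row - row_mid) / half_height`. The inclusion
#' variant multiplies the field by a cosine taper that ramps to zero at
#' the center of a passive circular inclusion.
#'
#' @param points M x 2 matrix of (`row`, `col`) positions.
#' @param t frame time, 0-based.
#' @param cfg a [synthetic_config].
#' @return M x 2 matrix of (row, col) displacements in pixels.
#' @export
displacement_field <- function(points, t, cfg) {
  a <- activation(t, cfg$period, cfg$sharpness)
  mid_r <- (cfg$dim[1] + 1) / 2
  mid_c <- (cfg$dim[2] + 1) / 2
  half_r <- (cfg$dim[1] - 1) / 2
  half_c <- (cfg$dim[2] - 1) / 2
  u_col <- -a * cfg$peak_amplitude * (points[, 2] - mid_c) / half_c
  u_row <- cfg$nu * a * cfg$peak_amplitude * (points[, 1] - mid_r) / half_r
  if (cfg$variant == "inclusion") {
    rho <- sqrt((points[, 1] - cfg$inclusion_center[1])^2 +
                (points[, 2] - cfg$inclusion_center[2])^2) / cfg$inclusion_radius
    taper <- ifelse(rho >= 1, 1, 0.5 * (1 - cos(pi * pmin(rho, 1))))
    u_col <- u_col * taper
    u_row <- u_row * taper
  }
  cbind(row = u_row, col = u_col)
}

#' Estimate a projective transformation (homography)
#'
#' For exactly 4 correspondences the 8 x 8 linear system is solved
#' directly (exact interpolation); for more, the normalized
#' direct-linear-transform least-squares solution is used. The returned
#' 3 x 3 matrix maps homogeneous (row, col, 1) source points to
#' destination points, last entry normalized to 1.
#'
#' @param src,dst n x 2 matrices of (`row`, `col`) points, n >= 4.
#' @return 3 x 3 homography matrix.
#' @export
estimate_projective <- function(src, dst) {
  n <- nrow(src)
  if (n < 4 || nrow(dst) != n)
    bt_error("need >= 4 point correspondences", "bt_geometry")
  if (n == 4) {
    A <- matrix(0, 8, 8); b <- numeric(8)
    for (i in 1:4) {
      r <- src[i, 1]; c_ <- src[i, 2]; rp <- dst[i, 1]; cp <- dst[i, 2]
      A[2 * i - 1, ] <- c(r, c_, 1, 0, 0, 0, -rp * r, -rp * c_)
      A[2 * i, ]     <- c(0, 0, 0, r, c_, 1, -cp * r, -cp * c_)
      b[2 * i - 1] <- rp; b[2 * i] <- cp
    }
    h <- tryCatch(solve(A, b), error = function(e)
      bt_error("degenerate point configuration", "bt_geometry"))
    return(matrix(c(h, 1), 3, 3, byrow = TRUE))
  }
  norm_t <- function(p) {
    ctr <- colMeans(p)
    d <- sweep(p, 2, ctr)
    s <- sqrt(2) / mean(sqrt(rowSums(d^2)))
    T <- rbind(c(s, 0, -s * ctr[1]), c(0, s, -s * ctr[2]), c(0, 0, 1))
    list(T = T, p = cbind(s * d[, 1], s * d[, 2]))
  }
  ns <- norm_t(src); nd <- norm_t(dst)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    r <- ns$p[i, 1]; c_ <- ns$p[i, 2]; rp <- nd$p[i, 1]; cp <- nd$p[i, 2]
    A[2 * i - 1, ] <- c(r, c_, 1, 0, 0, 0, -rp * r, -rp * c_, -rp)
    A[2 * i, ]     <- c(0, 0, 0, r, c_, 1, -cp * r, -cp * c_, -cp)
  }
  sv <- svd(A)
  h <- sv$v[, 9]
  H <- matrix(h, 3, 3, byrow = TRUE)
  if (abs(det(H)) < 1e-12)
    bt_error("degenerate point configuration", "bt_geometry")
  H <- solve(nd$T) %*% H %*% ns$T
  H / H[3, 3]
}

#' Apply a homography to points
#'
#' @param H 3 x 3 homography from [estimate_projective()].
#' @param points M x 2 matrix of (`row`, `col`) points.
#' @return M x 2 matrix of mapped points.
#' @export
apply_projective <- function(H, points) {
  den <- H[3, 1] * points[, 1] + H[3, 2] * points[, 2] + H[3, 3]
  cbind(row = (H[1, 1] * points[, 1] + H[1, 2] * points[, 2] + H[1, 3]) / den,
        col = (H[2, 1] * points[, 1] + H[2, 2] * points[, 2] + H[2, 3]) / den)
}

#' Warp a texture by a displacement field, cell by cell
#'
#' The image is tiled into `warp_cell`-sized cells whose corner nodes are
#' shared between neighbors. Each cell's projective transform is estimated
#' from its 4 node correspondences (node and node + displacement) and the
#' cell is inverse-warped with bilinear sampling; shared nodes keep the
#' result continuous across cell edges. Cells whose nodes do not move are
#' copied verbatim.
#'
#' @param texture grayscale matrix.
#' @param field function mapping an M x 2 (`row`, `col`) matrix to an
#'   M x 2 displacement matrix.
#' @param warp_cell cell size in pixels.
#' @return Warped matrix, same shape as `texture`.
#' @export
warp_frame <- function(texture, field, warp_cell = 16) {
  nr <- nrow(texture); nc <- ncol(texture)
  rs <- unique(c(seq(1L, nr, by = warp_cell), nr))
  cs <- unique(c(seq(1L, nc, by = warp_cell), nc))
  nR <- length(rs); nC <- length(cs)
  nodes <- cbind(row = rep(rs, nC), col = rep(cs, each = nR))
  U <- field(nodes)
  out <- matrix(0, nr, nc)
  for (j in seq_len(nC - 1)) {
    for (i in seq_len(nR - 1)) {
      ids <- c((j - 1) * nR + i, (j - 1) * nR + i + 1,
               j * nR + i, j * nR + i + 1)
      rpix <- rs[i]:(if (i < nR - 1) rs[i + 1] - 1L else rs[i + 1])
      cpix <- cs[j]:(if (j < nC - 1) cs[j + 1] - 1L else cs[j + 1])
      if (all(U[ids, ] == 0)) {
        out[rpix, cpix] <- texture[rpix, cpix]
        next
      }
      src <- nodes[ids, , drop = FALSE]
      dst <- src + U[ids, , drop = FALSE]
      H <- estimate_projective(dst, src)  # deformed -> reference
      pr <- rep(rpix, length(cpix))
      pc <- rep(cpix, each = length(rpix))
      den <- H[3, 1] * pr + H[3, 2] * pc + H[3, 3]
      sr <- (H[1, 1] * pr + H[1, 2] * pc + H[1, 3]) / den
      sc <- (H[2, 1] * pr + H[2, 2] * pc + H[2, 3]) / den
      out[rpix, cpix] <- bilinear_sample(texture, sr, sc)
    }
  }
  out
}

# 2-D gradient (Perlin) noise field over an nr x nc pixel grid with lattice
# spacing in pixels. Uses the classic quintic fade; consumes the current
# RNG stream.
perlin_field <- function(nr, nc, spacing) {
  u <- ((seq_len(nr)) - 1) / spacing
  v <- ((seq_len(nc)) - 1) / spacing
  U <- matrix(rep(u, nc), nr, nc)
  V <- matrix(rep(v, each = nr), nr, nc)
  i0 <- floor(U); j0 <- floor(V)
  fu <- U - i0; fv <- V - j0
  ni <- max(i0) + 2L; nj <- max(j0) + 2L
  theta <- matrix(stats::runif(ni * nj, 0, 2 * pi), ni, nj)
  gr <- cos(theta); gc <- sin(theta)
  corner_dot <- function(a, b) {
    idx <- cbind(as.vector(i0) + 1L + a, as.vector(j0) + 1L + b)
    matrix(gr[idx] * as.vector(fu - a) + gc[idx] * as.vector(fv - b), nr, nc)
  }
  fade <- function(x) x * x * x * (x * (x * 6 - 15) + 10)
  su <- fade(fu); sv <- fade(fv)
  n00 <- corner_dot(0, 0); n10 <- corner_dot(1, 0)
  n01 <- corner_dot(0, 1); n11 <- corner_dot(1, 1)
  nx0 <- n00 + su * (n10 - n00)
  nx1 <- n01 + su * (n11 - n01)
  nx0 + sv * (nx1 - nx0)
}

#' Add Perlin noise to a frame
#'
#' Smooth lattice-gradient noise with a base lattice of `octaves` periods
#' across the longer image side, scaled so that the maximum absolute
#' perturbation equals `magnitude_ratio` times the frame's intensity
#' range, then added to the frame. Deterministic for a given seed; a
#' magnitude ratio of 0 returns the frame unchanged.
#'
#' @param frame grayscale matrix.
#' @param magnitude_ratio noise amplitude as a fraction of the intensity
#'   range (>= 0).
#' @param octaves number of lattice periods across the longer side.
#' @param seed integer RNG seed.
#' @return The perturbed frame (not clamped; [write_movie()] clamps).
#' @export
add_perlin_noise <- function(frame, magnitude_ratio, octaves, seed) {
  if (magnitude_ratio <= 0) return(frame)
  spacing <- max(dim(frame)) / octaves
  raw <- with_seed(seed, perlin_field(nrow(frame), ncol(frame), spacing))
  mx <- max(abs(raw))
  if (mx == 0) return(frame)
  frame + raw / mx * magnitude_ratio * diff(range(frame))
}

# Band-limited speckle texture: bright textured tissue band on a darker,
# weakly textured background. Consumes the current RNG stream.
speckle_texture <- function(dim, tissue_rows, sigma = 2) {
  wn <- matrix(stats::rnorm(prod(dim)), dim[1], dim[2])
  sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(wn), sigma = sigma))
  sm <- (sm - mean(sm)) / stats::sd(sm)
  band <- seq_len(dim[1]) >= tissue_rows[1] & seq_len(dim[1]) <= tissue_rows[2]
  tex <- 0.15 + 0.04 * sm
  tex[band, ] <- 0.55 + 0.18 * sm[band, ]
  pmin(pmax(tex, 0.01), 0.99)
}

#' Generate a synthetic beating movie with exact ground truth
#'
#' Renders `n_frames` frames by warping the texture with the analytic
#' displacement field at each frame time (adding Perlin noise when
#' configured) and quantizing to the 16-bit grid, so a written movie
#' reloads bit-for-bit. Ground truth carries the analytic field, the
#' central 90 x 90 evaluation window, the true tissue region, and the
#' true mean absolute displacement series over the window.
#'
#' @param cfg a [synthetic_config].
#' @return List with `stack` (a [movie_stack]) and `truth` (class
#'   `synthetic_truth`).
#' @export
generate_movie <- function(cfg) {
  texture <- cfg$texture
  if (is.null(texture))
    texture <- with_seed(cfg$seed, speckle_texture(cfg$dim, cfg$tissue_rows))
  frames <- vector("list", cfg$n_frames)
  for (j in seq_len(cfg$n_frames)) {
    t <- j - 1
    a <- activation(t, cfg$period, cfg$sharpness)
    f <- if (a == 0 || cfg$peak_amplitude == 0) texture else
      warp_frame(texture, function(p) displacement_field(p, t, cfg), cfg$warp_cell)
    if (cfg$noise_magnitude_ratio > 0)
      f <- add_perlin_noise(f, cfg$noise_magnitude_ratio, cfg$noise_octaves,
                            cfg$seed)
    frames[[j]] <- round(pmin(pmax(f, 0), 1) * 65535) / 65535
  }
  stack <- movie_stack(frames, fps = cfg$fps, scale = cfg$scale)
  list(stack = stack, truth = synthetic_truth(cfg))
}

#' @rdname generate_movie
#' @export
synthetic_truth <- function(cfg) {
  mid <- (cfg$dim + 1) / 2
  side <- min(90, cfg$dim)  # central evaluation window, 90 px when possible
  w0 <- floor(mid - side / 2) + 1
  window <- c(w0[1], w0[1] + side - 1, w0[2], w0[2] + side - 1)
  pts <- cbind(row = rep(window[1]:window[2], side),
               col = rep(window[3]:window[4], each = side))
  series <- vapply(seq_len(cfg$n_frames), function(j) {
    u <- displacement_field(pts, j - 1, cfg)
    mean(sqrt(u[, 1]^2 + u[, 2]^2))
  }, numeric(1))
  mask <- matrix(FALSE, cfg$dim[1], cfg$dim[2])
  mask[cfg$tissue_rows[1]:cfg$tissue_rows[2], ] <- TRUE
  structure(list(cfg = cfg, window = window,
                 field = function(points, t) displacement_field(points, t, cfg),
                 tissue_mask = mask, series = series),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %s, amplitude %.2f px, period %d, %d frames\n",
              x$cfg$variant, x$cfg$peak_amplitude, x$cfg$period, x$cfg$n_frames))
  invisible(x)
}

#' Write a synthetic movie and its ground truth to disk
#'
#' The movie goes to a 16-bit multi-page TIFF, the truth displacement
#' field on the evaluation-window lattice to per-frame text arrays, and
#' the configuration to a JSON sidecar.
#'
#' @param movie result of [generate_movie()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_movie <- function(movie, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_movie(movie$stack, file.path(dir, "movie.tif"))
  cfg <- movie$truth$cfg
  keep <- !vapply(cfg, is.null, logical(1)) & names(cfg) != "texture"
  jsonlite::write_json(unclass(cfg)[keep], file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  w <- movie$truth$window
  pts <- cbind(row = rep(w[1]:w[2], w[4] - w[3] + 1),
               col = rep(w[3]:w[4], each = w[2] - w[1] + 1))
  for (j in seq_len(cfg$n_frames)) {
    u <- movie$truth$field(pts, j - 1)
    write.table(cbind(pts, u), file.path(dir, sprintf("truth_frame%04d.txt", j)),
                row.names = FALSE, col.names = c("row", "col", "u_row", "u_col"))
  }
  invisible(dir)
}

#' Compare tracked and ground-truth per-beat series
#'
#' For each beat, reports the percentage error at peak displacement,
#' `|tracked_peak - truth_peak| / truth_peak * 100`, and the coefficient
#' of determination R-squared of the tracked series against the truth
#' series. Single numeric vectors are treated as one beat.
#'
#' @param tracked_beats list of per-beat tracked series (or one vector).
#' @param truth_beats matching list of ground-truth series.
#' @return List with `per_beat` (data frame: beat, peak_pct_error, r2),
#'   `worst_peak_pct_error`, and `min_r2`.
#' @export
validation_compare <- function(tracked_beats, truth_beats) {
  if (is.numeric(tracked_beats)) tracked_beats <- list(tracked_beats)
  if (is.numeric(truth_beats)) truth_beats <- list(truth_beats)
  stopifnot(length(tracked_beats) == length(truth_beats))
  per_beat <- do.call(rbind, lapply(seq_along(tracked_beats), function(k) {
    tr <- tracked_beats[[k]]; th <- truth_beats[[k]]
    stopifnot(length(tr) == length(th))
    pk <- max(th)
    if (pk <= 0)
      bt_error("truth series peak is zero; peak error undefined", "bt_zero_variance")
    data.frame(beat = k,
               peak_pct_error = abs(max(tr) - pk) / pk * 100,
               r2 = r2_score(th, tr))
  }))
  list(per_beat = per_beat,
       worst_peak_pct_error = max(per_beat$peak_pct_error),
       min_r2 = min(per_beat$r2))
}
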