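# Programmatic fixtures, cached across test files.

.fixtures <- new.env()

# A compact beating movie: 128x128, 3 complete beats, super-pixel motion.
small_cfg <- function(...) {
  defaults <- list(dim = c(128, 128), period = 30, n_frames = 151,
                   peak_amplitude = 2, seed = 1)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

small_movie <- function() {
  if (is.null(.fixtures$small)) .fixtures$small <- generate_movie(small_cfg())
  .fixtures$small
}

small_pipeline <- function() {
  if (is.null(.fixtures$small_res))
    .fixtures$small_res <- suppressWarnings(
      run_pipeline(small_movie()$stack, n_tiles = c(2, 2)))
  .fixtures$small_res
}

# Band-limited deterministic texture: a sum of incommensurate sinusoids,
# evaluable at arbitrary (sub-pixel) coordinates.
analytic_texture <- function(n = 96) {
  # chirped (frequency-modulated) components: band-limited (wavelengths
  # >= ~5 px) yet aperiodic, so every neighborhood is unique and sparse
  # optical flow has no false matching basins
  f <- function(r, c)
    0.5 + 0.16 * sin(0.16 * r + 0.0008 * r^2 + 0.22 * c) +
      0.14 * cos(0.28 * c + 0.0012 * c^2 - 0.10 * r) +
      0.05 * sin(0.45 * r + 0.0028 * r^2) +
      0.05 * cos(0.40 * c + 0.0030 * c^2) +
      0.05 * sin(0.55 * r + 0.70 * c + 0.0008 * r * c) +
      0.04 * cos(0.85 * c - 0.55 * r + 0.0012 * r * c)
  list(f = f,
       img = outer(seq_len(n), seq_len(n), f))
}

# Movie translating an analytic texture by (dr, dc) per frame (exact,
# including sub-pixel shifts).
shift_movie <- function(n_frames, dr, dc, n = 96) {
  tex <- analytic_texture(n)
  frames <- lapply(seq_len(n_frames) - 1, function(k)
    outer(seq_len(n), seq_len(n), function(r, c) tex$f(r - k * dr, c - k * dc)))
  movie_stack(frames)
}

full_mask <- function(n, border = 10) {
  m <- matrix(0L, n, n)
  m[(border + 1):(n - border), (border + 1):(n - border)] <- 1L
  tissue_mask(m)
}

mlog <- function(m) unclass(m) > 0

inclusion_movie <- function() {
  if (is.null(.fixtures$incl))
    .fixtures$incl <- generate_movie(
      small_cfg(variant = "inclusion", inclusion_radius = 18, seed = 4))
  .fixtures$incl
}

inclusion_pipeline <- function() {
  if (is.null(.fixtures$incl_res))
    .fixtures$incl_res <- suppressWarnings(
      run_pipeline(inclusion_movie()$stack, extents = c(34, 96, 34, 96),
                   n_tiles = c(3, 3)))
  .fixtures$incl_res
}
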