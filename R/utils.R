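# Internal helpers shared across modules.

bt_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "bundletrack_error")))
}

bt_warning <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "bundletrack_warning")))
}

# Run code with a private RNG stream; the global .Random.seed is untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Shift a matrix by (dr, dc) with replicate padding.
img_shift <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# 3x3 convolution with replicate padding (kernel given row-major, centered).
conv3 <- function(m, k) {
  out <- matrix(0, nrow(m), ncol(m))
  for (i in -1:1) for (j in -1:1) {
    w <- k[i + 2, j + 2]
    if (w != 0) out <- out + w * img_shift(m, i, j)
  }
  out
}

sobel_gradients <- function(m) {
  kr <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3, byrow = TRUE)  # d/drow
  kc <- t(kr)                                                        # d/dcol
  list(gr = conv3(m, kr), gc = conv3(m, kc))
}

# Vectorized bilinear sampling of img at sub-pixel (r, c), replicate-clamped.
bilinear_sample <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  r <- pmin(pmax(r, 1), nr)
  c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L)
  c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0
  fc <- c - c0
  i00 <- cbind(r0, c0)
  v00 <- img[i00]
  v01 <- img[cbind(r0, c0 + 1)]
  v10 <- img[cbind(r0 + 1, c0)]
  v11 <- img[cbind(r0 + 1, c0 + 1)]
  (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11)
}

# Largest connected component (8-connectivity) with interior holes filled.
# Idempotent by construction.
largest_component_filled <- function(bin) {
  lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
  lab <- EBImage::imageData(lab)
  if (max(lab) < 1) return(matrix(FALSE, nrow(bin), ncol(bin)))
  areas <- tabulate(lab[lab > 0])
  keep <- which.max(areas)
  comp <- lab == keep
  filled <- EBImage::fillHull(EBImage::Image(comp * 1))
  EBImage::imageData(filled) > 0
}

r2_score <- function(truth, fitted) {
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot <= 0)
    bt_error("coefficient of determination undefined: truth series has zero variance",
             "bt_zero_variance")
  1 - sum((truth - fitted)^2) / ss_tot
}
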