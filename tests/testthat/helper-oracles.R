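# Independent brute-force oracles, deliberately written as literal (slow)
# implementations of the definitions so they share no code with the package.

# Minimum structure-tensor eigenvalue at a pixel, by explicit loops:
# Sobel gradients with replicate padding, tensor summed over a 3x3 block.
oracle_corner_score <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  px <- function(i, j) img[min(max(i, 1), nr), min(max(j, 1), nc)]
  grad <- function(i, j) {
    gr <- (px(i + 1, j - 1) + 2 * px(i + 1, j) + px(i + 1, j + 1)) -
          (px(i - 1, j - 1) + 2 * px(i - 1, j) + px(i - 1, j + 1))
    gc <- (px(i - 1, j + 1) + 2 * px(i, j + 1) + px(i + 1, j + 1)) -
          (px(i - 1, j - 1) + 2 * px(i, j - 1) + px(i + 1, j - 1))
    c(gr, gc)
  }
  a <- 0; b <- 0; d <- 0
  for (i in (r - 1):(r + 1)) for (j in (c - 1):(c + 1)) {
    g <- grad(i, j)
    a <- a + g[1]^2; b <- b + g[1] * g[2]; d <- d + g[2]^2
  }
  a <- a / 9; b <- b / 9; d <- d / 9
  0.5 * ((a + d) - sqrt((a - d)^2 + 4 * b^2))
}

# O(n^2) peak finding with prominence, straight from the definition.
oracle_find_peaks <- function(series, distance = 1, prominence = 0) {
  n <- length(series)
  maxima <- integer(0)
  i <- 2
  while (i < n) {
    if (series[i - 1] < series[i]) {
      j <- i
      while (j < n && series[j + 1] == series[i]) j <- j + 1
      if (j < n && series[j + 1] < series[i]) maxima <- c(maxima, (i + j) %/% 2)
      i <- j
    }
    i <- i + 1
  }
  prom <- sapply(maxima, function(p) {
    h <- series[p]
    left_stop <- 0
    for (j in seq_len(p - 1)) if (series[p - j] > h) { left_stop <- p - j; break }
    lbase <- if (left_stop + 1 <= p - 1) min(series[(left_stop + 1):(p - 1)], h) else h
    right_stop <- n + 1
    if (p < n) for (j in (p + 1):n) if (series[j] > h) { right_stop <- j; break }
    rbase <- if (p + 1 <= right_stop - 1 && right_stop - 1 <= n)
      min(series[(p + 1):(right_stop - 1)], h) else h
    h - max(lbase, rbase)
  })
  if (length(maxima) == 0) return(integer(0))
  keep <- prom >= prominence
  maxima <- maxima[keep]; prom <- prom[keep]
  # distance suppression, highest prominence first
  alive <- rep(TRUE, length(maxima))
  for (k in order(-prom, -series[maxima], maxima)) {
    if (!alive[k]) next
    for (l in seq_along(maxima)) {
      if (l == k || !alive[l]) next
      if (abs(maxima[l] - maxima[k]) < distance &&
          (prom[l] < prom[k] || (prom[l] == prom[k] && l > k)))
        alive[l] <- FALSE
    }
  }
  sort(maxima[alive])
}

# Least-squares deformation gradient by stacking the pair systems into one
# tall design matrix and solving with qr.solve (independent of the normal
# equation used by the package).
oracle_F_lsq <- function(ref, cur) {
  m <- nrow(ref)
  pairs <- t(combn(m, 2))
  A <- matrix(0, 2 * nrow(pairs), 4)
  b <- numeric(2 * nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    v0 <- ref[pairs[k, 1], ] - ref[pairs[k, 2], ]
    v1 <- cur[pairs[k, 1], ] - cur[pairs[k, 2], ]
    A[2 * k - 1, ] <- c(v0[1], v0[2], 0, 0)
    A[2 * k, ]     <- c(0, 0, v0[1], v0[2])
    b[2 * k - 1] <- v1[1]; b[2 * k] <- v1[2]
  }
  matrix(qr.solve(A, b), 2, 2, byrow = TRUE)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)
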