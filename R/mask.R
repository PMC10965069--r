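#' Binary tissue mask
#'
#' A 0/1 matrix of the same shape as the movie frames marking the tissue
#' region over which fiducial markers are detected.
#'
#' @param grid matrix of 0/1 (or logical) values.
#' @return An object of class `tissue_mask` (integer 0/1 matrix).
#' @export
tissue_mask <- function(grid) {
  if (is.logical(grid)) grid <- grid * 1L
  if (!is.matrix(grid) || !all(grid %in% c(0, 1)))
    bt_error("mask values must be 0 or 1", "bt_value")
  if (sum(grid) < 1) bt_error("mask has no foreground pixels", "bt_value")
  structure(matrix(as.integer(grid), nrow(grid), ncol(grid)), class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("tissue_mask: %d x %d px, %d foreground pixels\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

mask_logical <- function(mask) unclass(mask) > 0

#' Post-process a binary image to a single tissue domain
#'
#' Keeps the largest 8-connected foreground component and fills its interior
#' holes. The operation is idempotent.
#'
#' @param bin logical or 0/1 matrix.
#' @return A [tissue_mask].
#' @export
postprocess_mask <- function(bin) {
  tissue_mask(largest_component_filled(bin > 0))
}

#' Automatic tissue mask generation
#'
#' Three threshold-based segmentation variants: Otsu's threshold applied to
#' (a) the first frame, (b) the Sobel gradient magnitude of the first frame,
#' or (c) the per-pixel min/max projection across all frames. The foreground
#' polarity is chosen as the side of the threshold whose largest connected
#' component is larger (tissue may be darker or brighter than background),
#' and the result is post-processed with [postprocess_mask()].
#'
#' @param stack a [movie_stack].
#' @param method one of `"threshold"`, `"sobel_threshold"`,
#'   `"projection_threshold"`.
#' @param projection for the projection method, `"min"` or `"max"`.
#' @return A [tissue_mask].
#' @export
generate_mask <- function(stack,
                          method = c("threshold", "sobel_threshold",
                                     "projection_threshold"),
                          projection = c("min", "max")) {
  method <- match.arg(method)
  projection <- match.arg(projection)
  operand <- switch(method,
    threshold = stack$frames[[1]],
    sobel_threshold = {
      g <- sobel_gradients(stack$frames[[1]])
      mag <- sqrt(g$gr^2 + g$gc^2)
      # smooth the gradient magnitude so textured regions threshold as a
      # solid domain rather than a speckle of edges
      EBImage::imageData(EBImage::gblur(EBImage::Image(mag), sigma = 2))
    },
    projection_threshold = {
      acc <- stack$frames[[1]]
      for (f in stack$frames[-1])
        acc <- if (projection == "min") pmin(acc, f) else pmax(acc, f)
      acc
    })
  rng <- range(operand)
  if (diff(rng) <= 0)
    bt_error("degenerate input: image has zero intensity range", "bt_degenerate")
  scaled <- (operand - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  hi <- scaled > thr
  # Foreground polarity: tissue may be darker or brighter than background,
  # but the background is the side whose dominant component is anchored at
  # the image corners. Prefer the side whose largest connected component
  # touches fewer corners; break ties toward the larger component.
  side_score <- function(side) {
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(side * 1)))
    if (max(lab) < 1) return(c(corners = 4, area = 0))
    areas <- tabulate(lab[lab > 0])
    keep <- which.max(areas)
    nr <- nrow(lab); nc <- ncol(lab)
    corners <- sum(c(lab[1, 1], lab[1, nc], lab[nr, 1], lab[nr, nc]) == keep)
    c(corners = corners, area = max(areas))
  }
  s_hi <- side_score(hi); s_lo <- side_score(!hi)
  fg <- if (s_hi["corners"] < s_lo["corners"] ||
            (s_hi["corners"] == s_lo["corners"] &&
             s_hi["area"] >= s_lo["area"])) hi else !hi
  postprocess_mask(fg)
}

#' Read an externally supplied tissue mask
#'
#' Parses a whitespace-delimited text array of 0/1 values (the
#' `tissue_mask.txt` convention: tissue is 1, background is 0).
#'
#' @param path text file path.
#' @param frame_shape expected `c(rows, cols)` of the movie frames.
#' @return A [tissue_mask].
#' @export
load_external_mask <- function(path, frame_shape) {
  rows <- readLines(path)
  rows <- rows[nzchar(trimws(rows))]
  vals <- lapply(strsplit(trimws(rows), "\\s+"), as.numeric)
  if (length(unique(lengths(vals))) != 1)
    bt_error("ragged mask rows", "bt_shape")
  m <- do.call(rbind, vals)
  if (!identical(dim(m), as.integer(frame_shape)))
    bt_error(sprintf("mask shape %d x %d does not match frame shape %d x %d",
                     nrow(m), ncol(m), frame_shape[1], frame_shape[2]),
             "bt_shape")
  if (!all(m %in% c(0, 1)) || anyNA(m))
    bt_error("mask values must be 0 or 1", "bt_value")
  tissue_mask(m)
}

#' Write a tissue mask as whitespace-delimited 0/1 text
#'
#' Inverse of [load_external_mask()].
#'
#' @param mask a [tissue_mask].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_external_mask <- function(mask, path) {
  write.table(unclass(mask), path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Principal axis of the tissue mask
#'
#' Center of rotation and in-plane long axis of the tissue, computed from
#' the second central moments of the foreground pixel coordinates. The axis
#' is the eigenvector of the larger eigenvalue, sign-fixed to a non-negative
#' column component. Nearly isotropic masks (relative eigenvalue gap below
#' `tol`) fall back to the image horizontal with a warning.
#'
#' @param mask a [tissue_mask].
#' @param tol relative eigenvalue-gap tolerance for the isotropic fallback.
#' @return A [rotation_spec].
#' @export
mask_principal_axis <- function(mask, tol = 1e-3) {
  idx <- which(mask_logical(mask), arr.ind = TRUE)
  center <- colMeans(idx)
  d <- sweep(idx, 2, center)
  cov <- crossprod(d) / nrow(d)
  e <- eigen(cov, symmetric = TRUE)
  if ((e$values[1] - e$values[2]) <= tol * max(e$values[1], .Machine$double.eps)) {
    bt_warning("mask is nearly isotropic; falling back to the image horizontal axis",
               "bt_isotropic_mask")
    axis <- c(0, 1)
  } else {
    axis <- e$vectors[, 1]
    if (axis[2] < 0) axis <- -axis
    if (axis[2] == 0 && axis[1] < 0) axis <- -axis
  }
  rotation_spec(center = unname(center), axis = unname(axis))
}
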