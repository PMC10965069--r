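#' Pillar specification
#'
#' Geometry and stiffness of one support pillar (post), plus the tissue
#' cross-section used for stress. Supply either a direct spring constant
#' `stiffness` (uN/um) or the cantilever beam parameters, from which
#' `k = 3 E I / L^3` with `I = w t^3 / 12` (end-loaded rectangular beam).
#' `stiffness_factor` is an optional multiplicative correction (spherical
#' caps, load height), default 1.
#'
#' @param region_mask a [tissue_mask] over the pillar head (optional; only
#'   needed for [track_pillar()]).
#' @param stiffness spring constant in uN/um, or `NULL`.
#' @param elastic_modulus beam elastic modulus in Pa.
#' @param length beam length in um.
#' @param width beam cross-section width in um.
#' @param thickness beam cross-section thickness in um (bending direction).
#' @param tissue_width,tissue_depth tissue cross-section in um (for
#'   stress); `tissue_depth` has no default and must be supplied for
#'   stress output.
#' @param stiffness_factor multiplicative stiffness correction.
#' @return An object of class `pillar_spec`.
#' @export
pillar_spec <- function(region_mask = NULL, stiffness = NULL,
                        elastic_modulus = NULL, length = NULL, width = NULL,
                        thickness = NULL, tissue_width = NULL,
                        tissue_depth = NULL, stiffness_factor = 1) {
  beam <- list(elastic_modulus, length, width, thickness)
  has_beam <- all(!vapply(beam, is.null, logical(1)))
  any_beam <- any(!vapply(beam, is.null, logical(1)))
  if (is.null(stiffness) && !has_beam)
    bt_error("supply either stiffness or the full beam geometry (elastic_modulus, length, width, thickness)",
             "bt_spec")
  if (!is.null(stiffness) && any_beam)
    bt_error("supply stiffness or beam geometry, not both", "bt_spec")
  geom <- c(stiffness, elastic_modulus, length, width, thickness,
            tissue_width, tissue_depth)
  if (any(geom <= 0)) bt_error("all geometry must be positive", "bt_spec")
  structure(list(region_mask = region_mask, stiffness = stiffness,
                 elastic_modulus = elastic_modulus, length = length,
                 width = width, thickness = thickness,
                 tissue_width = tissue_width, tissue_depth = tissue_depth,
                 stiffness_factor = stiffness_factor),
            class = "pillar_spec")
}

pillar_stiffness <- function(spec) {
  k <- if (!is.null(spec$stiffness)) spec$stiffness else {
    I_um4 <- spec$width * spec$thickness^3 / 12
    # E [Pa] * I [um^4] / L^3 [um^3] = 1e-6 uN/um
    3 * spec$elastic_modulus * I_um4 / spec$length^3 * 1e-6
  }
  k * spec$stiffness_factor
}

#' Track a pillar region
#'
#' Reuses the feature-detection and optical-flow machinery with the pillar
#' head as the tracked region. Returns the mean absolute displacement
#' series plus directional (row/col) mean displacement series, in pixels,
#' and in micrometers when `scale` is given.
#'
#' @param stack a [movie_stack].
#' @param spec a [pillar_spec] with a `region_mask`.
#' @param scale micrometers per pixel, or `NULL` (falls back to
#'   `stack$scale`).
#' @return List with `abs`, `row`, `col` per-frame series (pixels) and,
#'   when a scale is available, `abs_um`, `row_um`, `col_um`.
#' @export
track_pillar <- function(stack, spec, scale = NULL) {
  if (is.null(spec$region_mask)) bt_error("pillar spec has no region mask", "bt_spec")
  if (is.null(scale)) scale <- stack$scale
  tuned <- tune_feature_params(stack$frames[[1]], spec$region_mask)
  markers <- detect_features(stack$frames[[1]], spec$region_mask, tuned$params)
  tw <- tune_window_size(stack, markers, tuned$params)
  traj <- tw$traj
  r <- traj$row[traj$valid, , drop = FALSE]
  c_ <- traj$col[traj$valid, , drop = FALSE]
  out <- list(abs = colMeans(sqrt((r - r[, 1])^2 + (c_ - c_[, 1])^2)),
              row = colMeans(r - r[, 1]),
              col = colMeans(c_ - c_[, 1]))
  if (!is.null(scale)) {
    out$abs_um <- out$abs * scale
    out$row_um <- out$row * scale
    out$col_um <- out$col * scale
  }
  out
}

#' Convert pillar deflection to force
#'
#' `F = k * delta` with the spring constant from the spec (direct or
#' cantilever-beam derived). Force is linear in displacement.
#'
#' @param displacement deflection series in micrometers.
#' @param spec a [pillar_spec].
#' @return Force series in micronewtons.
#' @export
pillar_force <- function(displacement, spec) {
  pillar_stiffness(spec) * displacement
}

#' Convert pillar force to tissue stress
#'
#' Stress = force / (tissue width x tissue depth), reported in kPa
#' (1 uN/um^2 = 1 MPa).
#'
#' @param force force series in micronewtons.
#' @param spec a [pillar_spec] with `tissue_width` and `tissue_depth`.
#' @return Stress series in kilopascals.
#' @export
tissue_stress <- function(force, spec) {
  if (is.null(spec$tissue_width) || is.null(spec$tissue_depth))
    bt_error("tissue_width and tissue_depth are required for stress", "bt_spec")
  force / (spec$tissue_width * spec$tissue_depth) * 1e3
}
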