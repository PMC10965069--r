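# Evaluation of tracked output against synthetic ground truth.

#' Per-beat tracked vs. truth mean-absolute-displacement series
#'
#' For every beat, tracked marker displacements (relative to the beat's
#' first frame) are interpolated onto a structured lattice covering the
#' truth evaluation window and reduced to a mean absolute displacement
#' series; the analytic truth field is evaluated on the same lattice with
#' the same per-beat reference. The pair of per-beat series is then scored
#' with [validation_compare()].
#'
#' @param traj a [marker_traj] over the whole movie.
#' @param seg a [segment_beats()] result.
#' @param truth a `synthetic_truth`.
#' @param spacing lattice spacing in pixels (default 3).
#' @param margin markers this far outside the window still support the
#'   interpolation (default 15 px).
#' @return List with `tracked_beats`, `truth_beats` (lists of series) and
#'   `comparison` (see [validation_compare()]).
#' @export
evaluate_displacement <- function(traj, seg, truth, spacing = 3, margin = 15) {
  w <- truth$window
  lattice <- cbind(row = rep(seq(w[1], w[2], by = spacing),
                             length(seq(w[3], w[4], by = spacing))),
                   col = rep(seq(w[3], w[4], by = spacing),
                             each = length(seq(w[1], w[2], by = spacing))))
  sel <- traj$valid &
    traj$row[, 1] >= w[1] - margin & traj$row[, 1] <= w[2] + margin &
    traj$col[, 1] >= w[3] - margin & traj$col[, 1] <= w[4] + margin
  if (sum(sel) < 3)
    bt_error("too few markers near the evaluation window", "bt_geometry")
  r <- traj$row[sel, , drop = FALSE]
  c_ <- traj$col[sel, , drop = FALSE]
  tracked_beats <- list(); truth_beats <- list()
  for (k in seq_len(nrow(seg$beats))) {
    idx <- seg$beats[k, "start"]:seg$beats[k, "end"]
    ref <- idx[1]
    pos_ref <- cbind(r[, ref], c_[, ref])
    u_ref <- truth$field(lattice, ref - 1)
    tr <- numeric(length(idx)); th <- numeric(length(idx))
    for (f in seq_along(idx)) {
      j <- idx[f]
      disp <- cbind(r[, j] - r[, ref], c_[, j] - c_[, ref])
      ui <- interpolate_displacements(pos_ref, disp, lattice)$displacements
      tr[f] <- mean(sqrt(ui[, 1]^2 + ui[, 2]^2))
      ut <- truth$field(lattice, j - 1) - u_ref
      th[f] <- mean(sqrt(ut[, 1]^2 + ut[, 2]^2))
    }
    tracked_beats[[k]] <- tr
    truth_beats[[k]] <- th
  }
  list(tracked_beats = tracked_beats, truth_beats = truth_beats,
       comparison = validation_compare(tracked_beats, truth_beats))
}

#' Per-tile tracked vs. truth Green-Lagrange strain series
#'
#' Tracked per-tile E_cc series come from [subdomain_strain_series()] on
#' the per-beat trajectories; truth series are computed from the analytic
#' field through the same pairwise least-squares operators
#' ([compute_F_avg()], [green_lagrange()]) applied to a dense point
#' lattice inside each tile, with the same per-beat reference frame.
#'
#' @inheritParams evaluate_displacement
#' @param grid a subdomain grid from [define_subdomains()]; default 2 x 2
#'   tiling of the truth
#'   evaluation window.
#' @param spacing truth lattice spacing in pixels (default 3).
#' @return List with `per_tile` (data frame: beat, tile, r2,
#'   tracked_peak, truth_peak) and `min_r2`.
#' @export
evaluate_strain <- function(traj, seg, truth, grid = NULL, spacing = 3) {
  if (is.null(grid))
    grid <- define_subdomains(extents = truth$window, n_tiles = c(2, 2))
  beats <- split_per_beat(traj, seg)
  rows <- list()
  for (k in seq_along(beats)) {
    bt <- beats[[k]]
    frames <- attr(bt, "frames")
    ss <- subdomain_strain_series(bt, grid)
    for (lab in names(ss$E)) {
      tl <- grid$tiles[grid$tiles$label == lab, ]
      X <- cbind(row = rep(seq(tl$row_min, tl$row_max, by = spacing),
                           length(seq(tl$col_min, tl$col_max, by = spacing))),
                 col = rep(seq(tl$col_min, tl$col_max, by = spacing),
                           each = length(seq(tl$row_min, tl$row_max, by = spacing))))
      p_ref <- X + truth$field(X, frames[1] - 1)
      th <- vapply(seq_along(frames), function(f) {
        p_cur <- X + truth$field(X, frames[f] - 1)
        green_lagrange(compute_F_avg(p_ref, p_cur))[2, 2]
      }, numeric(1))
      tr <- ss$E_cc[, lab]
      rows[[length(rows) + 1]] <-
        data.frame(beat = k, tile = lab, r2 = r2_score(th, tr),
                   tracked_peak = tr[which.max(abs(tr))],
                   truth_peak = th[which.max(abs(th))])
    }
  }
  per_tile <- do.call(rbind, rows)
  list(per_tile = per_tile, min_r2 = min(per_tile$r2))
}
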