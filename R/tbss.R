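# Voxel-skeleton comparator implementing TBSS-style projection semantics:
# skeletonization of a mean FA map, per-voxel search direction given by
# the direction of maximum FA change in the local 3x3x3 neighbourhood,
# maximum-FA projection, and stopping governed by the skeleton distance
# map (a step stops once it would move closer to a different skeleton
# voxel). This is an emulation of those semantics for method comparison,
# not a port of the reference implementation.

#' Skeletonize a mean FA map
#'
#' A voxel joins the skeleton iff its mean FA is at or above `fa_floor`
#' and is a strict local maximum along its search direction (one voxel
#' either way); the search direction is the lattice direction of maximum
#' FA change within the 3x3x3 neighbourhood.
#'
#' @param mean_fa a [scalar_volume()] of group-mean FA in `[0, 1]`.
#' @param fa_floor skeleton inclusion threshold; no population-specific
#'   default is assumed, set it explicitly for your cohort.
#' @return A `voxel_skeleton`: list with `dims`, `affine`, `voxels`
#'   (N x 3, 0-based), `offsets` (N x 3 integer lattice search offsets)
#'   and `directions` (N x 3 unit world vectors).
#' @export
fa_skeletonize <- function(mean_fa, fa_floor = 0.2) {
  stopifnot(inherits(mean_fa, "scalar_volume"))
  FA <- mean_fa$values
  d <- mean_fa$dims
  offs <- neighbor_offsets_26()
  # Keep one representative per +/- pair.
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
                 (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), ,
               drop = FALSE]
  # Axis directions first so exact ties resolve to the shortest step.
  offs <- offs[order(rowSums(abs(offs))), , drop = FALSE]
  best_score <- array(-Inf, dim = d)
  best_drop <- array(-Inf, dim = d)
  best_off <- array(0L, dim = c(d, 3))
  tol <- 1e-12
  for (i in seq_len(nrow(offs))) {
    o <- offs[i, ]
    fp <- shift_array(FA, -o)  # FA at v + o
    fm <- shift_array(FA, o)   # FA at v - o
    score <- abs(fp - fm)
    drop <- FA - pmax(fp, fm)  # ridge curvature along this direction
    # Direction of maximum change; exact ties (e.g. at a symmetric ridge,
    # where the central difference vanishes) resolved toward the direction
    # of steepest two-sided descent.
    upd <- (score > best_score + tol) |
      (score > best_score - tol & drop > best_drop + tol)
    best_score[upd] <- score[upd]
    best_drop[upd] <- drop[upd]
    for (k in 1:3) {
      sl <- best_off[, , , k]
      sl[upd] <- o[k]
      best_off[, , , k] <- sl
    }
  }
  member <- (FA >= fa_floor) & (best_drop > 0)
  lin <- which(member)
  if (length(lin) == 0L) {
    ts_warn("FA skeletonization produced an empty skeleton")
  }
  idx0 <- lin - 1L
  vox <- cbind(idx0 %% d[1], (idx0 %/% d[1]) %% d[2], idx0 %/% (d[1] * d[2]))
  off_sel <- cbind(best_off[, , , 1][lin], best_off[, , , 2][lin],
                   best_off[, , , 3][lin])
  dirs <- unit_rows(t(mean_fa$affine[1:3, 1:3] %*% t(off_sel)))
  structure(list(dims = d, affine = mean_fa$affine, voxels = vox,
                 offsets = off_sel, directions = dirs,
                 fa_floor = fa_floor),
            class = "voxel_skeleton")
}

#' @export
print.voxel_skeleton <- function(x, ...) {
  cat(sprintf("<voxel_skeleton> %d voxels on a %s grid\n",
              nrow(x$voxels), paste(x$dims, collapse = "x")))
  invisible(x)
}

#' Project a subject FA map onto a voxel skeleton, TBSS-style
#'
#' For each skeleton voxel the maximum subject FA is taken stepping one
#' voxel at a time along the search direction (both ways), stopping when a
#' step would land closer to a different skeleton voxel than to the one
#' being projected onto, or once the path exceeds `max_search_mm`.
#'
#' @param subject_fa a [scalar_volume()] on the skeleton grid.
#' @param vs a `voxel_skeleton` from [fa_skeletonize()].
#' @param max_search_mm search cap along the direction, mm.
#' @return Numeric vector of projected values, one per skeleton voxel.
#' @export
tbss_project <- function(subject_fa, vs, max_search_mm = 10) {
  stopifnot(inherits(subject_fa, "scalar_volume"),
            inherits(vs, "voxel_skeleton"))
  if (!all(subject_fa$dims == vs$dims) ||
      max(abs(subject_fa$affine - vs$affine)) > 1e-4) {
    ts_stop("validation_error", "subject volume and skeleton grids differ")
  }
  FA <- subject_fa$values
  n <- nrow(vs$voxels)
  skel_w <- voxel_to_world(vs$voxels, vs$affine)
  A3 <- vs$affine[1:3, 1:3]
  step_mm <- sqrt(rowSums((vs$offsets %*% t(A3))^2))
  out <- numeric(n)
  for (i in seq_len(n)) {
    v <- vs$voxels[i, ]
    o <- vs$offsets[i, ]
    m <- if (step_mm[i] > 0) floor(max_search_mm / step_mm[i]) else 0L
    cand <- v
    for (sgn in c(1, -1)) {
      for (j in seq_len(m)) {
        vv <- v + sgn * j * o
        if (any(vv < 0) || any(vv > vs$dims - 1)) break
        pw <- voxel_to_world(vv, vs$affine)
        d2 <- rowSums(sweep(skel_w, 2, as.numeric(pw))^2)
        if (which.min(d2) != i && d2[i] > min(d2) + 1e-9) break
        cand <- rbind(cand, vv)
      }
    }
    out[i] <- max(FA[voxel_linear_index(rbind_points(cand), vs$dims)])
  }
  out
}

#' Label skeleton voxels belonging to a tract
#'
#' Returns the subset of skeleton voxels whose center lies inside the
#' tract mask — the skeleton-labeling step that makes a whole-WM voxel
#' skeleton tract-specific.
#'
#' @param vs a `voxel_skeleton`.
#' @param tract_mask a [binary_mask()] on the same grid.
#' @return Integer indices into `vs$voxels` of the labeled voxels; empty
#'   (with a warning) if the tract does not touch the skeleton.
#' @export
label_skeleton_by_tract <- function(vs, tract_mask) {
  stopifnot(inherits(vs, "voxel_skeleton"), inherits(tract_mask, "binary_mask"))
  if (!all(vs$dims == tract_mask$dims) ||
      max(abs(vs$affine - tract_mask$affine)) > 1e-4) {
    ts_stop("validation_error", "skeleton and tract mask grids differ")
  }
  inside <- tract_mask$values[voxel_linear_index(vs$voxels, vs$dims)] > 0
  if (!any(inside)) {
    ts_warn("tract mask does not overlap the skeleton")
  }
  which(inside)
}
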