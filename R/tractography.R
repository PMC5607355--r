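# Deterministic FACT tractography and ROI-based tract selection.
#
# FACT follows each voxel's principal eigenvector without interpolation:
# within a voxel the path is a straight segment along that voxel's e1,
# entering and leaving through voxel faces found by exact parametric
# ray-box intersection. A 1e-6-voxel nudge across each face prevents
# re-entering the voxel just left.

#' FACT tracking parameters
#'
#' @param fa_threshold minimum FA for seeding and propagation (default 0.1).
#' @param angle_threshold_deg maximum turning angle between successive
#'   segment directions, degrees (default 45).
#' @param max_steps per-direction cap on face-to-face steps.
#' @return A `tracking_params` list.
#' @export
tracking_params <- function(fa_threshold = 0.1, angle_threshold_deg = 45,
                            max_steps = 2000L) {
  if (fa_threshold <= 0 || fa_threshold >= 1) {
    ts_stop("validation_error", "fa_threshold must be in (0, 1)")
  }
  if (angle_threshold_deg <= 0 || angle_threshold_deg >= 180) {
    ts_stop("validation_error", "angle_threshold_deg must be in (0, 180)")
  }
  structure(list(fa_threshold = fa_threshold,
                 angle_threshold_deg = angle_threshold_deg,
                 max_steps = as.integer(max_steps)),
            class = "tracking_params")
}

#' Construct a tractogram
#'
#' @param streamlines list of numeric matrices (points x 3, world mm), each
#'   with at least 2 points and no repeated consecutive points.
#' @param provenance optional record of how the streamlines were produced.
#' @return A `tractogram` object.
#' @export
tractogram <- function(streamlines = list(), provenance = list()) {
  for (i in seq_along(streamlines)) {
    s <- streamlines[[i]]
    if (!is.matrix(s) || ncol(s) != 3 || nrow(s) < 2) {
      ts_stop("validation_error",
              "streamline %d must be a matrix with >= 2 points x 3", i)
    }
    step <- sqrt(rowSums((s[-1, , drop = FALSE] -
                            s[-nrow(s), , drop = FALSE])^2))
    if (any(step == 0)) {
      ts_stop("validation_error",
              "streamline %d has repeated consecutive points", i)
    }
  }
  structure(list(streamlines = streamlines, provenance = provenance),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  np <- if (length(x$streamlines)) sum(vapply(x$streamlines, nrow, 1L)) else 0L
  cat(sprintf("<tractogram> %d streamlines, %d points\n",
              length(x$streamlines), np))
  invisible(x)
}

#' Whole-volume deterministic FACT tractography
#'
#' Seeds one bidirectional streamline from the center of every voxel with
#' FA at or above the threshold. Propagation follows the current voxel's
#' principal eigenvector to the voxel face and stops when entering a voxel
#' below the FA threshold, when the turning angle exceeds the threshold,
#' on leaving the grid, or after `max_steps`. The eigenvector sign is
#' chosen to minimize turning relative to the incoming direction.
#'
#' @param tv a [tensor_volume()].
#' @param params a [tracking_params()].
#' @return A [tractogram()] in world mm.
#' @export
fact_track <- function(tv, params = tracking_params()) {
  stopifnot(inherits(tv, "tensor_volume"), inherits(params, "tracking_params"))
  d <- tv$dims
  comp <- matrix(tv$tensors, ncol = 6)
  ev <- tensor_eigenvalues(comp)
  fa_flat <- fa_from_eigenvalues(ev)
  fa_flat[rowSums(abs(comp)) == 0] <- 0
  seed_lin <- which(fa_flat >= params$fa_threshold)
  if (length(seed_lin) == 0L) {
    ts_warn("no voxels at or above the FA threshold; empty tractogram")
    return(tractogram(provenance = c(unclass(params), list(n_seeds = 0))))
  }
  # Principal eigenvector per above-threshold voxel (world frame).
  e1 <- matrix(NA_real_, length(fa_flat), 3)
  A3 <- tv$affine[1:3, 1:3]
  for (idx in seed_lin) {
    es <- eigen(as_tensor_matrix(comp[idx, ]), symmetric = TRUE)
    e1[idx, ] <- es$vectors[, 1]
  }
  Ainv3 <- solve(A3)
  cos_thresh <- cos(params$angle_threshold_deg * pi / 180)
  pass <- fa_flat >= params$fa_threshold

  lin_of <- function(v) 1L + v[1] + d[1] * (v[2] + d[2] * v[3])
  track_half <- function(v0, sgn) {
    pts <- list()
    v <- v0
    p <- as.numeric(v0)  # continuous voxel coords
    dir_w <- sgn * e1[lin_of(v0), ]
    steps <- 0L
    repeat {
      dv <- as.numeric(Ainv3 %*% dir_w)
      s_ax <- ifelse(abs(dv) > 1e-12,
                     ((v + 0.5 * sign(dv)) - p) / dv, Inf)
      s <- min(s_ax)
      if (!is.finite(s) || s < 0) break
      p_exit <- p + s * dv
      pts[[length(pts) + 1L]] <- p_exit
      p_next <- p + (s + 1e-6) * dv
      v_next <- round(p_next)
      steps <- steps + 1L
      if (steps >= params$max_steps) break
      if (any(v_next < 0) || any(v_next > d - 1)) break
      lin_next <- lin_of(v_next)
      if (!pass[lin_next]) break
      cand <- e1[lin_next, ]
      dp <- sum(cand * dir_w)
      if (dp < 0) { cand <- -cand; dp <- -dp }
      if (dp < cos_thresh) break
      dir_w <- cand
      v <- v_next
      p <- p_next
    }
    pts
  }

  streamlines <- vector("list", length(seed_lin))
  vox_seed <- cbind((seed_lin - 1L) %% d[1],
                    ((seed_lin - 1L) %/% d[1]) %% d[2],
                    (seed_lin - 1L) %/% (d[1] * d[2]))
  for (i in seq_along(seed_lin)) {
    v0 <- vox_seed[i, ]
    fwd <- track_half(v0, +1)
    bwd <- track_half(v0, -1)
    pts_v <- do.call(rbind, c(rev(bwd), list(as.numeric(v0)), fwd))
    pts_w <- voxel_to_world(pts_v, tv$affine)
    keep <- c(TRUE, rowSums((pts_w[-1, , drop = FALSE] -
                               pts_w[-nrow(pts_w), , drop = FALSE])^2) > 1e-18)
    pts_w <- pts_w[keep, , drop = FALSE]
    streamlines[[i]] <- if (nrow(pts_w) >= 2) pts_w else NULL
  }
  streamlines <- Filter(Negate(is.null), streamlines)
  tractogram(streamlines,
             provenance = c(unclass(params), list(n_seeds = length(seed_lin))))
}

#' Waypoint/exclusion selection rule for streamlines
#'
#' @param waypoint_rois list of [binary_mask()] the streamline must all
#'   intersect (logical AND); at least one required.
#' @param exclusion_rois list of [binary_mask()] the streamline must avoid.
#' @return A `selection_rule` object.
#' @export
selection_rule <- function(waypoint_rois, exclusion_rois = list()) {
  if (inherits(waypoint_rois, "binary_mask")) waypoint_rois <- list(waypoint_rois)
  if (inherits(exclusion_rois, "binary_mask")) exclusion_rois <- list(exclusion_rois)
  if (length(waypoint_rois) == 0L) {
    ts_stop("validation_error", "at least one waypoint ROI is required")
  }
  for (m in c(waypoint_rois, exclusion_rois)) stopifnot(inherits(m, "binary_mask"))
  ref <- waypoint_rois[[1]]
  for (m in c(waypoint_rois[-1], exclusion_rois)) {
    require_same_grid(ref, m, "selection ROIs")
  }
  structure(list(waypoint_rois = waypoint_rois,
                 exclusion_rois = exclusion_rois),
            class = "selection_rule")
}

streamline_hits_mask <- function(s, mask) {
  vox <- round(world_to_voxel(s, mask$affine))
  ok <- in_grid(vox, mask$dims)
  if (!any(ok)) return(FALSE)
  any(mask$values[voxel_linear_index(vox[ok, , drop = FALSE], mask$dims)] > 0)
}

#' Filter streamlines by waypoint and exclusion ROIs
#'
#' A streamline is kept iff it intersects every waypoint ROI and no
#' exclusion ROI; intersection means any streamline point falls in a mask
#' voxel.
#'
#' @param tg a [tractogram()].
#' @param rule a [selection_rule()].
#' @return The filtered [tractogram()].
#' @export
select_streamlines <- function(tg, rule) {
  stopifnot(inherits(tg, "tractogram"), inherits(rule, "selection_rule"))
  keep <- vapply(tg$streamlines, function(s) {
    for (m in rule$waypoint_rois) {
      if (!streamline_hits_mask(s, m)) return(FALSE)
    }
    for (m in rule$exclusion_rois) {
      if (streamline_hits_mask(s, m)) return(FALSE)
    }
    TRUE
  }, logical(1))
  tractogram(tg$streamlines[keep], provenance = tg$provenance)
}

densify_streamline <- function(s, max_step) {
  seg <- s[-1, , drop = FALSE] - s[-nrow(s), , drop = FALSE]
  len <- sqrt(rowSums(seg^2))
  out <- list(s[1, , drop = FALSE])
  for (i in seq_len(nrow(seg))) {
    n <- max(1L, ceiling(len[i] / max_step))
    tt <- seq_len(n) / n
    out[[i + 1L]] <- s[rep(i, n), , drop = FALSE] + outer(tt, seg[i, ])
  }
  do.call(rbind, out)
}

#' Rasterize a tractogram into a binary mask
#'
#' Streamlines are densified to at most half-voxel point spacing before
#' rasterization; a voxel is set iff at least one point falls in it.
#'
#' @param tg a [tractogram()].
#' @param dims grid size.
#' @param affine 4x4 voxel-to-world matrix of the target grid.
#' @return A [binary_mask()].
#' @export
tract_mask <- function(tg, dims, affine = diag(4)) {
  stopifnot(inherits(tg, "tractogram"))
  dims <- check_dims(dims)
  arr <- array(0L, dim = dims)
  if (length(tg$streamlines) == 0L) {
    ts_warn("empty tractogram; returning an all-zero mask")
    return(binary_mask(arr, affine))
  }
  max_step <- min(voxel_sizes(affine)) / 2
  for (s in tg$streamlines) {
    pts <- densify_streamline(s, max_step)
    vox <- round(world_to_voxel(pts, affine))
    ok <- in_grid(vox, dims)
    if (any(ok)) {
      arr[unique(voxel_linear_index(vox[ok, , drop = FALSE], dims))] <- 1L
    }
  }
  binary_mask(arr, affine)
}

#' Signal-to-noise ratio of a region of interest
#'
#' SNR is the mean signal divided by the sample standard deviation over the
#' ROI voxels, as used on a b=0 volume with a small ROI in homogeneous
#' white matter.
#'
#' @param b0 a [scalar_volume()] of signal intensities.
#' @param roi a [binary_mask()] on the same grid with at least 2 voxels.
#' @return SNR (dimensionless); `Inf` with a warning if the ROI is
#'   constant.
#' @export
snr_estimate <- function(b0, roi) {
  stopifnot(inherits(b0, "scalar_volume"), inherits(roi, "binary_mask"))
  require_same_grid(b0, roi)
  vals <- b0$values[roi$values > 0]
  if (length(vals) < 2) {
    ts_stop("validation_error", "ROI must contain at least 2 voxels")
  }
  s <- stats::sd(vals)
  if (s == 0) {
    ts_warn("ROI is constant; SNR is infinite")
    return(Inf)
  }
  mean(vals) / s
}
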