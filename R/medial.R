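# Discrete medial-surface models of sheet-like tracts.
#
# The skeleton is built from the binary tract mask: Euclidean distance
# transform -> medial-ridge voxel detection (local maxima of the distance
# transform along the sheet's thin axis) -> height-field triangulation over
# the ridge point cloud -> Laplacian smoothing. The radius function R is
# the distance transform sampled at the vertices, so each vertex plus or
# minus R times its normal lies on the tract boundary.

#' Construct a medial surface
#'
#' @param vertices V x 3 matrix of world-mm points.
#' @param triangles T x 3 integer matrix of 1-based vertex indices.
#' @param normals V x 3 matrix of unit per-vertex normals (across the
#'   sheet's thin direction).
#' @param radius length-V positive radius function, mm: the radius of the
#'   maximal inscribed sphere centred at each vertex.
#' @return A `medial_surface` object.
#' @export
medial_surface <- function(vertices, triangles, normals, radius) {
  vertices <- as.matrix(vertices); normals <- as.matrix(normals)
  triangles <- matrix(as.integer(triangles), ncol = 3)
  nv <- nrow(vertices)
  if (nv == 0L) ts_stop("validation_error", "surface has no vertices")
  stopifnot(ncol(vertices) == 3, nrow(normals) == nv, length(radius) == nv)
  if (any(triangles < 1L) || any(triangles > nv)) {
    ts_stop("validation_error", "triangle indices out of range")
  }
  nn <- sqrt(rowSums(normals^2))
  if (any(abs(nn - 1) > 1e-6)) {
    ts_stop("validation_error", "normals must be unit length")
  }
  if (any(radius <= 0)) {
    ts_stop("validation_error", "radius must be positive at every vertex")
  }
  areas <- triangle_areas(vertices, triangles)
  if (any(areas <= 1e-12)) {
    ts_stop("validation_error", "degenerate (zero-area) triangles: %s",
            paste(which(areas <= 1e-12), collapse = ", "))
  }
  ec <- edge_counts(triangles)
  if (any(ec > 2L)) {
    ts_stop("validation_error",
            "triangulation is not edge-manifold (%d over-shared edges)",
            sum(ec > 2L))
  }
  structure(list(vertices = vertices, triangles = triangles,
                 normals = normals, radius = as.numeric(radius)),
            class = "medial_surface")
}

#' @export
print.medial_surface <- function(x, ...) {
  cat(sprintf("<medial_surface> %d vertices, %d triangles, R in [%.2f, %.2f] mm\n",
              nrow(x$vertices), nrow(x$triangles),
              min(x$radius), max(x$radius)))
  invisible(x)
}

triangle_areas <- function(vertices, triangles) {
  a <- vertices[triangles[, 1], , drop = FALSE]
  b <- vertices[triangles[, 2], , drop = FALSE]
  c_ <- vertices[triangles[, 3], , drop = FALSE]
  u <- b - a; v <- c_ - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  sqrt(rowSums(cr^2)) / 2
}

edge_counts <- function(triangles) {
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  table(key)
}

#' Vertex adjacency list of a surface triangulation
#'
#' @param surface a [medial_surface()].
#' @return A list, one integer vector of neighbor indices per vertex.
#' @export
surface_adjacency <- function(surface) {
  tr <- surface$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  adj <- split(e[, 2], factor(e[, 1], levels = seq_len(nrow(surface$vertices))))
  lapply(adj, function(v) sort(unique(v)))
}

# 1D squared distance transform (Felzenszwalb & Huttenlocher), grid units.
dt1d <- function(f) {
  n <- length(f)
  if (n == 1L) return(f)
  v <- integer(n); z <- numeric(n + 1)
  k <- 1L; v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  for (q in 2:n) {
    repeat {
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
      if (k > 1L && s <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q; z[k] <- s; z[k + 1] <- Inf
  }
  d <- numeric(n); k <- 1L
  for (q in 1:n) {
    while (z[k + 1] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Euclidean distance transform of a binary mask
#'
#' Exact Euclidean distance (mm) from each foreground voxel to the nearest
#' background voxel center, computed with the separable lower-envelope
#' algorithm; anisotropic voxel sizes are honored. Background voxels get 0.
#'
#' @param mask a [binary_mask()].
#' @return A [scalar_volume()] of distances in mm.
#' @export
distance_transform <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  d <- mask$dims
  h <- voxel_sizes(mask$affine)
  BIG <- 1e12
  f <- array(ifelse(mask$values > 0, BIG, 0), dim = d)
  for (ax in 1:3) {
    h2 <- h[ax]^2
    f <- apply_along_axis(f, ax, function(col) dt1d(col / h2) * h2)
  }
  scalar_volume(sqrt(f), mask$affine, metric = "distance_mm")
}

apply_along_axis <- function(arr, ax, fn) {
  d <- dim(arr)
  perm <- c(ax, setdiff(1:3, ax))
  m <- aperm(arr, perm)
  dm <- dim(m)
  m <- matrix(m, nrow = dm[1])
  m <- apply(m, 2, fn)
  m <- array(m, dim = dm)
  aperm(m, order(perm))
}

mask_voxel_coords <- function(mask) {
  idx <- which(mask$values > 0) - 1L
  d <- mask$dims
  cbind(idx %% d[1], (idx %/% d[1]) %% d[2], idx %/% (d[1] * d[2]))
}

# 26-neighborhood integer offsets (excluding the origin).
neighbor_offsets_26 <- function() {
  o <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  o[rowSums(abs(o)) > 0, , drop = FALSE]
}

#' Extract a discrete medial surface from a sheet-like tract mask
#'
#' Medial-ridge voxels are local maxima of the Euclidean distance transform
#' along the sheet's thin axis (the smallest principal axis of the mask
#' voxel cloud, snapped to the nearest lattice direction). The ridge cloud
#' is triangulated as a height field over its tangential plane and
#' Laplacian-smoothed; per-vertex normals come from the mesh and the radius
#' function is the distance transform sampled at each vertex.
#'
#' Tubular or blob-like masks, for which the medial locus degenerates to a
#' curve or point, are rejected: both tangential extents of the ridge cloud
#' must exceed 3 voxels.
#'
#' @param mask a nonempty [binary_mask()] of a sheet-like tract.
#' @param smoothing_mm Laplacian smoothing scale, mm (default 1).
#' @return A [medial_surface()].
#' @export
extract_medial_surface <- function(mask, smoothing_mm = 1) {
  stopifnot(inherits(mask, "binary_mask"))
  if (sum(mask$values) == 0) {
    ts_stop("validation_error", "mask is empty")
  }
  h <- mean(voxel_sizes(mask$affine))
  dtv <- distance_transform(mask)
  D <- dtv$values

  # Global thin axis from PCA of the mask voxel cloud (world mm), used as
  # a fallback where the distance-transform gradient vanishes (at the
  # ridge crest of a symmetric sheet).
  vox <- mask_voxel_coords(mask)
  pts <- voxel_to_world(vox, mask$affine)
  pc <- stats::prcomp(pts, center = TRUE, scale. = FALSE)
  w_axis <- pc$rotation[, 3]

  # Candidate lattice directions: one per +/- pair of the 26-neighborhood.
  offs <- neighbor_offsets_26()
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
                 (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), ,
               drop = FALSE]
  A3 <- mask$affine[1:3, 1:3]
  offs_u <- unit_rows(t(A3 %*% t(offs)))
  w_snap_id <- which.max(abs(offs_u %*% w_axis))
  d <- mask$dims
  hs <- voxel_sizes(mask$affine)

  # Distance-transform gradient (central differences, mm) per voxel.
  gx <- (shift_array(D, c(-1, 0, 0), "edge") -
           shift_array(D, c(1, 0, 0), "edge")) / (2 * hs[1])
  gy <- (shift_array(D, c(0, -1, 0), "edge") -
           shift_array(D, c(0, 1, 0), "edge")) / (2 * hs[2])
  gz <- (shift_array(D, c(0, 0, -1), "edge") -
           shift_array(D, c(0, 0, 1), "edge")) / (2 * hs[3])
  gmat <- cbind(as.vector(gx), as.vector(gy), as.vector(gz))
  gnorm <- sqrt(rowSums(gmat^2))
  axis_id <- max.col(abs(gmat %*% t(offs_u)), ties.method = "first")
  axis_id[gnorm < 1e-9] <- w_snap_id

  # Ridge voxels: local maxima of D along their own (gradient-aligned)
  # axis, with sub-voxel refinement by a 3-point parabolic fit.
  inmask <- mask$values > 0
  ridge <- array(FALSE, dim = d)
  delta <- array(0, dim = d)
  axis_arr <- array(axis_id, dim = d)
  for (ai in seq_len(nrow(offs))) {
    sel <- inmask & (axis_arr == ai)
    if (!any(sel)) next
    o <- offs[ai, ]
    Dp <- shift_array(D, -o)  # value at v + o
    Dm <- shift_array(D, o)   # value at v - o
    is_r <- sel & (D >= Dp) & (D >= Dm)
    ridge[is_r] <- TRUE
    den <- Dm + Dp - 2 * D
    dl <- ifelse(abs(den) > 1e-9, 0.5 * (Dm - Dp) / den, 0)
    delta[is_r] <- pmin(pmax(dl[is_r], -1), 1)
  }
  rvox <- which(ridge)
  if (length(rvox) == 0L) {
    ts_stop("validation_error", "no medial ridge voxels found")
  }
  idx0 <- rvox - 1L
  rv <- cbind(idx0 %% d[1], (idx0 %/% d[1]) %% d[2], idx0 %/% (d[1] * d[2]))
  rv <- rv + delta[rvox] * offs[axis_arr[rvox], , drop = FALSE]
  rpts <- voxel_to_world(rv, mask$affine)

  # Tangential frame and tubularity check on the ridge cloud.
  rpc <- stats::prcomp(rpts, center = TRUE, scale. = FALSE)
  u1 <- rpc$rotation[, 1]; u2 <- rpc$rotation[, 2]; w <- rpc$rotation[, 3]
  ctr <- colMeans(rpts)
  a <- as.numeric((rpts - rep(ctr, each = nrow(rpts))) %*% u1)
  b <- as.numeric((rpts - rep(ctr, each = nrow(rpts))) %*% u2)
  hw <- as.numeric((rpts - rep(ctr, each = nrow(rpts))) %*% w)
  ext1 <- diff(range(a)) / h; ext2 <- diff(range(b)) / h
  if (ext2 <= 3) {
    ts_stop("ill_suited_geometry",
            paste("medial locus degenerates to a curve or point",
                  "(tangential extents %.1f and %.1f voxels); the medial",
                  "surface model is ill-suited to tubular structures"),
            ext1, ext2)
  }

  # Height field: average ridge height per grid node in the (u1, u2)
  # plane; the lattice is anchored at the median coordinate so the bulk
  # of the ridge points falls near node centers (a min anchor would be
  # thrown off by sub-voxel-refined points at the grid border).
  a0 <- a[which.min(abs(a - stats::median(a)))]
  b0 <- b[which.min(abs(b - stats::median(b)))]
  ia <- round((a - a0) / h); ib <- round((b - b0) / h)
  ia <- ia - min(ia) + 1L; ib <- ib - min(ib) + 1L
  na_ <- max(ia); nb_ <- max(ib)
  Hsum <- matrix(0, na_, nb_); Hcnt <- matrix(0L, na_, nb_)
  for (i in seq_along(ia)) {
    Hsum[ia[i], ib[i]] <- Hsum[ia[i], ib[i]] + hw[i]
    Hcnt[ia[i], ib[i]] <- Hcnt[ia[i], ib[i]] + 1L
  }
  H <- ifelse(Hcnt > 0, Hsum / pmax(Hcnt, 1L), NA_real_)
  ia_off <- min(round((a - a0) / h))
  ib_off <- min(round((b - b0) / h))

  # Fill isolated lattice holes (columns the voxel staircase skipped) from
  # their neighbors.
  for (pass in 1:3) {
    miss <- is.na(H)
    if (!any(miss)) break
    nsum <- matrix(0, na_, nb_); ncnt <- matrix(0L, na_, nb_)
    for (da in -1:1) for (db in -1:1) {
      if (da == 0 && db == 0) next
      src_a <- seq_len(na_) + da; src_b <- seq_len(nb_) + db
      ok_a <- src_a >= 1 & src_a <= na_; ok_b <- src_b >= 1 & src_b <= nb_
      nb_mat <- matrix(NA_real_, na_, nb_)
      nb_mat[ok_a, ok_b] <- H[src_a[ok_a], src_b[ok_b]]
      have <- !is.na(nb_mat)
      nsum[have] <- nsum[have] + nb_mat[have]
      ncnt[have] <- ncnt[have] + 1L
    }
    fill <- miss & ncnt >= 5L
    H[fill] <- nsum[fill] / ncnt[fill]
  }

  occ <- which(!is.na(H), arr.ind = TRUE)
  node_id <- matrix(NA_integer_, na_, nb_)
  node_id[occ] <- seq_len(nrow(occ))
  nodes <- data.frame(ia = occ[, 1] + ia_off - 1L,
                      ib = occ[, 2] + ib_off - 1L,
                      h = H[occ])

  # Triangulate complete grid cells (two triangles each).
  tris <- list()
  for (ci in seq_len(na_ - 1)) {
    for (cj in seq_len(nb_ - 1)) {
      p00 <- node_id[ci, cj]; p10 <- node_id[ci + 1, cj]
      p01 <- node_id[ci, cj + 1]; p11 <- node_id[ci + 1, cj + 1]
      if (!is.na(p00) && !is.na(p10) && !is.na(p01) && !is.na(p11)) {
        tris[[length(tris) + 1L]] <- c(p00, p10, p11)
        tris[[length(tris) + 1L]] <- c(p00, p11, p01)
      }
    }
  }
  if (length(tris) == 0L) {
    ts_stop("ill_suited_geometry", "ridge cloud too sparse to triangulate")
  }
  triangles <- do.call(rbind, tris)

  # Laplacian smoothing of the height component only (keeps the tangential
  # lattice regular, so no in-plane shrinkage).
  nv <- nrow(nodes)
  adj <- adjacency_from_triangles(triangles, nv)
  n_iter <- max(1L, round(2 * smoothing_mm / h))
  hh <- nodes$h
  for (it in seq_len(n_iter)) {
    mh <- vapply(seq_len(nv), function(v) {
      nb <- adj[[v]]
      if (length(nb)) mean(hh[nb]) else hh[v]
    }, numeric(1))
    hh <- hh + 0.5 * (mh - hh)
  }

  vertices <- rep(ctr, each = nv) +
    outer(a0 + nodes$ia * h, u1) + outer(b0 + nodes$ib * h, u2) +
    outer(hh, w)

  # Radius from the distance transform; drop vertices that fell outside.
  vvox <- world_to_voxel(vertices, mask$affine)
  radius <- trilinear(D, vvox)
  keep <- radius > 0.25 * h & in_grid(round(vvox), mask$dims)
  if (!all(keep)) {
    remap <- cumsum(keep)
    triangles <- triangles[rowSums(matrix(keep[triangles], ncol = 3)) == 3L, ,
                           drop = FALSE]
    triangles <- matrix(remap[triangles], ncol = 3)
    vertices <- vertices[keep, , drop = FALSE]
    radius <- radius[keep]
  }
  if (nrow(triangles) == 0L || nrow(vertices) < 3L) {
    ts_stop("ill_suited_geometry", "no valid medial surface after pruning")
  }
  # Drop vertices referenced by no triangle.
  used <- sort(unique(as.integer(triangles)))
  if (length(used) < nrow(vertices)) {
    remap <- integer(nrow(vertices)); remap[used] <- seq_along(used)
    vertices <- vertices[used, , drop = FALSE]
    radius <- radius[used]
    triangles <- matrix(remap[triangles], ncol = 3)
  }
  normals <- vertex_normals(vertices, triangles, orient = w)
  medial_surface(vertices, triangles, normals, radius)
}

adjacency_from_triangles <- function(triangles, nv) {
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  adj <- split(e[, 2], factor(e[, 1], levels = seq_len(nv)))
  lapply(adj, function(v) sort(unique(v)))
}

vertex_normals <- function(vertices, triangles, orient = NULL) {
  a <- vertices[triangles[, 1], , drop = FALSE]
  b <- vertices[triangles[, 2], , drop = FALSE]
  c_ <- vertices[triangles[, 3], , drop = FALSE]
  u <- b - a; v <- c_ - a
  fn <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])  # area-weighted
  nv <- nrow(vertices)
  vn <- matrix(0, nv, 3)
  idx <- factor(c(triangles[, 1], triangles[, 2], triangles[, 3]),
                levels = seq_len(nv))
  for (k in 1:3) {
    acc <- tapply(rep(fn[, k], 3), idx, sum)
    vn[, k] <- ifelse(is.na(acc), 0, acc)
  }
  vn <- unit_rows(vn)
  if (!is.null(orient)) {
    flip <- as.numeric(vn %*% orient) < 0
    vn[flip, ] <- -vn[flip, ]
  }
  vn
}

#' Boundary offset points of a medial surface
#'
#' By construction `v + R(v) * normal(v)` and `v - R(v) * normal(v)` lie on
#' the tract boundary.
#'
#' @param surface a [medial_surface()].
#' @return A list with `upper` and `lower` V x 3 point matrices (world mm).
#' @export
boundary_offsets <- function(surface) {
  stopifnot(inherits(surface, "medial_surface"))
  list(upper = surface$vertices + surface$radius * surface$normals,
       lower = surface$vertices - surface$radius * surface$normals)
}

#' Fraction of a mask covered by the surface's inscribed balls
#'
#' The fraction of mask voxel centers lying within distance `R(v)` of some
#' vertex `v` — a reconstruction-quality metric for the medial model.
#'
#' @param surface a [medial_surface()].
#' @param mask a [binary_mask()].
#' @return A number in `[0, 1]`.
#' @export
coverage_fraction <- function(surface, mask) {
  stopifnot(inherits(surface, "medial_surface"), inherits(mask, "binary_mask"))
  centers <- voxel_to_world(mask_voxel_coords(mask), mask$affine)
  if (nrow(centers) == 0L) return(0)
  verts <- surface$vertices
  r2 <- surface$radius^2
  covered <- logical(nrow(centers))
  chunk <- max(1L, floor(4e6 / nrow(verts)))
  for (i0 in seq(1L, nrow(centers), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nrow(centers))
    cc <- centers[i0:i1, , drop = FALSE]
    d2 <- outer(rowSums(cc^2), rowSums(verts^2), `+`) -
      2 * cc %*% t(verts)
    covered[i0:i1] <- rowSums(sweep(d2, 2, r2, `<=`)) > 0
  }
  mean(covered)
}
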