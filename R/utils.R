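# Internal helpers shared across modules: affine geometry, interpolation,
# seeded RNG scopes and small validation utilities.

`%||%` <- function(a, b) if (is.null(a)) b else a

ts_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "tractsheet_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

ts_warn <- function(msg, ...) warning(sprintf(msg, ...), call. = FALSE)

check_affine <- function(affine) {
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)) ||
      !all(is.finite(affine))) {
    ts_stop("validation_error", "affine must be a finite 4x4 matrix")
  }
  if (abs(det(affine[1:3, 1:3])) < 1e-12) {
    ts_stop("validation_error", "affine is not invertible (det ~ 0)")
  }
  invisible(affine)
}

check_dims <- function(dims) {
  if (length(dims) != 3L || any(dims < 1L) || any(dims != round(dims))) {
    ts_stop("validation_error", "dims must be 3 positive integers")
  }
  as.integer(dims)
}

# Points are row-per-point matrices; voxel indices are 0-based with voxel
# centers at integer coordinates (NIfTI convention).
voxel_to_world <- function(vox, affine) {
  vox <- rbind_points(vox)
  p <- cbind(vox, 1) %*% t(affine)
  p[, 1:3, drop = FALSE]
}

world_to_voxel <- function(pts, affine) {
  pts <- rbind_points(pts)
  p <- cbind(pts, 1) %*% t(solve(affine))
  p[, 1:3, drop = FALSE]
}

rbind_points <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 3) else x
}

in_grid <- function(vox, dims) {
  vox[, 1] >= 0 & vox[, 1] <= dims[1] - 1 &
    vox[, 2] >= 0 & vox[, 2] <= dims[2] - 1 &
    vox[, 3] >= 0 & vox[, 3] <= dims[3] - 1
}

# Linear index (1-based) into an array of dims for 0-based voxel rows.
voxel_linear_index <- function(vox, dims) {
  1L + vox[, 1] + dims[1] * (vox[, 2] + dims[2] * vox[, 3])
}

voxel_sizes <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

# Trilinear interpolation of a 3D array at continuous 0-based voxel coords.
# Out-of-grid points are clamped to the boundary.
trilinear <- function(arr, vox) {
  d <- dim(arr)
  vox <- rbind_points(vox)
  cl <- function(x, hi) pmin(pmax(x, 0), hi)
  x <- cl(vox[, 1], d[1] - 1); y <- cl(vox[, 2], d[2] - 1); z <- cl(vox[, 3], d[3] - 1)
  x0 <- pmin(floor(x), d[1] - 2); y0 <- pmin(floor(y), d[2] - 2); z0 <- pmin(floor(z), d[3] - 2)
  x0 <- pmax(x0, 0); y0 <- pmax(y0, 0); z0 <- pmax(z0, 0)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  g <- function(i, j, k) arr[cbind(x0 + i + 1, y0 + j + 1, z0 + k + 1)]
  (g(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
     g(1, 0, 0) * fx * (1 - fy) * (1 - fz) +
     g(0, 1, 0) * (1 - fx) * fy * (1 - fz) +
     g(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
     g(1, 1, 0) * fx * fy * (1 - fz) +
     g(1, 0, 1) * fx * (1 - fy) * fz +
     g(0, 1, 1) * (1 - fx) * fy * fz +
     g(1, 1, 1) * fx * fy * fz)
}

# Run code with a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

unit_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  m / pmax(n, .Machine$double.eps)
}

# Connected components of an undirected graph restricted to `members`
# (integer vertex ids), given an adjacency list over all vertices.
# Returns a list of integer vectors.
graph_components <- function(members, adj) {
  if (length(members) == 0L) return(list())
  inset <- logical(length(adj))
  inset[members] <- TRUE
  seen <- logical(length(adj))
  comps <- list()
  for (v in members) {
    if (seen[v]) next
    queue <- v
    seen[v] <- TRUE
    comp <- integer(0)
    while (length(queue)) {
      u <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      comp <- c(comp, u)
      nb <- adj[[u]]
      nb <- nb[inset[nb] & !seen[nb]]
      if (length(nb)) {
        seen[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# Shift a 3D array by an integer voxel offset, padding with `fill`;
# `fill = "edge"` replicates the boundary values instead.
shift_array <- function(arr, off, fill = 0) {
  d <- dim(arr)
  if (identical(fill, "edge")) {
    idx <- lapply(1:3, function(a) pmin(pmax(seq_len(d[a]) - off[a], 1), d[a]))
    return(arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE])
  }
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    o <- off[a]
    if (o >= 0) {
      if (o >= d[a]) return(out)
      src[[a]] <- 1:(d[a] - o); dst[[a]] <- (1 + o):d[a]
    } else {
      if (-o >= d[a]) return(out)
      src[[a]] <- (1 - o):d[a]; dst[[a]] <- 1:(d[a] + o)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}
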