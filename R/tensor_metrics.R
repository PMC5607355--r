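# Eigen-analysis of diffusion tensors and the scalar DTI metrics derived
# from it (FA, MD, AD, RD), plus tensor averaging for the mean-value
# projection strategy.

#' Eigen-decomposition of a symmetric 3x3 diffusion tensor
#'
#' @param tensor symmetric 3x3 matrix, or a length-6 vector of unique
#'   components (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz).
#' @return A list of class `eigensystem` with `values` (descending
#'   eigenvalues, mm^2/s) and `vectors` (columns e1, e2, e3, unit length,
#'   sign canonicalized so the largest-magnitude component is positive).
#' @export
eigensystem <- function(tensor) {
  m <- as_tensor_matrix(tensor)
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m)))) {
    ts_stop("validation_error", "tensor is not symmetric")
  }
  es <- eigen((m + t(m)) / 2, symmetric = TRUE)
  vec <- es$vectors
  for (j in 1:3) {
    k <- which.max(abs(vec[, j]))
    if (vec[k, j] < 0) vec[, j] <- -vec[, j]
  }
  structure(list(values = es$values, vectors = vec), class = "eigensystem")
}

as_tensor_matrix <- function(tensor) {
  if (is.matrix(tensor)) {
    if (!all(dim(tensor) == c(3, 3))) {
      ts_stop("validation_error", "tensor matrix must be 3x3")
    }
    return(tensor)
  }
  if (length(tensor) != 6L) {
    ts_stop("validation_error",
            "tensor must be 3x3 or 6 unique components, got length %d",
            length(tensor))
  }
  matrix(c(tensor[1], tensor[2], tensor[3],
           tensor[2], tensor[4], tensor[5],
           tensor[3], tensor[5], tensor[6]), 3, 3)
}

tensor_components <- function(m) {
  c(m[1, 1], m[1, 2], m[1, 3], m[2, 2], m[2, 3], m[3, 3])
}

eig_values_of <- function(x) {
  if (inherits(x, "eigensystem")) x$values else eigensystem(x)$values
}

#' Fractional anisotropy
#'
#' `FA = sqrt(3/2) * ||lambda - MD|| / ||lambda||`; 0 for an isotropic
#' tensor, approaching 1 as the tensor approaches rank one, invariant
#' under uniform scaling of the eigenvalues.
#'
#' @param es an [eigensystem()], a tensor, or a numeric vector of 3
#'   eigenvalues.
#' @return FA in `[0, 1]` (0 for an all-zero tensor, by convention).
#' @export
fa <- function(es) {
  l <- eigenvalues_arg(es)
  if (all(l == 0)) return(0)
  if (l[1] < 0) ts_warn("negative leading eigenvalue; FA computed as-is")
  m <- mean(l)
  num <- sqrt(sum((l - m)^2))
  den <- sqrt(sum(l^2))
  sqrt(1.5) * num / den
}

#' Mean diffusivity `(l1 + l2 + l3) / 3`
#' @param es an [eigensystem()], tensor, or eigenvalue vector.
#' @return MD in mm^2/s.
#' @export
md <- function(es) mean(eigenvalues_arg(es))

#' Axial diffusivity `l1`
#' @inheritParams md
#' @return AD in mm^2/s.
#' @export
ad <- function(es) eigenvalues_arg(es)[1]

#' Radial diffusivity `(l2 + l3) / 2`
#' @inheritParams md
#' @return RD in mm^2/s.
#' @export
rd <- function(es) mean(eigenvalues_arg(es)[2:3])

eigenvalues_arg <- function(es) {
  if (inherits(es, "eigensystem")) return(es$values)
  if (is.numeric(es) && is.null(dim(es)) && length(es) == 3L) {
    return(sort(es, decreasing = TRUE))
  }
  eig_values_of(es)
}

# Vectorized eigenvalues of many symmetric 3x3 tensors given as an N x 6
# component matrix, via the trigonometric (Cardano) closed form. Returns an
# N x 3 matrix with descending eigenvalues per row.
tensor_eigenvalues <- function(comp) {
  comp <- matrix(comp, ncol = 6)
  a11 <- comp[, 1]; a12 <- comp[, 2]; a13 <- comp[, 3]
  a22 <- comp[, 4]; a23 <- comp[, 5]; a33 <- comp[, 6]
  q <- (a11 + a22 + a33) / 3
  p1 <- a12^2 + a13^2 + a23^2
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(p2 / 6)
  n <- nrow(comp)
  out <- matrix(q, n, 3)
  nz <- p > 0
  if (any(nz)) {
    ip <- 1 / p[nz]
    b11 <- (a11[nz] - q[nz]) * ip; b22 <- (a22[nz] - q[nz]) * ip
    b33 <- (a33[nz] - q[nz]) * ip
    b12 <- a12[nz] * ip; b13 <- a13[nz] * ip; b23 <- a23[nz] * ip
    detb <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(pmax(detb / 2, -1), 1)
    phi <- acos(r) / 3
    l1 <- q[nz] + 2 * p[nz] * cos(phi)
    l3 <- q[nz] + 2 * p[nz] * cos(phi + 2 * pi / 3)
    out[nz, 1] <- l1
    out[nz, 3] <- l3
    out[nz, 2] <- 3 * q[nz] - l1 - l3
  }
  out
}

# Vectorized FA from an N x 3 eigenvalue matrix; all-zero rows give 0.
fa_from_eigenvalues <- function(ev) {
  m <- rowMeans(ev)
  num <- sqrt((ev[, 1] - m)^2 + (ev[, 2] - m)^2 + (ev[, 3] - m)^2)
  den <- sqrt(ev[, 1]^2 + ev[, 2]^2 + ev[, 3]^2)
  out <- ifelse(den > 0, sqrt(1.5) * num / den, 0)
  pmin(pmax(out, 0), 1)
}

metric_from_eigenvalues <- function(ev, metric) {
  switch(metric,
         FA = fa_from_eigenvalues(ev),
         MD = rowMeans(ev),
         AD = ev[, 1],
         RD = (ev[, 2] + ev[, 3]) / 2,
         ts_stop("validation_error", "unknown metric '%s'", metric))
}

#' Compute a scalar DTI metric map from a tensor volume
#'
#' Background voxels (all-zero tensors) map to 0.
#'
#' @param tv a [tensor_volume()].
#' @param metric one of `"FA"`, `"MD"`, `"AD"`, `"RD"`.
#' @return A [scalar_volume()] on the same grid.
#' @export
metric_volume <- function(tv, metric = c("FA", "MD", "AD", "RD")) {
  metric <- match.arg(metric)
  stopifnot(inherits(tv, "tensor_volume"))
  comp <- matrix(tv$tensors, ncol = 6)
  ev <- tensor_eigenvalues(comp)
  vals <- metric_from_eigenvalues(ev, metric)
  bg <- rowSums(abs(comp)) == 0
  vals[bg] <- 0
  scalar_volume(array(vals, dim = tv$dims), tv$affine, metric = metric)
}

#' Average a set of diffusion tensors
#'
#' The log-Euclidean mean (default) averages matrix logarithms and
#' exponentiates back, which avoids the swelling artifact of the Euclidean
#' mean and keeps the result positive definite; eigenvalues are clamped at
#' 1e-12 before the logarithm only.
#'
#' @param tensors list of symmetric 3x3 matrices (or length-6 component
#'   vectors), or an N x 6 matrix of components.
#' @param space `"log_euclidean"` or `"euclidean"`.
#' @return A symmetric 3x3 matrix.
#' @export
mean_tensor <- function(tensors, space = c("log_euclidean", "euclidean")) {
  space <- match.arg(space)
  if (is.matrix(tensors) && ncol(tensors) == 6) {
    tensors <- lapply(seq_len(nrow(tensors)), function(i) tensors[i, ])
  }
  if (length(tensors) == 0L) {
    ts_stop("validation_error", "cannot average an empty list of tensors")
  }
  mats <- lapply(tensors, as_tensor_matrix)
  if (space == "euclidean") {
    return(Reduce(`+`, mats) / length(mats))
  }
  logs <- lapply(mats, function(m) {
    es <- eigen((m + t(m)) / 2, symmetric = TRUE)
    lam <- pmax(es$values, 1e-12)
    es$vectors %*% diag(log(lam)) %*% t(es$vectors)
  })
  lmean <- Reduce(`+`, logs) / length(logs)
  es <- eigen((lmean + t(lmean)) / 2, symmetric = TRUE)
  m <- es$vectors %*% diag(exp(es$values)) %*% t(es$vectors)
  (m + t(m)) / 2
}
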