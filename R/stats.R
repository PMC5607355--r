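# Point-wise linear regression on skeleton maps and permutation-based
# suprathreshold cluster inference with family-wise error rate control.
#
# The permutation scheme is Freedman-Lane: residuals from the nuisance-only
# model are permuted, refitted under the full model, and the maximum
# suprathreshold cluster size over the surface forms the null distribution.

#' Design specification for skeleton regression
#'
#' @param predictor name of the covariate of interest (e.g. `"PMA_scan"`).
#' @param nuisance character vector of nuisance covariate names (e.g.
#'   `"GA_birth"`); must not contain the predictor.
#' @param contrast `"positive"`, `"negative"` or `"two_sided"` — the tail
#'   of the t statistic tested.
#' @return A `design_spec` list.
#' @export
design_spec <- function(predictor, nuisance = character(0),
                        contrast = c("positive", "negative", "two_sided")) {
  contrast <- match.arg(contrast)
  if (predictor %in% nuisance) {
    ts_stop("validation_error", "predictor cannot also be a nuisance covariate")
  }
  structure(list(predictor = predictor, nuisance = nuisance,
                 contrast = contrast),
            class = "design_spec")
}

# Assemble response matrix (subjects x vertices) from a list of skeleton
# maps or a plain matrix; NA marks missing.
maps_matrix <- function(maps) {
  if (is.matrix(maps)) return(maps)
  do.call(rbind, lapply(maps, function(m) {
    v <- m$values
    v[m$missing] <- NA_real_
    v
  }))
}

design_matrix <- function(cohort, design) {
  cols <- c(design$predictor, design$nuisance)
  miss <- setdiff(cols, names(cohort))
  if (length(miss)) {
    ts_stop("validation_error", "cohort table lacks columns: %s",
            paste(miss, collapse = ", "))
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(cohort[, cols, drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    ts_stop("validation_error", "design is rank deficient; collinear: %s",
            paste(bad, collapse = ", "))
  }
  X
}

T_CAP <- 1e6  # sentinel for t statistics with (numerically) zero residual

# Core vectorized OLS: Y is n x V (no NAs), X n x p. Returns list with
# beta (p x V), se, t for the column `j` of interest, df.
ols_tmap <- function(Y, X, j) {
  n <- nrow(X); p <- ncol(X)
  qrX <- qr(X)
  B <- qr.coef(qrX, Y)
  res <- qr.resid(qrX, Y)
  df <- n - p
  sigma2 <- colSums(res^2) / df
  xtxinv_jj <- chol2inv(qr.R(qrX))[j, j]
  se <- sqrt(pmax(sigma2 * xtxinv_jj, 0))
  tt <- B[j, ] / se
  bad <- !is.finite(tt)  # exact fit: 0/0 or beta/0
  tt[bad] <- sign(B[j, ])[bad] * T_CAP
  tt <- pmin(pmax(tt, -T_CAP), T_CAP)
  list(beta = B, se = se, t = tt, df = df)
}

#' Point-wise GLM on skeleton maps
#'
#' Ordinary least squares of each vertex's response on an intercept, the
#' predictor of interest and the nuisance covariates; returns the t
#' statistic of the predictor per vertex. Vertices observed in fewer than
#' `min_frac` of subjects are excluded (`NA`); otherwise the fit uses the
#' subjects with data at that vertex.
#'
#' @param maps list of skeleton maps (see [project_subject()]) in cohort
#'   order, or a subjects x vertices matrix (`NA` = missing).
#' @param cohort cohort `data.frame` (see [read_cohort()]).
#' @param design a [design_spec()].
#' @param min_frac minimum fraction of subjects required per vertex.
#' @return A list with `t`, `beta`, `se` (per vertex, `NA` where excluded),
#'   `df`, `excluded` (logical).
#' @export
fit_glm <- function(maps, cohort, design, min_frac = 0.9) {
  Y <- maps_matrix(maps)
  if (nrow(Y) != nrow(cohort)) {
    ts_stop("validation_error", "need one map per cohort row")
  }
  X <- design_matrix(cohort, design)
  n <- nrow(X); p <- ncol(X)
  if (n < p + 3) {
    ts_stop("validation_error",
            "need at least %d subjects for %d regressors", p + 3, p)
  }
  j <- 2L  # predictor column (after intercept)
  nv <- ncol(Y)
  nobs <- colSums(!is.na(Y))
  excluded <- nobs < max(ceiling(min_frac * n), p + 3)
  tvec <- beta <- se <- rep(NA_real_, nv)
  complete <- !excluded & nobs == n
  if (any(complete)) {
    r <- ols_tmap(Y[, complete, drop = FALSE], X, j)
    tvec[complete] <- r$t; beta[complete] <- r$beta[j, ]; se[complete] <- r$se
  }
  partial <- which(!excluded & nobs < n)
  for (v in partial) {
    okr <- !is.na(Y[, v])
    r <- ols_tmap(Y[okr, v, drop = FALSE], X[okr, , drop = FALSE], j)
    tvec[v] <- r$t; beta[v] <- r$beta[j, ]; se[v] <- r$se
  }
  list(t = tvec, beta = beta, se = se, df = n - p, excluded = excluded)
}

suprathreshold_set <- function(tvec, primary_t, contrast) {
  switch(contrast,
         positive = which(!is.na(tvec) & tvec > primary_t),
         negative = which(!is.na(tvec) & tvec < -primary_t),
         two_sided = which(!is.na(tvec) & abs(tvec) > primary_t))
}

max_cluster_size <- function(tvec, primary_t, contrast, adj) {
  vs <- suprathreshold_set(tvec, primary_t, contrast)
  if (length(vs) == 0L) return(0L)
  max(lengths(graph_components(vs, adj)))
}

#' Permutation-based suprathreshold cluster analysis with FWER correction
#'
#' Observed clusters are connected components (in the surface adjacency
#' graph) of vertices whose t statistic exceeds the cluster-forming
#' threshold. The null distribution is the maximum cluster size over the
#' surface under Freedman-Lane permutation of nuisance-model residuals;
#' the identity permutation is always part of the reference set, so
#' corrected p-values are bounded below by `1 / (n_perm + 1)`.
#'
#' @param maps list of skeleton maps or subjects x vertices matrix.
#' @param cohort cohort `data.frame`.
#' @param design a [design_spec()]; the contrast decides the tested tail.
#' @param adjacency adjacency list from [surface_adjacency()].
#' @param primary_t cluster-forming threshold on t; default is the t value
#'   of uncorrected p = 0.01 at the design's degrees of freedom (one- or
#'   two-tailed per the contrast).
#' @param n_perm number of random permutations (at least 100).
#' @param seed RNG seed for the permutations.
#' @return A `cluster_result`: list with `clusters` (list of vertex index
#'   vectors), `size`, `peak_t`, `corrected_p` per cluster, plus `t`
#'   (per-vertex map), `primary_threshold`, `n_permutations`, `seed`,
#'   `null_max_size`.
#' @export
cluster_permutation_test <- function(maps, cohort, design, adjacency,
                                     primary_t = NULL, n_perm = 1000L,
                                     seed = 1L) {
  if (n_perm < 100L) {
    ts_stop("validation_error", "n_perm must be at least 100")
  }
  Y <- maps_matrix(maps)
  X <- design_matrix(cohort, design)
  n <- nrow(X); p <- ncol(X)
  j <- 2L
  fit <- fit_glm(Y, cohort, design)
  if (is.null(primary_t)) {
    primary_t <- if (design$contrast == "two_sided") {
      stats::qt(1 - 0.005, df = fit$df)
    } else {
      stats::qt(1 - 0.01, df = fit$df)
    }
  }
  usable <- !fit$excluded & colSums(is.na(Y)) == 0
  adj_ok <- length(adjacency) == ncol(Y)
  if (!adj_ok) {
    ts_stop("validation_error",
            "adjacency has %d vertices but maps have %d",
            length(adjacency), ncol(Y))
  }
  tobs <- fit$t
  tobs[!usable] <- NA_real_
  obs_set <- suprathreshold_set(tobs, primary_t, design$contrast)
  clusters <- graph_components(obs_set, adjacency)

  result <- structure(list(clusters = clusters,
                           size = lengths(clusters),
                           peak_t = vapply(clusters, function(cl)
                             max(abs(tobs[cl])), numeric(1)),
                           corrected_p = numeric(length(clusters)),
                           t = tobs,
                           primary_threshold = primary_t,
                           n_permutations = as.integer(n_perm),
                           seed = seed,
                           null_max_size = integer(0)),
                      class = "cluster_result")
  if (length(clusters) == 0L) return(result)

  # Freedman-Lane: permute residuals of the nuisance-only model.
  Yc <- Y[, usable, drop = FALSE]
  Z <- X[, -j, drop = FALSE]
  qrZ <- qr(Z)
  Ez <- qr.resid(qrZ, Yc)
  Fz <- Yc - Ez
  qrX <- qr(X)
  xtxinv_jj <- chol2inv(qr.R(qrX))[j, j]
  df <- n - p
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      pi_ <- sample.int(n)
      Ystar <- Fz + Ez[pi_, , drop = FALSE]
      B <- qr.coef(qrX, Ystar)
      res <- qr.resid(qrX, Ystar)
      sigma2 <- colSums(res^2) / df
      se <- sqrt(pmax(sigma2 * xtxinv_jj, 1e-300))
      tt <- pmin(pmax(B[j, ] / se, -T_CAP), T_CAP)
      tfull <- rep(NA_real_, ncol(Y))
      tfull[usable] <- tt
      max_cluster_size(tfull, primary_t, design$contrast, adjacency)
    }, numeric(1))
  })
  result$null_max_size <- as.integer(null_max)
  result$corrected_p <- vapply(result$size, function(sz) {
    (1 + sum(null_max >= sz)) / (1 + n_perm)
  }, numeric(1))
  result
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d clusters, primary t = %.3f, %d permutations\n",
              length(x$clusters), x$primary_threshold, x$n_permutations))
  if (length(x$clusters)) {
    print(data.frame(size = x$size, peak_t = round(x$peak_t, 3),
                     corrected_p = round(x$corrected_p, 5)))
  }
  invisible(x)
}
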