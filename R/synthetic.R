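# Synthetic tensor phantoms and cohorts. Sheet phantoms emulate the
# geometry TSA targets: a thin, sheet-like tract with principal diffusion
# direction tangent to the sheet and an FA profile peaking at the
# mid-surface. Cohorts emulate a preterm-neonate study population scanned
# around term-equivalent age, with an optional planted linear age effect on
# a patch of skeleton vertices.

#' Specification of a sheet-like tensor phantom
#'
#' The phantom mid-surface is `z = z0 + amplitude * sin(k * x)` in world mm,
#' extruded across the full x-y extent of the grid, with half-thickness
#' `half_thickness_mm` measured along the local surface normal. Tensors are
#' axially symmetric with the principal axis tangent to the sheet; FA falls
#' off quadratically from `peak_fa` at the mid-surface to
#' `peak_fa - falloff * (peak_fa - outside_fa)` at the boundary. Voxels
#' outside the sheet hold near-isotropic tensors at `outside_fa`.
#'
#' @param dims grid size, 3 integers.
#' @param voxel_mm isotropic voxel edge, mm.
#' @param z0_mm mid-surface offset; defaults to the grid z-center.
#' @param amplitude_mm sine amplitude `a` (0 gives a flat slab).
#' @param k_per_mm sine angular frequency (rad/mm).
#' @param half_thickness_mm sheet half-thickness `t`; must be at least 2
#'   voxels.
#' @param peak_fa FA at the mid-surface.
#' @param outside_fa FA of the surround.
#' @param falloff fraction of the FA contrast lost at the boundary, in
#'   `[0, 1)`.
#' @param md_mm2s mean diffusivity everywhere (neonatal-plausible default).
#' @param distractor `NULL`, or `list(offset_mm =, fa =)` planting a
#'   one-voxel-thick high-FA layer `offset_mm` beyond the upper boundary.
#' @param noise_sd additive Gaussian noise SD on each tensor component.
#' @param seed RNG seed for the noise.
#' @return A `sheet_phantom_spec` list.
#' @export
sheet_phantom_spec <- function(dims = c(48, 40, 24), voxel_mm = 2,
                               z0_mm = NULL, amplitude_mm = 0,
                               k_per_mm = 2 * pi / 96,
                               half_thickness_mm = 5,
                               peak_fa = 0.55, outside_fa = 0.05,
                               falloff = 0.3, md_mm2s = 1.2e-3,
                               distractor = NULL, noise_sd = 0,
                               seed = 1L) {
  dims <- check_dims(dims)
  if (is.null(z0_mm)) z0_mm <- (dims[3] - 1) / 2 * voxel_mm
  if (half_thickness_mm < 2 * voxel_mm) {
    ts_stop("validation_error",
            "half thickness must be at least 2 voxels (%g mm)", 2 * voxel_mm)
  }
  if (peak_fa <= outside_fa) {
    ts_stop("validation_error", "peak_fa must exceed outside_fa")
  }
  if (!is.null(distractor)) {
    stopifnot(is.list(distractor), distractor$offset_mm > 0)
  }
  structure(list(dims = dims, voxel_mm = voxel_mm, z0_mm = z0_mm,
                 amplitude_mm = amplitude_mm, k_per_mm = k_per_mm,
                 half_thickness_mm = half_thickness_mm, peak_fa = peak_fa,
                 outside_fa = outside_fa, falloff = falloff,
                 md_mm2s = md_mm2s, distractor = distractor,
                 noise_sd = noise_sd, seed = seed),
            class = "sheet_phantom_spec")
}

# Eigenvalues of an axially symmetric tensor with given FA and MD:
# lambda = MD * (1 + 2 delta, 1 - delta, 1 - delta), delta = FA / sqrt(3 - 2 FA^2).
axial_eigenvalues <- function(fa_target, md_target) {
  delta <- fa_target / sqrt(3 - 2 * fa_target^2)
  cbind(md_target * (1 + 2 * delta), md_target * (1 - delta),
        md_target * (1 - delta))
}

# Components of R diag(l1,l2,l2) R' with principal axis u (unit rows N x 3):
# T = l2 I + (l1 - l2) u u'.
axial_tensor_components <- function(u, l1, l2) {
  cbind(l2 + (l1 - l2) * u[, 1]^2,
        (l1 - l2) * u[, 1] * u[, 2],
        (l1 - l2) * u[, 1] * u[, 3],
        l2 + (l1 - l2) * u[, 2]^2,
        (l1 - l2) * u[, 2] * u[, 3],
        l2 + (l1 - l2) * u[, 3]^2)
}

#' Generate a sheet-like tensor phantom with analytic ground truth
#'
#' @param spec a [sheet_phantom_spec()].
#' @return A list with elements `volume` (a [tensor_volume()]), `mask`
#'   (a [binary_mask()] of the sheet, excluding any distractor), and
#'   `truth`, a list of functions: `mid_z(x)` (mid-surface height),
#'   `normal_at(x)` (unit surface normal), `signed_dist(pts)` (signed
#'   normal distance of world points to the mid-surface, positive above),
#'   `inside(pts)`, and `expected_fa(pts)` (noise-free FA at world points).
#' @export
make_sheet_phantom <- function(spec) {
  stopifnot(inherits(spec, "sheet_phantom_spec"))
  d <- spec$dims; h <- spec$voxel_mm
  affine <- diag(c(h, h, h, 1))
  a <- spec$amplitude_mm; k <- spec$k_per_mm
  z0 <- spec$z0_mm; t <- spec$half_thickness_mm

  mid_z <- function(x) z0 + a * sin(k * x)
  slope <- function(x) a * k * cos(k * x)
  normal_at <- function(x) {
    s <- slope(x)
    unit_rows(cbind(-s, 0, rep(1, length(s))))
  }
  # Signed normal distance: for gentle slopes the vertical offset scaled by
  # cos of the local inclination; exact for a flat slab.
  signed_dist <- function(pts) {
    pts <- rbind_points(pts)
    s <- slope(pts[, 1])
    (pts[, 3] - mid_z(pts[, 1])) / sqrt(1 + s^2)
  }
  inside <- function(pts) abs(signed_dist(pts)) <= t
  fa_at_dist <- function(dist) {
    inside_fa <- spec$peak_fa -
      spec$falloff * (spec$peak_fa - spec$outside_fa) * (dist / t)^2
    ifelse(abs(dist) <= t, inside_fa, spec$outside_fa)
  }
  expected_fa <- function(pts) fa_at_dist(signed_dist(pts))

  vox <- as.matrix(expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1),
                               z = 0:(d[3] - 1)))
  pts <- voxel_to_world(vox, affine)
  dist <- signed_dist(pts)
  fa_vals <- fa_at_dist(dist)
  tangent <- unit_rows(cbind(rep(1, nrow(pts)), 0, slope(pts[, 1])))
  dir <- tangent
  out_idx <- abs(dist) > t
  dir[out_idx, ] <- matrix(rep(c(1, 0, 0), sum(out_idx)),
                           ncol = 3, byrow = TRUE)
  if (!is.null(spec$distractor)) {
    off <- spec$distractor$offset_mm
    in_layer <- dist > t + off - h / 2 & dist <= t + off + h / 2
    fa_vals[in_layer] <- spec$distractor$fa
    dir[in_layer, ] <- tangent[in_layer, ]
  }
  ev <- axial_eigenvalues(fa_vals, spec$md_mm2s)
  comp <- axial_tensor_components(dir, ev[, 1], ev[, 2])
  if (spec$noise_sd > 0) {
    comp <- comp + with_seed(spec$seed,
      matrix(stats::rnorm(length(comp), sd = spec$noise_sd), nrow(comp), 6))
  }
  tensors <- array(comp, dim = c(d, 6))
  mask_arr <- array(as.integer(abs(dist) <= t), dim = d)
  list(volume = tensor_volume(tensors, affine),
       mask = binary_mask(mask_arr, affine),
       truth = list(mid_z = mid_z, normal_at = normal_at,
                    signed_dist = signed_dist, inside = inside,
                    expected_fa = expected_fa,
                    half_thickness_mm = t))
}

#' Specification of a synthetic skeleton-map cohort
#'
#' Ages emulate a preterm cohort scanned at term-equivalent age: gestational
#' age at birth and post-menstrual age at scan are drawn uniformly within
#' the given ranges (weeks). Per-vertex FA is
#' `baseline + beta * (PMA - midrange) * patch + ga_beta * (GA - midrange)
#'  + subject + noise`
#' where `subject ~ N(0, between_sd)` is shared across vertices and
#' `noise ~ N(0, noise_sd)` is vertex-wise.
#'
#' @param n_subjects number of subjects (at least 6).
#' @param ga_range gestational-age-at-birth range, weeks.
#' @param pma_range post-menstrual-age-at-scan range, weeks.
#' @param beta planted FA change per week of PMA on the patch vertices.
#' @param ga_beta optional nuisance FA change per week of GA (all vertices).
#' @param patch_size number of connected vertices carrying the effect.
#' @param baseline_fa mean FA level.
#' @param between_sd between-subject SD (shared across vertices).
#' @param noise_sd vertex-wise noise SD.
#' @param seed RNG seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 48, ga_range = c(24, 32.86),
                        pma_range = c(38.57, 47.14), beta = 0,
                        ga_beta = 0, patch_size = 50, baseline_fa = 0.35,
                        between_sd = 0.02, noise_sd = 0.03, seed = 1L) {
  if (n_subjects < 6) {
    ts_stop("validation_error", "need at least 6 subjects")
  }
  stopifnot(ga_range[1] > 0, pma_range[1] > 0,
            diff(ga_range) >= 0, diff(pma_range) >= 0,
            max(ga_range) < min(pma_range))
  structure(list(n_subjects = as.integer(n_subjects), ga_range = ga_range,
                 pma_range = pma_range, beta = beta, ga_beta = ga_beta,
                 patch_size = as.integer(patch_size),
                 baseline_fa = baseline_fa, between_sd = between_sd,
                 noise_sd = noise_sd, seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic cohort of skeleton maps on a surface
#'
#' The effect patch is a connected set of vertices grown breadth-first from
#' the vertex nearest the surface centroid.
#'
#' @param spec a [cohort_spec()].
#' @param surface a [medial_surface()] providing vertex count and adjacency.
#' @return A list with `cohort` (data.frame: subject_id, GA_birth,
#'   PMA_scan), `maps` (subjects x vertices FA matrix), `patch` (vertex
#'   indices carrying the effect) and `beta`.
#' @export
make_cohort <- function(spec, surface) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(surface, "medial_surface"))
  nv <- nrow(surface$vertices)
  adj <- surface_adjacency(surface)
  ctr <- colMeans(surface$vertices)
  seed_v <- which.min(rowSums(sweep(surface$vertices, 2, ctr)^2))
  patch <- grow_patch(seed_v, adj, min(spec$patch_size, nv))
  with_seed(spec$seed, {
    n <- spec$n_subjects
    pma <- stats::runif(n, spec$pma_range[1], spec$pma_range[2])
    ga <- stats::runif(n, spec$ga_range[1], spec$ga_range[2])
    subj_eff <- stats::rnorm(n, 0, spec$between_sd)
    noise <- matrix(stats::rnorm(n * nv, 0, spec$noise_sd), n, nv)
    maps <- matrix(spec$baseline_fa, n, nv) + subj_eff + noise
    maps <- maps + spec$ga_beta * (ga - mean(spec$ga_range))
    if (spec$beta != 0) {
      maps[, patch] <- maps[, patch] +
        spec$beta * (pma - mean(spec$pma_range))
    }
    cohort <- data.frame(subject_id = sprintf("sub-%03d", seq_len(n)),
                         GA_birth = ga, PMA_scan = pma,
                         stringsAsFactors = FALSE)
    list(cohort = cohort, maps = maps, patch = patch, beta = spec$beta)
  })
}

grow_patch <- function(start, adj, size) {
  seen <- logical(length(adj))
  seen[start] <- TRUE
  queue <- start
  out <- integer(0)
  while (length(queue) && length(out) < size) {
    v <- queue[[1]]; queue <- queue[-1]
    out <- c(out, v)
    nb <- adj[[v]]
    nb <- nb[!seen[nb]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  sort(out)
}
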