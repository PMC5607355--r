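# Shared fixtures, generated in code. Phantom geometry: 2 mm isotropic
# voxels (the acquisition resolution typical of neonatal DTI), sheet
# half-thickness 5 mm.

flat_phantom <- function(dims = c(30, 24, 16), half_thickness_mm = 5, ...) {
  make_sheet_phantom(sheet_phantom_spec(
    dims = dims, voxel_mm = 2, half_thickness_mm = half_thickness_mm, ...))
}

# A small surface + cohort reused by the statistics tests.
small_surface <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- flat_phantom(dims = c(24, 18, 14))
      cache <<- extract_medial_surface(ph$mask)
    }
    cache
  }
})

# Uniform single-direction tensor field.
uniform_field <- function(dims = c(10, 10, 10), dir = c(1, 0, 0),
                          fa_val = 0.8, md_val = 1.2e-3, voxel_mm = 2) {
  ev <- tractsheet:::axial_eigenvalues(fa_val, md_val)
  comp <- tractsheet:::axial_tensor_components(matrix(dir / sqrt(sum(dir^2)),
                                                      1), ev[1], ev[2])
  arr <- array(0, dim = c(dims, 6))
  for (k in 1:6) arr[, , , k] <- comp[k]
  tensor_volume(arr, diag(c(voxel_mm, voxel_mm, voxel_mm, 1)))
}

# Two blocks with a 90-degree orientation change at x = dims[1]/2.
interface_field <- function(dims = c(12, 8, 8), voxel_mm = 2) {
  ev <- tractsheet:::axial_eigenvalues(0.8, 1.2e-3)
  cx <- tractsheet:::axial_tensor_components(matrix(c(1, 0, 0), 1),
                                             ev[1], ev[2])
  cz <- tractsheet:::axial_tensor_components(matrix(c(0, 0, 1), 1),
                                             ev[1], ev[2])
  arr <- array(0, dim = c(dims, 6))
  half <- dims[1] %/% 2
  for (k in 1:6) {
    arr[1:half, , , k] <- cx[k]
    arr[(half + 1):dims[1], , , k] <- cz[k]
  }
  list(tv = tensor_volume(arr, diag(c(voxel_mm, voxel_mm, voxel_mm, 1))),
       half = half)
}

random_spd_tensor <- function(scale = 1e-3) {
  a <- matrix(stats::rnorm(9), 3, 3)
  s <- crossprod(a) * scale + diag(3) * 1e-6 * scale
  tractsheet:::tensor_components(s)
}

random_symmetric_tensor <- function(scale = 1e-3) {
  m <- matrix(stats::rnorm(9), 3, 3) * scale
  tractsheet:::tensor_components((m + t(m)) / 2)
}

block_mask <- function(dims, xr, yr, zr, affine = diag(c(2, 2, 2, 1))) {
  arr <- array(0L, dim = dims)
  arr[xr, yr, zr] <- 1L
  binary_mask(arr, affine)
}
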