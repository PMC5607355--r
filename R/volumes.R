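# Domain containers for gridded data and their NIfTI readers/writers.
#
# All volumes share the same layout: a 3D grid with 0-based voxel indices,
# voxel centers at integer indices, and a 4x4 voxel-to-world affine in mm.
# Tensor volumes store the 6 unique components of the symmetric diffusion
# tensor per voxel in lower-triangle row order (Dxx, Dxy, Dxz, Dyy, Dyz,
# Dzz), units mm^2/s.

TENSOR_COMPONENTS <- c("Dxx", "Dxy", "Dxz", "Dyy", "Dyz", "Dzz")

#' Construct a diffusion tensor volume
#'
#' @param tensors 4D numeric array `dims x 6`, the unique tensor components
#'   per voxel in the order Dxx, Dxy, Dxz, Dyy, Dyz, Dzz (mm^2/s).
#' @param affine 4x4 voxel-to-world matrix (mm); voxel centers sit at
#'   integer 0-based indices.
#' @return A `tensor_volume` object.
#' @export
tensor_volume <- function(tensors, affine = diag(4)) {
  if (length(dim(tensors)) != 4L || dim(tensors)[4] != 6L) {
    ts_stop("format_error",
            "tensor array must be X x Y x Z x 6, got [%s]",
            paste(dim(tensors), collapse = " x "))
  }
  check_affine(affine)
  structure(list(dims = check_dims(dim(tensors)[1:3]),
                 affine = affine, tensors = tensors),
            class = "tensor_volume")
}

#' Construct a scalar volume (e.g. an FA or diffusivity map)
#'
#' @param values 3D numeric array.
#' @param affine 4x4 voxel-to-world matrix (mm).
#' @param metric optional metric label ("FA", "MD", "AD", "RD", ...).
#' @return A `scalar_volume` object.
#' @export
scalar_volume <- function(values, affine = diag(4), metric = NULL) {
  if (length(dim(values)) != 3L) {
    ts_stop("format_error", "scalar volume must be a 3D array")
  }
  check_affine(affine)
  structure(list(dims = check_dims(dim(values)), affine = affine,
                 values = values, metric = metric),
            class = "scalar_volume")
}

#' Construct a binary mask on a voxel grid
#'
#' Values are binarized as `value > 0.5`, which is robust to interpolation
#' dust left by upstream resampling.
#'
#' @param values 3D array (numeric or logical).
#' @param affine 4x4 voxel-to-world matrix (mm).
#' @return A `binary_mask` object with 0/1 integer values.
#' @export
binary_mask <- function(values, affine = diag(4)) {
  if (length(dim(values)) != 3L) {
    ts_stop("format_error", "mask must be a 3D array")
  }
  check_affine(affine)
  v <- array(as.integer(values > 0.5), dim = dim(values))
  structure(list(dims = check_dims(dim(values)), affine = affine, values = v),
            class = "binary_mask")
}

#' @export
print.tensor_volume <- function(x, ...) {
  cat(sprintf("<tensor_volume> %s voxels, voxel size %s mm\n",
              paste(x$dims, collapse = "x"),
              paste(signif(voxel_sizes(x$affine), 4), collapse = "x")))
  invisible(x)
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume%s> %s voxels, range [%.4g, %.4g]\n",
              if (is.null(x$metric)) "" else paste0(" ", x$metric),
              paste(x$dims, collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels, %d foreground\n",
              paste(x$dims, collapse = "x"), sum(x$values)))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-4) {
  all(a$dims == b$dims) && max(abs(a$affine - b$affine)) < tol
}

require_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b)) {
    ts_stop("validation_error", "%s are not on a common grid", what)
  }
  invisible(TRUE)
}

strip_nifti_attrs <- function(img) {
  arr <- as.array(img)
  array(as.numeric(arr), dim = dim(arr))
}

nifti_affine <- function(img) {
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  matrix(as.numeric(aff), 4, 4)
}

write_nifti_array <- function(arr, affine, path) {
  img <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  RNifti::pixdim(img) <- c(voxel_sizes(affine), rep(1, max(0L, nd - 3L)))
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a diffusion tensor volume from NIfTI
#'
#' Accepts a 4D file with 6 volumes (the FSL/dtifit convention) or the 5D
#' `X x Y x Z x 1 x 6` symmetric-matrix dialect; components are normalized
#' to lower-triangle row order Dxx, Dxy, Dxz, Dyy, Dyz, Dzz.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return A [tensor_volume()].
#' @export
read_tensor_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- strip_nifti_attrs(img)
  d <- dim(arr)
  if (length(d) == 5L && d[4] == 1L) {
    arr <- array(arr, dim = d[c(1:3, 5)])
    d <- dim(arr)
  }
  if (length(d) != 4L || d[4] != 6L) {
    ts_stop("format_error",
            "expected a tensor NIfTI with 6 components, got shape [%s]",
            paste(d, collapse = " x "))
  }
  tensor_volume(arr, nifti_affine(img))
}

#' Write a tensor volume to NIfTI
#' @param tv a [tensor_volume()].
#' @param path output `.nii` / `.nii.gz` path.
#' @export
write_tensor_volume <- function(tv, path) {
  stopifnot(inherits(tv, "tensor_volume"))
  write_nifti_array(tv$tensors, tv$affine, path)
}

#' Read a scalar volume from NIfTI
#' @param path input path.
#' @return A [scalar_volume()].
#' @export
read_scalar_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- strip_nifti_attrs(img)
  if (length(dim(arr)) != 3L) {
    ts_stop("format_error", "expected a 3D scalar NIfTI, got shape [%s]",
            paste(dim(arr), collapse = " x "))
  }
  scalar_volume(arr, nifti_affine(img))
}

#' Write a scalar volume to NIfTI
#' @param sv a [scalar_volume()].
#' @param path output path.
#' @export
write_scalar_volume <- function(sv, path) {
  stopifnot(inherits(sv, "scalar_volume"))
  write_nifti_array(sv$values, sv$affine, path)
}

#' Read a binary ROI mask from NIfTI
#' @param path input path; values are binarized as `> 0.5`.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path) {
  sv <- read_scalar_volume(path)
  binary_mask(sv$values, sv$affine)
}

#' Write a binary mask to NIfTI
#' @param mask a [binary_mask()].
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  write_nifti_array(mask$values, mask$affine, path)
}

#' Read a subject covariate table
#'
#' The cohort CSV has a header row and at least the columns `subject_id`,
#' `GA_birth` (gestational age at birth, weeks), `PMA_scan` (post-menstrual
#' age at scan, weeks) and optionally `tensor_path`.
#'
#' @param path CSV path.
#' @return A validated `data.frame`.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(df)
}

#' Write a subject covariate table to CSV
#' @param cohort a cohort `data.frame` (see [read_cohort()]).
#' @param path output CSV path.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

validate_cohort <- function(df) {
  need <- c("subject_id", "GA_birth", "PMA_scan")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    ts_stop("format_error", "cohort table missing columns: %s",
            paste(miss, collapse = ", "))
  }
  if (anyDuplicated(df$subject_id)) {
    ts_stop("validation_error", "subject_id values must be unique")
  }
  if (any(df$GA_birth <= 0) || any(df$PMA_scan <= 0) ||
      any(df$GA_birth >= df$PMA_scan)) {
    ts_stop("validation_error",
            "ages must be positive with GA_birth < PMA_scan for every subject")
  }
  df
}
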