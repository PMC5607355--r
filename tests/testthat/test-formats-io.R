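# Round trips and typed failure modes for every on-disk format.

test_that("tensor volume NIfTI round trip preserves data and affine", {
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- c(-20, -18, -12)
  arr <- array(rnorm(5 * 6 * 7 * 6), dim = c(5, 6, 7, 6))
  tv <- tensor_volume(arr, aff)
  f <- tempfile(fileext = ".nii.gz")
  write_tensor_volume(tv, f)
  tv2 <- read_tensor_volume(f)
  expect_identical(tv2$tensors, arr)
  expect_identical(tv2$affine, aff)
})

test_that("tensor reader rejects wrong component counts with a format error", {
  f <- tempfile(fileext = ".nii")
  tractsheet:::write_nifti_array(array(0, dim = c(4, 4, 4, 7)), diag(4), f)
  expect_error(read_tensor_volume(f), class = "format_error")
  expect_error(read_tensor_volume(f), "7")
  expect_error(tensor_volume(array(0, dim = c(3, 3, 3, 5))),
               class = "format_error")
})

test_that("scalar and mask round trips; masks binarize at 0.5", {
  aff <- diag(c(1.5, 1.5, 2, 1))
  sv <- scalar_volume(array(runif(60), c(3, 4, 5)), aff)
  f <- tempfile(fileext = ".nii")
  write_scalar_volume(sv, f)
  expect_equal(read_scalar_volume(f)$values, sv$values, tolerance = 1e-7)

  vals <- array(c(0, 0.4, 0.51, 1, 0.499, 0.6, rep(0, 18)), c(2, 3, 4))
  m <- binary_mask(vals, aff)
  expect_identical(as.integer(m$values), as.integer(vals > 0.5))
})

test_that("non-invertible affines are rejected", {
  bad <- diag(4); bad[1, 1] <- 0
  expect_error(scalar_volume(array(0, c(2, 2, 2)), bad),
               class = "validation_error")
})

test_that("mesh VTK round trip reproduces vertices, radius and normals", {
  ph <- flat_phantom(dims = c(16, 12, 12), half_thickness_mm = 4.5)
  surf <- extract_medial_surface(ph$mask)
  f <- tempfile(fileext = ".vtk")
  write_mesh(surf, f)
  s2 <- read_mesh(f)
  expect_lt(max(abs(s2$vertices - surf$vertices)), 1e-6)
  expect_lt(max(abs(s2$radius - surf$radius)), 1e-6)
  expect_lt(max(abs(s2$normals - surf$normals)), 1e-5)
  expect_identical(s2$triangles, surf$triangles)
})

test_that("mesh writer rejects invalid surfaces", {
  expect_error(medial_surface(matrix(numeric(0), 0, 3),
                              matrix(integer(0), 0, 3),
                              matrix(numeric(0), 0, 3), numeric(0)),
               class = "validation_error")
  # degenerate (zero-area) triangle
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0, 1, 0))
  expect_error(
    medial_surface(v, rbind(c(1, 2, 3), c(1, 2, 4)),
                   matrix(rep(c(0, 0, 1), 4), ncol = 3, byrow = TRUE),
                   rep(1, 4)),
    "degenerate")
})

test_that("random meshes round trip within 1e-6 mm", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 4 + rep
    g <- expand.grid(x = seq_len(n), y = seq_len(n))
    v <- cbind(g$x * 1.7, g$y * 2.3, rnorm(nrow(g))) + rnorm(3 * nrow(g)) * 50
    id <- function(i, j) (j - 1) * n + i
    tri <- do.call(rbind, lapply(seq_len(n - 1), function(i) {
      do.call(rbind, lapply(seq_len(n - 1), function(j) {
        rbind(c(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
              c(id(i, j), id(i + 1, j + 1), id(i, j + 1)))
      }))
    }))
    nr <- tractsheet:::unit_rows(matrix(rnorm(3 * nrow(v)), ncol = 3))
    surf <- medial_surface(v, tri, nr, runif(nrow(v), 0.5, 3))
    f <- tempfile(fileext = ".vtk")
    write_mesh(surf, f)
    s2 <- read_mesh(f)
    expect_lt(max(abs(s2$vertices - surf$vertices)), 1e-6)
  }
})

test_that("TCK and TRK round trip in world mm", {
  sl <- list(cbind(seq(0, 9), 1, 2), cbind(0:3, 0:3, 0:3) * 1.5)
  tg <- tractogram(sl)
  ftck <- tempfile(fileext = ".tck")
  write_tractogram(tg, ftck)
  tg2 <- read_tractogram(ftck)
  expect_equal(length(tg2$streamlines), 2L)
  expect_lt(max(mapply(function(a, b) max(abs(a - b)),
                       tg$streamlines, tg2$streamlines)), 1e-4)

  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- c(-10, -20, -5)
  ftrk <- tempfile(fileext = ".trk")
  write_tractogram(tg, ftrk, affine = aff, dims = c(20, 20, 20))
  tg3 <- read_tractogram(ftrk)
  expect_lt(max(mapply(function(a, b) max(abs(a - b)),
                       tg$streamlines, tg3$streamlines)), 1e-4)
})

test_that("zero-streamline tractogram files read back empty without error", {
  tg <- tractogram(list())
  ftck <- tempfile(fileext = ".tck")
  write_tractogram(tg, ftck)
  expect_length(read_tractogram(ftck)$streamlines, 0)
  ftrk <- tempfile(fileext = ".trk")
  write_tractogram(tg, ftrk, affine = diag(4), dims = c(5, 5, 5))
  expect_length(read_tractogram(ftrk)$streamlines, 0)
})

test_that("truncated tractogram files raise format errors naming an offset", {
  sl <- list(cbind(seq(0, 9), 1, 2))
  ftrk <- tempfile(fileext = ".trk")
  write_tractogram(tractogram(sl), ftrk, affine = diag(4), dims = c(5, 5, 5))
  sz <- file.info(ftrk)$size
  raw <- readBin(ftrk, "raw", n = sz - 10)
  writeBin(raw, ftrk)
  expect_error(read_tractogram(ftrk), class = "format_error")
  expect_error(read_tractogram(ftrk), "byte")
  expect_error(read_tractogram(tempfile(fileext = ".xyz")),
               class = "format_error")
})

test_that("TRK files written by an independent implementation read identically", {
  # nibabel writes the reference file for the same streamline set.
  sl0 <- cbind(seq(0, 18, by = 2), seq(1, 19, by = 2), 3)
  ref <- tempfile(fileext = ".trk")
  script <- sprintf("
import numpy as np, nibabel as nib
sl = np.stack([np.arange(0,19,2.), np.arange(1,20,2.), np.full(10,3.)], 1)
t = nib.streamlines.Tractogram([sl.astype(np.float32)],
                               affine_to_rasmm=np.eye(4))
hdr = {'voxel_sizes': (2.,2.,2.), 'dimensions': (20,20,20),
       'voxel_to_rasmm': np.diag([2.,2.,2.,1.])}
nib.streamlines.TrkFile(t, header=hdr).save(r'%s')
", ref)
  status <- system2("python", "-", input = script,
                    stdout = FALSE, stderr = FALSE)
  expect_identical(status, 0L)
  tg <- read_tractogram(ref)
  expect_length(tg$streamlines, 1)
  expect_lt(max(abs(tg$streamlines[[1]] - sl0)), 1e-4)

  # and nibabel reads ours back byte-compatibly
  ours <- tempfile(fileext = ".trk")
  write_tractogram(tractogram(list(sl0)), ours,
                   affine = diag(c(2, 2, 2, 1)), dims = c(20, 20, 20))
  check <- sprintf("
import numpy as np, nibabel as nib, sys
t = nib.streamlines.load(r'%s')
sl = np.stack([np.arange(0,19,2.), np.arange(1,20,2.), np.full(10,3.)], 1)
sys.exit(0 if np.abs(t.streamlines[0] - sl).max() < 1e-4 else 1)
", ours)
  expect_identical(system2("python", "-", input = check,
                           stdout = FALSE, stderr = FALSE), 0L)
})

test_that("cohort CSV round trips and invalid tables are rejected", {
  co <- data.frame(subject_id = c("a", "b", "c"),
                   GA_birth = c(28, 30, 26.5),
                   PMA_scan = c(40, 41.5, 39),
                   tensor_path = c("a.nii", "b.nii", "c.nii"))
  f <- tempfile(fileext = ".csv")
  write_cohort(co, f)
  expect_equal(read_cohort(f), co)
  bad <- co; bad$subject_id[2] <- "a"
  expect_error(write_cohort(bad, f), class = "validation_error")
  bad2 <- co; bad2$GA_birth[1] <- 45
  expect_error(write_cohort(bad2, f), class = "validation_error")
  expect_error(read_cohort({
    f2 <- tempfile(fileext = ".csv")
    utils::write.csv(data.frame(x = 1), f2, row.names = FALSE)
    f2
  }), class = "format_error")
})
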