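# FACT tracking geometry, ROI selection and rasterization.

test_that("uniform field gives straight streamlines spanning the mask", {
  tv <- uniform_field(dims = c(10, 10, 10), dir = c(1, 0, 0))
  tg <- fact_track(tv, tracking_params())
  expect_length(tg$streamlines, 1000)
  for (s in tg$streamlines[sample(1000, 30)]) {
    expect_lt(max(abs(s[, 2] - s[1, 2])), 1e-9)  # straight
    expect_lt(max(abs(s[, 3] - s[1, 3])), 1e-9)
    expect_gte(diff(range(s[, 1])), 10 * 2)       # spans the grid
  }
})

test_that("no seeds below the FA threshold", {
  tv <- uniform_field(fa_val = 0.05)
  expect_warning(tg <- fact_track(tv, tracking_params(fa_threshold = 0.1)))
  expect_length(tg$streamlines, 0)
})

test_that("90-degree interface stops tracking at 45 deg and passes at 95 deg", {
  fld <- interface_field(dims = c(12, 8, 8))
  # voxel x-indices visited by segment midpoints
  mid_vx <- function(s) {
    mid <- (s[-1, , drop = FALSE] + s[-nrow(s), , drop = FALSE]) / 2
    round(mid[, 1] / 2)
  }
  crosses <- function(tg) {
    vapply(tg$streamlines, function(s) {
      vx <- mid_vx(s)
      any(vx <= fld$half - 1) && any(vx >= fld$half)
    }, logical(1))
  }
  tg45 <- fact_track(fld$tv, tracking_params(angle_threshold_deg = 45))
  expect_false(any(crosses(tg45)))
  tg95 <- fact_track(fld$tv, tracking_params(angle_threshold_deg = 95))
  # exactly the streamlines seeded in the x-oriented block reach and cross
  n_block1 <- as.integer(fld$half * 8 * 8)
  expect_identical(sum(crosses(tg95)), n_block1)

  # analytic-field oracle: beyond the interface motion is along z only
  for (s in tg95$streamlines[crosses(tg95)][1:20]) {
    vx <- mid_vx(s)
    in_b2 <- which(vx >= fld$half)
    seg_pts <- s[c(in_b2, max(in_b2) + 1), , drop = FALSE]
    expect_lt(diff(range(seg_pts[, 2])), 1e-9)          # y frozen
    expect_lt(diff(range(seg_pts[, 1])), 2 * 2e-6 + 1e-9)  # x frozen
  }
})

test_that("tracking is deterministic and respects the FA floor", {
  ph <- flat_phantom(dims = c(14, 10, 12))
  tg1 <- fact_track(ph$volume, tracking_params())
  tg2 <- fact_track(ph$volume, tracking_params())
  expect_identical(tg1$streamlines, tg2$streamlines)

  fa_vol <- metric_volume(ph$volume, "FA")$values
  for (s in tg1$streamlines[sample(length(tg1$streamlines), 20)]) {
    mid <- (s[-1, , drop = FALSE] + s[-nrow(s), , drop = FALSE]) / 2
    vox <- round(tractsheet:::world_to_voxel(mid, ph$volume$affine))
    ok <- tractsheet:::in_grid(vox, dim(fa_vol))
    # interior segment midpoints lie in voxels at/above threshold
    interior <- ok
    interior[c(1, length(interior))] <- FALSE
    if (any(interior)) {
      v <- fa_vol[tractsheet:::voxel_linear_index(
        vox[interior, , drop = FALSE], dim(fa_vol))]
      expect_true(all(v >= 0.1 - 1e-9))
    }
  }
})

test_that("select_streamlines applies waypoint AND / exclusion NOT semantics", {
  aff <- diag(c(2, 2, 2, 1))
  dims <- c(12, 8, 8)
  w1 <- block_mask(dims, 1:2, 1:8, 1:8, aff)
  w2 <- block_mask(dims, 11:12, 1:8, 1:8, aff)
  ex <- block_mask(dims, 6:6, 1:8, 4:4, aff)
  through <- cbind(seq(0, 22, by = 1), 4, 4)       # crosses w1, w2
  through_ex <- cbind(seq(0, 22, by = 1), 4, 6)    # z=6mm -> voxel z=3
  short <- cbind(seq(0, 8, by = 1), 4, 4)          # only w1
  tg <- tractogram(list(through, through_ex, short))

  kept <- select_streamlines(tg, selection_rule(list(w1, w2)))
  expect_length(kept$streamlines, 2)
  kept2 <- select_streamlines(tg, selection_rule(list(w1, w2), list(ex)))
  expect_identical(kept2$streamlines, list(through))

  # idempotence
  rule <- selection_rule(list(w1, w2), list(ex))
  once <- select_streamlines(tg, rule)
  twice <- select_streamlines(once, rule)
  expect_identical(once$streamlines, twice$streamlines)
})

test_that("selection matches a brute-force membership oracle on random data", {
  set.seed(31)
  aff <- diag(c(2, 2, 2, 1))
  dims <- c(10, 10, 10)
  masks <- replicate(3, {
    arr <- array(as.integer(runif(1000) < 0.15), dim = dims)
    binary_mask(arr, aff)
  }, simplify = FALSE)
  sls <- replicate(100, {
    n <- sample(3:10, 1)
    start <- runif(3, 0, 18)
    step <- matrix(rnorm(3 * n), ncol = 3)
    pts <- start + apply(step, 2, cumsum)
    pts
  }, simplify = FALSE)
  tg <- tractogram(sls)
  rule <- selection_rule(masks[1:2], masks[3])
  kept <- select_streamlines(tg, rule)
  brute_keep <- vapply(sls, function(s) {
    inmask <- function(m) {
      any(vapply(seq_len(nrow(s)), function(i) {
        v <- round(tractsheet:::world_to_voxel(s[i, , drop = FALSE], aff))
        all(v >= 0) && all(v <= dims - 1) &&
          m$values[v[1] + 1, v[2] + 1, v[3] + 1] > 0
      }, logical(1)))
    }
    inmask(masks[[1]]) && inmask(masks[[2]]) && !inmask(masks[[3]])
  }, logical(1))
  expect_identical(kept$streamlines, sls[brute_keep])
})

test_that("tract_mask rasterizes densified streamlines correctly", {
  aff <- diag(c(2, 2, 2, 1))
  # one x-parallel streamline through voxel row y=3, z=4 (0-based)
  s <- cbind(c(0, 18), 6, 8)
  m <- tract_mask(tractogram(list(s)), c(10, 8, 8), aff)
  expect_identical(sum(m$values), 10L)
  expect_true(all(m$values[, 4, 5] == 1))

  expect_warning(m0 <- tract_mask(tractogram(list()), c(4, 4, 4), aff))
  expect_identical(sum(m0$values), 0L)

  # random tractogram vs naive dense-point rasterization oracle
  set.seed(41)
  sls <- replicate(20, {
    pts <- matrix(runif(9, 0, 18), ncol = 3)
    pts
  }, simplify = FALSE)
  tg <- tractogram(sls)
  m1 <- tract_mask(tg, c(10, 10, 10), aff)
  arr <- array(0L, dim = c(10, 10, 10))
  for (s in sls) {
    for (i in seq_len(nrow(s) - 1)) {
      # same half-voxel densification contract, written independently
      len <- sqrt(sum((s[i + 1, ] - s[i, ])^2))
      tt <- seq(0, 1, length.out = max(2L, ceiling(len / 1) + 1L))
      pts <- cbind(s[i, 1] + tt * (s[i + 1, 1] - s[i, 1]),
                   s[i, 2] + tt * (s[i + 1, 2] - s[i, 2]),
                   s[i, 3] + tt * (s[i + 1, 3] - s[i, 3]))
      vox <- round(pts / 2)
      ok <- vox[, 1] >= 0 & vox[, 1] <= 9 & vox[, 2] >= 0 & vox[, 2] <= 9 &
        vox[, 3] >= 0 & vox[, 3] <= 9
      arr[vox[ok, , drop = FALSE] + 1L] <- 1L
    }
  }
  expect_identical(m1$values, arr)
})

test_that("snr_estimate is mean over sample SD", {
  aff <- diag(4)
  vals <- array(0, c(2, 2, 2))
  vals[1:4] <- c(10, 10, 12, 12)
  roi <- array(0L, c(2, 2, 2)); roi[1:4] <- 1L
  sv <- scalar_volume(vals, aff)
  expect_equal(snr_estimate(sv, binary_mask(roi, aff)), 11 / sd(c(10, 10, 12, 12)),
               tolerance = 1e-10)
  expect_equal(round(snr_estimate(sv, binary_mask(roi, aff)), 4), 9.5263)

  vals2 <- vals; vals2[1:4] <- 7
  expect_warning(out <- snr_estimate(scalar_volume(vals2, aff),
                                     binary_mask(roi, aff)))
  expect_identical(out, Inf)

  set.seed(9)
  n <- 1e4
  dims <- c(25, 20, 20)
  noisy <- array(rnorm(prod(dims), 100, 5), dims)
  roi_all <- binary_mask(array(1L, dims), aff)
  est <- snr_estimate(scalar_volume(noisy, aff), roi_all)
  expect_lt(abs(est - 20) / 20, 0.05)
})
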