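# Point-wise GLM and permutation cluster inference.

make_design <- function(contrast = "positive", nuisance = "GA_birth") {
  design_spec("PMA_scan", nuisance = nuisance, contrast = contrast)
}

test_that("noiseless linear response is recovered exactly with capped t", {
  surf <- small_surface()
  n <- 10
  pma <- seq(38, 47, length.out = n)
  cohort <- data.frame(subject_id = as.character(1:n),
                       GA_birth = rep(28, n), PMA_scan = pma)
  Y <- matrix(2 * pma + 1, n, 5)
  fit <- fit_glm(Y, cohort, design_spec("PMA_scan"))
  expect_equal(unname(fit$beta), rep(2, 5), tolerance = 1e-9)
  expect_true(all(fit$t >= 1e5))  # capped sentinel, not Inf
  expect_true(all(is.finite(fit$t)))
})

test_that("beta, SE and t match a textbook normal-equations oracle", {
  set.seed(55)
  n <- 5
  cohort <- data.frame(subject_id = as.character(1:n),
                       GA_birth = c(26, 28, 30, 31, 32),
                       PMA_scan = c(39, 40.5, 42, 44, 46))
  for (rep_ in 1:10) {
    y <- rnorm(n)
    fit <- fit_glm(matrix(y, n, 1), cohort, design_spec("PMA_scan"),
                   min_frac = 0)
    X <- cbind(1, cohort$PMA_scan)
    xtx_inv <- solve(t(X) %*% X)
    bh <- xtx_inv %*% t(X) %*% y
    res <- y - X %*% bh
    s2 <- sum(res^2) / (n - 2)
    se <- sqrt(s2 * xtx_inv[2, 2])
    expect_equal(fit$beta[1], bh[2], tolerance = 1e-10)
    expect_equal(fit$se[1], se, tolerance = 1e-10)
    expect_equal(fit$t[1], bh[2] / se, tolerance = 1e-10)
  }
})

test_that("null t statistics follow Student t with the design's df", {
  set.seed(60)
  n <- 48L
  cohort <- data.frame(subject_id = as.character(1:n),
                       GA_birth = runif(n, 24, 33),
                       PMA_scan = runif(n, 38.6, 47.1))
  Y <- matrix(rnorm(n * 1000), n, 1000)
  fit <- fit_glm(Y, cohort, make_design())
  ks <- suppressWarnings(stats::ks.test(fit$t, function(q)
    stats::pt(q, df = fit$df)))
  expect_gt(ks$p.value, 0.01)
  expect_identical(fit$df, n - 3L)
})

test_that("rank-deficient designs fail naming the collinear column", {
  n <- 12
  cohort <- data.frame(subject_id = as.character(1:n),
                       GA_birth = rep(28, n),  # constant: collinear with 1
                       PMA_scan = seq(39, 46, length.out = n))
  expect_error(fit_glm(matrix(rnorm(n * 3), n, 3), cohort, make_design()),
               "GA_birth")
})

test_that("cluster permutation test is reproducible and order invariant", {
  surf <- small_surface()
  adj <- surface_adjacency(surf)
  co <- make_cohort(cohort_spec(n_subjects = 16, beta = 0.012, seed = 3),
                    surf)
  des <- make_design()
  r1 <- cluster_permutation_test(co$maps, co$cohort, des, adj,
                                 n_perm = 200, seed = 11)
  r2 <- cluster_permutation_test(co$maps, co$cohort, des, adj,
                                 n_perm = 200, seed = 11)
  expect_identical(r1$corrected_p, r2$corrected_p)
  expect_identical(r1$null_max_size, r2$null_max_size)

  perm <- sample(nrow(co$maps))
  r3 <- cluster_permutation_test(co$maps[perm, ], co$cohort[perm, ], des,
                                 adj, n_perm = 200, seed = 11)
  expect_equal(r3$t, r1$t, tolerance = 1e-10)
  expect_identical(r3$size, r1$size)

  expect_true(all(r1$corrected_p >= 1 / 201))
})

test_that("raising the primary threshold never grows clusters", {
  surf <- small_surface()
  adj <- surface_adjacency(surf)
  co <- make_cohort(cohort_spec(n_subjects = 16, beta = 0.012, seed = 5),
                    surf)
  des <- make_design()
  sizes <- vapply(c(1.5, 2.5, 3.5), function(thr) {
    r <- cluster_permutation_test(co$maps, co$cohort, des, adj,
                                  primary_t = thr, n_perm = 100, seed = 2)
    if (length(r$size)) max(r$size) else 0L
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("clusters are connected in the surface graph", {
  surf <- small_surface()
  adj <- surface_adjacency(surf)
  co <- make_cohort(cohort_spec(n_subjects = 20, beta = 0.015, seed = 8),
                    surf)
  r <- cluster_permutation_test(co$maps, co$cohort, make_design(), adj,
                                n_perm = 100, seed = 4)
  expect_gt(length(r$clusters), 0)
  for (cl in r$clusters) {
    comp <- tractsheet:::graph_components(cl, adj)
    expect_length(comp, 1)
  }
})

test_that("no suprathreshold vertices yields an empty result, not an error", {
  surf <- small_surface()
  adj <- surface_adjacency(surf)
  co <- make_cohort(cohort_spec(n_subjects = 16, beta = 0, seed = 10), surf)
  r <- cluster_permutation_test(co$maps, co$cohort, make_design(), adj,
                                primary_t = 50, n_perm = 100, seed = 1)
  expect_length(r$clusters, 0)
})

test_that("positive and negative contrasts separate signed effects", {
  surf <- small_surface()
  adj <- surface_adjacency(surf)
  co <- make_cohort(cohort_spec(n_subjects = 24, beta = -0.02,
                                noise_sd = 0.01, seed = 12), surf)
  rneg <- cluster_permutation_test(co$maps, co$cohort,
                                   make_design("negative"), adj,
                                   n_perm = 200, seed = 3)
  rpos <- cluster_permutation_test(co$maps, co$cohort,
                                   make_design("positive"), adj,
                                   n_perm = 200, seed = 3)
  expect_gt(length(rneg$clusters), 0)
  expect_lt(min(rneg$corrected_p), 0.05)
  if (length(rpos$clusters)) {
    expect_gt(min(rpos$corrected_p), 0.05)
  }
})

test_that("vertices missing in many subjects are excluded from analysis", {
  surf <- small_surface()
  nv <- nrow(surf$vertices)
  n <- 16
  co <- make_cohort(cohort_spec(n_subjects = n, beta = 0, seed = 14), surf)
  maps <- co$maps
  maps[1:8, 3] <- NA  # half the subjects missing at vertex 3
  fit <- fit_glm(maps, co$cohort, make_design())
  expect_true(fit$excluded[3])
  expect_true(is.na(fit$t[3]))
  expect_false(any(fit$excluded[-3]))
})
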