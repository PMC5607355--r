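# Evaluation metrics: pairwise Dice overlap of binary tract masks,
# FA-distribution comparison by Bhattacharyya distance, the exact Wilcoxon
# signed-rank test, and the combined native/TSA/TBSS projection report.

#' Dice overlap of two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`, the voxel-level overlap of two
#' subjects' tract segmentations.
#'
#' @param a,b [binary_mask()] objects on a common grid, not both empty.
#' @return Dice score in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  require_same_grid(a, b, "masks")
  na <- sum(a$values); nb <- sum(b$values)
  if (na + nb == 0) {
    ts_stop("validation_error", "both masks are empty")
  }
  2 * sum(a$values & b$values) / (na + nb)
}

#' Per-subject median of pairwise Dice scores
#'
#' For subject i, the median over all other subjects j of
#' `dice(mask_i, mask_j)` — the per-subject registration-consistency
#' summary.
#'
#' @param masks list of at least 3 [binary_mask()] objects on one grid.
#' @return Named numeric vector of per-subject medians.
#' @export
pairwise_median_dice <- function(masks) {
  n <- length(masks)
  if (n < 3) ts_stop("validation_error", "need at least 3 subjects")
  for (m in masks[-1]) require_same_grid(masks[[1]], m, "masks")
  D <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- dice(masks[[i]], masks[[j]])
    }
  }
  out <- vapply(seq_len(n), function(i) stats::median(D[i, -i]), numeric(1))
  names(out) <- names(masks) %||% paste0("subject_", seq_len(n))
  out
}

#' Normalized equal-width histogram of FA values
#'
#' @param values numeric vector; values outside `range` are clipped with a
#'   warning.
#' @param n_bins number of equal-width bins (at least 2).
#' @param range histogram support, default `[0, 1]`.
#' @return A `tract_histogram`: list with `bin_edges` and `probs`
#'   (summing to 1).
#' @export
fa_histogram <- function(values, n_bins = 100L, range = c(0, 1)) {
  if (length(values) == 0L) {
    ts_stop("validation_error", "cannot histogram an empty value set")
  }
  if (n_bins < 2L) ts_stop("validation_error", "n_bins must be >= 2")
  if (any(values < range[1] | values > range[2])) {
    ts_warn("values outside [%g, %g] clipped", range[1], range[2])
    values <- pmin(pmax(values, range[1]), range[2])
  }
  edges <- seq(range[1], range[2], length.out = n_bins + 1)
  bin <- findInterval(values, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  structure(list(bin_edges = edges, probs = counts / sum(counts)),
            class = "tract_histogram")
}

#' Bhattacharyya distance between two normalized histograms
#'
#' `D_B = -ln sum_i sqrt(p_i q_i)`; zero iff the histograms are equal,
#' symmetric, `+Inf` (with a warning) for disjoint supports.
#'
#' @param p,q `tract_histogram` objects with identical bin edges.
#' @return Nonnegative distance.
#' @export
bhattacharyya_distance <- function(p, q) {
  stopifnot(inherits(p, "tract_histogram"), inherits(q, "tract_histogram"))
  if (length(p$bin_edges) != length(q$bin_edges) ||
      max(abs(p$bin_edges - q$bin_edges)) > 1e-12) {
    ts_stop("validation_error", "histograms must share bin edges")
  }
  bc <- sum(sqrt(p$probs * q$probs))
  if (bc == 0) {
    ts_warn("histograms have disjoint support; distance is infinite")
    return(Inf)
  }
  max(-log(bc), 0)
}

#' Wilcoxon signed-rank test with exact small-sample null
#'
#' Zero differences are dropped (their count is reported via an
#' attribute). For 25 or fewer nonzero differences the p-value comes from
#' exact enumeration of the signed-rank statistic over all sign
#' assignments (tied ranks handled exactly via midranks); above that a
#' normal approximation with tie and continuity corrections is used.
#'
#' @param paired_diffs numeric vector of paired differences.
#' @param alternative `"two_sided"`, `"greater"` (positive shift) or
#'   `"less"`.
#' @return p-value in `(0, 1]`, with attributes `statistic` (W+),
#'   `n_zero_dropped` and `method`.
#' @export
wilcoxon_signed_rank <- function(paired_diffs,
                                 alternative = c("two_sided", "greater",
                                                 "less")) {
  alternative <- match.arg(alternative)
  zeros <- sum(paired_diffs == 0)
  d <- paired_diffs[paired_diffs != 0]
  n <- length(d)
  if (n == 0L) {
    ts_stop("validation_error", "all paired differences are zero")
  }
  if (n < 5L) {
    ts_warn("fewer than 5 nonzero differences; test has little power")
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  if (n <= 25L) {
    # Distribution of 2*W+ (integer-valued with midranks) by convolution
    # over the 2^n sign assignments.
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    probs <- numeric(total + 1L)  # index k+1 <-> 2W+ = k
    probs[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), probs[seq_len(total + 1L - ri)])
      probs <- (probs + shifted) / 2
    }
    w2 <- as.integer(round(2 * w_plus))
    p_ge <- sum(probs[(w2 + 1L):(total + 1L)])
    p_le <- sum(probs[seq_len(w2 + 1L)])
    p <- switch(alternative,
                greater = p_ge,
                less = p_le,
                two_sided = min(1, 2 * min(p_ge, p_le)))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    zstat <- function(shift) (w_plus - mu + shift) / sqrt(sig2)
    p <- switch(alternative,
                greater = stats::pnorm(zstat(-0.5), lower.tail = FALSE),
                less = stats::pnorm(zstat(0.5)),
                two_sided = min(1, 2 * min(
                  stats::pnorm(zstat(-0.5), lower.tail = FALSE),
                  stats::pnorm(zstat(0.5)))))
    method <- "normal_approx"
  }
  structure(max(p, .Machine$double.xmin), statistic = w_plus,
            n_zero_dropped = zeros, method = method)
}

#' Compare native-space, skeleton-projected and voxel-skeleton FA values
#'
#' Per subject: mean FA under each method and the Bhattacharyya distances
#' of the skeleton-projected distributions from the native-space one.
#' Cohort level: paired Wilcoxon signed-rank tests on the mean-FA
#' contrasts and on the paired Bhattacharyya distances.
#'
#' @param native_values list (one numeric vector per subject) of FA values
#'   over the native-space tract voxels — the reference distribution.
#' @param tsa_maps list of skeleton maps (see [project_subject()]) or
#'   numeric vectors of surface-projected FA.
#' @param tbss_values list of numeric vectors of voxel-skeleton-projected
#'   FA.
#' @param n_bins histogram resolution for the distances.
#' @return A list with `report` (data.frame, one row per subject:
#'   mean_native, mean_tsa, mean_tbss, db_tsa, db_tbss, n_bins) and
#'   `tests` (named p-values from paired two-sided Wilcoxon tests).
#' @export
compare_projection_methods <- function(native_values, tsa_maps, tbss_values,
                                       n_bins = 100L) {
  ns <- length(native_values)
  stopifnot(length(tsa_maps) == ns, length(tbss_values) == ns)
  tsa_values <- lapply(tsa_maps, function(m) {
    if (inherits(m, "skeleton_map")) m$values[!m$missing] else m
  })
  for (i in seq_len(ns)) {
    if (!length(native_values[[i]]) || !length(tsa_values[[i]]) ||
        !length(tbss_values[[i]])) {
      ts_stop("validation_error", "subject %d has an empty value set", i)
    }
  }
  row_of <- function(i) {
    hn <- fa_histogram(native_values[[i]], n_bins)
    ht <- fa_histogram(tsa_values[[i]], n_bins)
    hb <- fa_histogram(tbss_values[[i]], n_bins)
    data.frame(subject = i,
               mean_native = mean(native_values[[i]]),
               mean_tsa = mean(tsa_values[[i]]),
               mean_tbss = mean(tbss_values[[i]]),
               db_tsa = bhattacharyya_distance(hn, ht),
               db_tbss = bhattacharyya_distance(hn, hb),
               n_bins = n_bins)
  }
  report <- do.call(rbind, lapply(seq_len(ns), row_of))
  wp <- function(d) {
    if (all(d == 0)) return(1)  # identical methods: no evidence either way
    as.numeric(wilcoxon_signed_rank(d, "two_sided"))
  }
  tests <- c(native_vs_tsa = wp(report$mean_tsa - report$mean_native),
             native_vs_tbss = wp(report$mean_tbss - report$mean_native),
             tsa_vs_tbss = wp(report$mean_tbss - report$mean_tsa),
             db_tsa_vs_db_tbss = wp(report$db_tbss - report$db_tsa))
  list(report = report, tests = tests)
}
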