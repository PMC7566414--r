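# brute-force reference implementation of the correlation coefficient
cc_oracle <- function(t, r) {
  n <- length(t)
  mt <- sum(t) / n; mr <- sum(r) / n
  num <- 0; dt <- 0; dr <- 0
  for (i in seq_len(n)) {
    num <- num + (t[i] - mt) * (r[i] - mr)
    dt <- dt + (t[i] - mt)^2
    dr <- dr + (r[i] - mr)^2
  }
  num / sqrt(dt * dr)
}

test_that("cross_correlation matches identities and the brute-force oracle", {
  x <- c(0.3, -1, 2, 0.7, -0.2)
  expect_equal(cross_correlation(x, x), 1)
  expect_equal(cross_correlation(x, -x), -1)
  expect_equal(cross_correlation(c(1, -1, 1, -1), c(1, 1, -1, -1)), 0)
  set.seed(8)
  for (i in 1:20) {
    t <- rnorm(20); r <- rnorm(20)
    expect_equal(cross_correlation(t, r), cc_oracle(t, r),
                 tolerance = 1e-12)
  }
  expect_warning(v <- cross_correlation(rep(1, 5), rnorm(5)), "constant")
  expect_true(is.na(v))
  expect_error(cross_correlation(1:4, 1:5), "lengths differ")
})

test_that("cc is invariant to affine rescaling up to sign", {
  set.seed(2)
  t <- rnorm(30); r <- rnorm(30)
  base <- cross_correlation(t, r)
  expect_equal(cross_correlation(3.7 * t + 2, r), base, tolerance = 1e-12)
  expect_equal(cross_correlation(-2 * t + 5, r), -base, tolerance = 1e-12)
})

test_that("cc maps order tissue by response SNR on the default phantom", {
  ph <- small_phantom()
  pct <- to_percent_change(detrend_linear(ph$bh$bold))
  ref <- shift_waveform(boxcar(bh_design()), 15)
  cc <- cc_map(pct, ref)
  m_v <- mean(cc[ph$labels == "vessel"], na.rm = TRUE)
  m_g <- mean(cc[ph$labels == "GM"], na.rm = TRUE)
  m_w <- mean(cc[ph$labels == "WM"], na.rm = TRUE)
  expect_gt(m_v, m_g)
  expect_gt(m_g, m_w)
  expect_error(cc_map(pct, rep(0, 70)), "constant")
  expect_error(cc_map(pct, rep(1, 10)), "length")
  # constant voxel -> missing
  arr <- array(0, c(2, 1, 1, 5))
  arr[1, 1, 1, ] <- 1
  arr[2, 1, 1, ] <- rnorm(5)
  ccc <- cc_map(bold4d(arr), c(0, 1, 0, 1, 0))
  expect_true(is.na(ccc[1, 1, 1]))
  expect_false(is.na(ccc[2, 1, 1]))
})

test_that("rest-derived threshold is k x SD of the null cc distribution", {
  set.seed(5)
  null_cc <- replicate(2000, cor(rnorm(100), rnorm(100)))
  thr <- rest_null_threshold(null_cc, k = 4)
  expect_equal(thr$threshold, 4 * sd(null_cc))
  # null SD of Pearson r is ~ 1/sqrt(n - 1)
  expect_equal(thr$threshold, 4 / sqrt(99), tolerance = 0.1)
  expect_equal(rest_null_threshold(null_cc, k = 0)$threshold, 0)
  expect_equal(rest_null_threshold(null_cc, k = 8)$threshold,
               2 * thr$threshold)
  expect_error(rest_null_threshold(null_cc[1:50]), "at least 100")
})

test_that("analytic r threshold inverts the Student-t transform", {
  r70 <- analytic_r_threshold(70, 0.001)
  # oracle: root-find on the one-tailed p-value of r
  pfun <- function(r) {
    t <- r * sqrt(68 / (1 - r^2))
    pt(t, 68, lower.tail = FALSE) - 0.001
  }
  r_oracle <- uniroot(pfun, c(0.01, 0.99), tol = 1e-12)$root
  expect_equal(r70, r_oracle, tolerance = 1e-9)
  expect_equal(r70, 0.3632, tolerance = 1e-4)

  ns <- c(10, 20, 40, 70, 200)
  rs <- vapply(ns, analytic_r_threshold, numeric(1), p_one_tailed = 0.001)
  expect_true(all(diff(rs) < 0))
  expect_lt(analytic_r_threshold(70, 0.4999), 1e-3)
  expect_error(analytic_r_threshold(3, 0.001), "n must")
  expect_error(analytic_r_threshold(70, 0.7), "p_one_tailed")
})

test_that("cluster labeling respects connectivity and is deterministic", {
  m <- array(FALSE, c(5, 5, 3))
  m[1:2, 1, 1] <- TRUE                  # cluster of 2
  m[4, 4, 2] <- TRUE; m[5, 5, 3] <- TRUE  # corner-adjacent pair
  lab26 <- label_clusters(m, 26)
  lab6 <- label_clusters(m, 6)
  expect_equal(max(lab26), 2L)          # corner pair merges under 26-conn
  expect_equal(max(lab6), 3L)           # splits under 6-conn
  # labels ordered by size then position: both size-2 clusters, tie by voxel
  expect_equal(lab26[1, 1, 1], 1L)
  expect_identical(label_clusters(m, 26), lab26)
})

test_that("apply_threshold masks, prunes clusters and keeps sign", {
  stat <- array(0, c(8, 8, 4))
  stat[2:4, 2:4, 2] <- 0.8              # true blob (27 voxels)
  stat[7, 7, 1] <- 0.9                  # isolated crosser
  stat[1, 8, 4] <- -0.85                # negative isolated crosser
  a0 <- apply_threshold(stat, 1.0)
  expect_equal(a0$n_active, 0L)
  a1 <- apply_threshold(stat, 0, min_cluster_size = 1)
  expect_equal(a1$n_active, sum(is.finite(stat) & abs(stat) > 0))
  a2 <- apply_threshold(stat, 0.4, min_cluster_size = 5)
  expect_equal(a2$n_active, 9L)         # only the 3x3x1 blob survives
  expect_equal(max(a2$clusters), 1L)
  expect_true(all(a2$statistic[a2$mask] > 0))
})

test_that("Monte-Carlo cluster threshold is small for rough noise and
           monotone in alpha, deterministic under seed", {
  mc <- cluster_threshold_mc(c(16, 16, 16), 0, n_sims = 300, seed = 7)
  # rough noise: threshold equals the empirical 95th percentile of the
  # max-cluster null (Poisson-clumping puts it at 3 for these settings)
  expect_lte(mc$min_cluster_size, 4L)
  expect_equal(mc$min_cluster_size,
               as.integer(quantile(mc$max_sizes, 0.95, type = 1)))
  mc_strict <- cluster_threshold_mc(c(16, 16, 16), 0, alpha = 0.01,
                                    n_sims = 300, seed = 7)
  mc_loose <- cluster_threshold_mc(c(16, 16, 16), 0, alpha = 0.10,
                                   n_sims = 300, seed = 7)
  expect_gte(mc_strict$min_cluster_size, mc_loose$min_cluster_size)
  mc2 <- cluster_threshold_mc(c(16, 16, 16), 0, n_sims = 300, seed = 7)
  expect_identical(mc2$min_cluster_size, mc$min_cluster_size)
  expect_error(cluster_threshold_mc(c(1, 1, 1), 0), "degenerate")
  expect_error(cluster_threshold_mc(c(16, 16, 16), 0, n_sims = 50),
               "at least 100")
})

test_that("smoothing hits the requested FWHM and is mean-preserving", {
  set.seed(3)
  arr <- array(rnorm(32 * 32 * 16), c(32, 32, 16))
  sm <- gaussian_smooth_3d(arr, 6, c(2, 2, 2))
  expect_equal(mean(sm), mean(arr), tolerance = 0.02)
  est <- estimate_fwhm(sm, c(2, 2, 2))
  expect_gt(est, 4)
  expect_lt(est, 9)
  expect_identical(gaussian_smooth_3d(arr, 0), arr)
})
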