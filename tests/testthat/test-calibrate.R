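# y_matrix is V x T in array order
make_pct_bold <- function(y_matrix, dims3) {
  bold4d(array(y_matrix, c(dims3, ncol(y_matrix))), units = "pct")
}

test_that("glm_beta is exact on noiseless data and absorbs offsets", {
  d <- task_design()
  reg <- convolve_regressor(boxcar(d))
  A <- 0.7
  y <- rbind(A * reg$values,
             A * reg$values + 5,
             rep(2, 70))
  b <- make_pct_bold(y, c(3, 1, 1))
  bm <- glm_beta(b, reg)
  expect_equal(bm$beta[1, 1, 1], A, tolerance = 1e-10)
  expect_equal(bm$beta[2, 1, 1], A, tolerance = 1e-10)  # offset absorbed
  expect_equal(bm$beta[3, 1, 1], 0, tolerance = 1e-10)
  expect_error(glm_beta(b, rep(1, 70)), "rank-deficient")
  raw <- bold4d(array(1, c(2, 2, 1, 70)))
  expect_error(glm_beta(raw, reg), "percent")
})

test_that("pure-noise betas are centered at zero", {
  d <- task_design()
  reg <- convolve_regressor(boxcar(d))
  set.seed(12)
  y <- matrix(rnorm(200 * 70, 0, 0.2), 200, 70)
  bm <- glm_beta(make_pct_bold(y, c(200, 1, 1)), reg)
  expect_lt(abs(mean(bm$beta)), 3 * 0.2 / sqrt(200))
})

test_that("bh_amplitude_map passes through its source and records it", {
  maps <- quiet_fit()
  amp <- bh_amplitude_map(maps)
  idx <- which(maps$mask)
  expect_equal(amp[idx], maps$Smax[idx])
  expect_equal(attr(amp, "source"), "gamma_smax")
  expect_true(all(is.na(amp[!maps$mask])))  # missing fits -> missing amps
  expect_error(bh_amplitude_map(1:5), "source")

  # on the quiet phantom the two sources agree (up to a common scale)
  ph <- quiet_phantom()
  pct <- to_percent_change(ph$bh$bold, baseline = "rest",
                           design = bh_design())
  bb <- glm_beta(pct, suppressMessages(bh_delayed_regressor(bh_design())))
  amp2 <- bh_amplitude_map(bb)
  expect_equal(attr(amp2, "source"), "bh_glm_beta")
  common <- which(maps$mask & maps$converged & is.finite(amp2))
  expect_gt(cor(amp[common], amp2[common]), 0.9)
})

test_that("scale_map divides, floors and preserves sign", {
  beta <- array(c(1, -0.5, 0.2, 0.8), c(2, 2, 1))
  amp <- array(c(0.5, 0.5, 0.01, 0.5), c(2, 2, 1))
  sc <- scale_map(beta, amp, floor_pct = 0.05)
  expect_equal(sc$scaled[1, 1, 1], 2)
  expect_equal(sc$scaled[2, 1, 1], -1)          # sign preserved
  expect_true(is.na(sc$scaled[1, 2, 1]))        # below floor: invalid
  expect_false(any(is.infinite(sc$scaled)))
  expect_equal(sum(sc$valid), 3L)
  expect_error(scale_map(beta, array(1, c(3, 1, 1))), "grids differ")

  # uniform divisor: scaled = beta / c everywhere valid
  scu <- scale_map(beta, array(0.4, c(2, 2, 1)), floor_pct = 0.05)
  expect_equal(scu$scaled, beta / 0.4)
})

test_that("scaling is equivariant under a shared vascular gain field", {
  set.seed(9)
  dims <- c(6, 6, 2)
  nv <- prod(dims)
  neural <- array(runif(nv, 0.3, 1), dims)
  gain <- array(exp(rnorm(nv, 0, 0.4)), dims)
  beta1 <- neural               # gain-free world
  amp1 <- array(0.25, dims)
  beta2 <- neural * gain        # same world seen through the gain field
  amp2 <- 0.25 * gain
  s1 <- scale_map(beta1, amp1, floor_pct = 0.01)
  s2 <- scale_map(beta2, amp2, floor_pct = 0.01)
  expect_equal(s2$scaled, s1$scaled, tolerance = 1e-12)
})

test_that("activation_compare counts ROI membership and compactness", {
  stat <- array(0, c(8, 8, 2))
  stat[2:4, 2:4, 1] <- 1                 # blob inside ROI
  stat[7, 7, 2] <- 1; stat[1, 8, 2] <- 1 # strays outside
  before <- apply_threshold(stat, 0.5)
  stat2 <- stat; stat2[, , 2] <- 0
  after <- apply_threshold(stat2, 0.5)
  roi <- array(FALSE, c(8, 8, 2)); roi[2:4, 2:4, 1] <- TRUE
  cmpr <- activation_compare(before, after, roi)
  expect_equal(cmpr$before$n_out_roi, 2L)
  expect_equal(cmpr$after$n_out_roi, 0L)
  expect_lt(cmpr$delta_out_roi, 0)
  expect_gt(cmpr$after$compactness, cmpr$before$compactness)
  same <- activation_compare(before, before, roi)
  expect_equal(same$before, same$after)
  expect_error(activation_compare(before, after, roi & FALSE), "empty ROI")
})

test_that("Bartlett statistic matches the reference implementation", {
  set.seed(14)
  groups <- list(rnorm(20, sd = 1), rnorm(25, sd = 1.5), rnorm(30, sd = 0.7))
  mine <- bartlett_variance_test(groups)
  ref <- bartlett.test(groups)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(mine$df, 2)

  same <- bartlett_variance_test(list(groups[[1]], groups[[1]]))
  expect_equal(same$statistic, 0)
  expect_error(bartlett_variance_test(list(rep(1, 5), rnorm(5))),
               "non-positive")
  expect_error(bartlett_variance_test(list(rnorm(5))), "two groups")
})

test_that("distribution reports summarize before/after on common bins", {
  set.seed(15)
  before <- rnorm(200, 1, 0.5)
  after <- rnorm(200, 0.8, 0.2)
  rep_ <- distribution_report(before, after, n_bins = 20)
  expect_length(rep_$breaks, 21L)
  expect_equal(sum(rep_$counts_before), 200L)
  expect_equal(sum(rep_$counts_after), 200L)
  expect_lt(rep_$variances[["after"]], rep_$variances[["before"]])
  expect_lt(rep_$bartlett$p_value, 0.01)
  expect_error(distribution_report(rnorm(5), after), "at least 10")

  prefix <- file.path(withr::local_tempdir(), "dist")
  write_distribution_report(rep_, prefix)
  tab <- read.table(paste0(prefix, ".tsv"), header = TRUE)
  expect_equal(nrow(tab), 20L)
  js <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  expect_equal(js$bartlett$statistic, rep_$bartlett$statistic,
               tolerance = 1e-9)
})
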