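test_that("gamma_variate evaluates the closed form", {
  expect_equal(gamma_variate(2, Q = 1, t0 = 0, r = 2, b = 1), 4 * exp(-2))
  expect_equal(gamma_variate(c(0, 3, 5), Q = 1, t0 = 5, r = 2, b = 1),
               c(0, 0, 0))
  # peak at t0 + r b
  tt <- seq(0, 60, by = 0.001)
  v <- gamma_variate(tt, Q = 0.5, t0 = 4, r = 2.5, b = 4.5)
  expect_equal(tt[which.max(v)], 4 + 2.5 * 4.5, tolerance = 0.01)
})

test_that("derived parameters match closed forms and quadrature", {
  d <- derived_params(list(Q = 1, t0 = 0, r = 2, b = 1))
  expect_equal(d$Tmax, 2)
  expect_equal(d$Smax, 4 * exp(-2))
  expect_equal(d$SArea, gamma(3))       # = 2

  # homogeneity in Q
  d3 <- derived_params(list(Q = 3, t0 = 0, r = 2, b = 1))
  expect_equal(d3$Smax, 3 * d$Smax)
  expect_equal(d3$SArea, 3 * d$SArea)
  expect_equal(d3$Tmax, d$Tmax)

  set.seed(10)
  for (i in 1:10) {
    p <- list(Q = runif(1, 0.1, 2), t0 = runif(1, 0, 10),
              r = runif(1, 1, 4), b = runif(1, 2, 8))
    dv <- derived_params(p)
    q <- integrate(function(t) gamma_variate(t, p$Q, p$t0, p$r, p$b),
                   p$t0, Inf, rel.tol = 1e-10)$value
    expect_equal(dv$SArea, q, tolerance = 1e-6)
    opt <- optimize(function(t) gamma_variate(t, p$Q, p$t0, p$r, p$b),
                    c(p$t0, p$t0 + 100), maximum = TRUE, tol = 1e-10)
    expect_equal(dv$Tmax, opt$maximum, tolerance = 1e-6)
    expect_equal(dv$Smax, opt$objective, tolerance = 1e-6)
  }
})

test_that("fit_voxel recovers noiseless parameters and is deterministic", {
  d <- bh_design()
  tt <- volume_times(d); on <- d$epochs$onset_s
  set.seed(21)
  for (i in 1:3) {
    truth <- c(Q = runif(1, 0.01, 0.1), t0 = runif(1, 2, 10),
               r = runif(1, 1.5, 3.5), b = runif(1, 3, 8))
    y <- gamma_series(tt, on, 1, truth[2], truth[3], truth[4]) *
      truth[1] * (truth[3] * truth[4])^truth[3] * exp(-truth[3])
    f <- fit_voxel(y, tt, on, n_starts = 150, n_repeats = 2, seed = i)
    est <- c(f$Q, f$t0_rel, f$r, f$b)
    expect_lt(max(abs(est - truth) / truth), 1e-3)
  }
  f1 <- fit_voxel(gamma_series(tt, on, 0.3, 5, 2.5, 4.5) + 0.05, tt, on,
                  n_starts = 100, n_repeats = 2, seed = 5)
  f2 <- fit_voxel(gamma_series(tt, on, 0.3, 5, 2.5, 4.5) + 0.05, tt, on,
                  n_starts = 100, n_repeats = 2, seed = 5)
  expect_identical(unclass(f1), unclass(f2))
})

test_that("a flat series fits a straight line (Smax ~ 0)", {
  d <- bh_design()
  f <- fit_voxel(rep(0.37, 70), volume_times(d), d$epochs$onset_s,
                 n_starts = 50, n_repeats = 1, seed = 1)
  expect_lt(f$Smax, 1e-8)
  expect_equal(f$intercept, 0.37, tolerance = 1e-8)
  expect_error(fit_voxel(c(NA, rep(0, 69)), volume_times(d),
                         d$epochs$onset_s), "non-finite")
})

test_that("best-found RSS does not increase with more starts", {
  d <- bh_design()
  tt <- volume_times(d); on <- d$epochs$onset_s
  set.seed(33)
  for (i in 1:5) {
    y <- gamma_series(tt, on, 0.25, 5, 2.5, 4.5) + rnorm(70, 0, 0.2)
    f_small <- fit_voxel(y, tt, on, n_starts = 60, n_repeats = 1, seed = i)
    f_large <- fit_voxel(y, tt, on, n_starts = 240, n_repeats = 1, seed = i)
    # allow optimizer-noise slack of 1e-4 relative
    expect_lte(f_large$rss_best, f_small$rss_best * (1 + 1e-4))
  }
})

test_that("volume fits recover the quiet phantom and guard units", {
  maps <- quiet_fit()
  ph <- quiet_phantom()
  gm <- ph$labels == "GM" & maps$converged
  rel <- abs(maps$Smax[gm] - ph$truth$bh_amp_pct[gm]) /
    ph$truth$bh_amp_pct[gm]
  expect_lt(median(rel), 1e-2)
  expect_gt(mean(maps$converged[maps$mask]), 0.9)
  # background excluded from the mask
  expect_false(any(maps$mask[ph$labels == "background"]))
  # WM below GM almost everywhere without noise
  wm <- ph$labels == "WM" & maps$converged
  set.seed(3)
  n <- min(sum(gm), sum(wm))
  expect_gte(mean(sample(maps$Smax[wm], n) < sample(maps$Smax[gm], n)), 0.9)
  expect_error(fit_volume(ph$bh$bold, bh_design()), "percent")
})

test_that("tissue segmentation on SArea separates GM, WM and vessels", {
  maps <- quiet_fit()
  ph <- quiet_phantom()
  seg <- segment_tissue(maps)
  cls <- seg$classes
  gm_ok <- cls[ph$labels == "GM" & !is.na(cls)] != "WM-like"
  wm_ok <- cls[ph$labels == "WM" & !is.na(cls)] == "WM-like"
  expect_gte(mean(c(gm_ok, wm_ok)), 0.95)   # overall GM/WM agreement
  expect_gte(mean(wm_ok), 0.95)
  # vessel amplitudes land in the vessel-like (top percentile) class
  vz <- cls[ph$labels == "vessel" & !is.na(cls)]
  expect_gt(mean(vz == "vessel-like"), 0.5)

  degenerate <- maps
  degenerate$SArea[degenerate$mask] <- 1
  expect_error(segment_tissue(degenerate), "degenerate")
})

test_that("per-class summaries report the GM/WM area ratio", {
  maps <- quiet_fit()
  seg <- segment_tissue(maps)
  st <- gm_wm_stats(maps, seg$classes)
  expect_setequal(intersect(st$table$class, c("GM-like", "WM-like")),
                  c("GM-like", "WM-like"))
  # amplitudes differ ~4x and the shape is shared, so SArea ratio ~4
  expect_gt(st$gm_wm_sarea_ratio, 2)
  expect_lt(st$gm_wm_sarea_ratio, 6)
  # identical classes -> ratio 1
  m2 <- maps
  even <- which(m2$mask & m2$converged)
  cls2 <- array(NA_character_, dim(m2$mask))
  cls2[even] <- rep(c("GM-like", "WM-like"), length.out = length(even))
  m2$Smax[even] <- 1; m2$t0_rel[even] <- 5; m2$SArea[even] <- 7
  st2 <- gm_wm_stats(m2, cls2)
  expect_equal(st2$gm_wm_sarea_ratio, 1)
  expect_error(gm_wm_stats(maps, array(NA_character_, dim(maps$mask))),
               "empty")
})

test_that("epoch splitting yields three identical-structure sub-runs", {
  ph <- small_phantom()
  pct <- to_percent_change(detrend_linear(ph$bh$bold))
  sp <- split_epochs(pct, bh_design())
  expect_length(sp$runs, 3L)
  for (r in sp$runs) expect_equal(dim(r)[4], 20L)
  expect_equal(sp$design$n_volumes, 20L)
  expect_equal(sp$design$epochs$onset_s, 30)
  # sub-runs are contiguous slices of the original
  expect_equal(sp$runs[[2]]$data, pct$data[, , , 21:40])
  d2 <- build_block_design(30, 2, 16, 44, 3)
  expect_error(split_epochs(pct, d2), "exactly 3")
})

test_that("epoch reliability is 1 on identical maps and high at low noise", {
  maps <- quiet_fit()
  rel <- epoch_reliability(maps, maps, maps, n_boot = 50, seed = 1)
  expect_true(all(abs(rel$cor - 1) < 1e-12))
  expect_true(all(rel$boot_sd < 1e-12))

  # low-noise phantom: single-epoch fits agree across epochs
  ph <- quiet_phantom()
  spec <- phantom_spec(grid_shape = c(16L, 16L, 16L), noise_sd_pct = 0.05,
                       drift_pct_per_run = 0)
  sim <- simulate_bh_run(ph$labels, spec, bh_design(), truth = ph$truth)
  pct <- to_percent_change(detrend_linear(sim$bold))
  sp <- split_epochs(pct, bh_design())
  ms <- lapply(sp$runs, function(r) fit_volume(r, sp$design))
  rel2 <- epoch_reliability(ms[[1]], ms[[2]], ms[[3]], n_boot = 100,
                            seed = 2)
  smax <- rel2[rel2$param == "Smax", ]
  expect_true(all(smax$cor > 0.8))
  # bootstrap point estimate consistent with its CI
  expect_true(all(smax$cor >= smax$ci_lo - 0.05 &
                    smax$cor <= smax$ci_hi + 0.05))
})

test_that("gamma maps round-trip through NIfTI + sidecar", {
  maps <- quiet_fit()
  prefix <- file.path(withr::local_tempdir(), "gamma")
  write_gamma_maps(maps, prefix)
  back <- read_gamma_maps(prefix)
  expect_equal(sum(back$mask), sum(maps$mask))
  idx <- which(maps$mask & maps$converged)
  expect_equal(back$Smax[idx], maps$Smax[idx], tolerance = 1e-5)
  expect_equal(back$epoch_onsets, maps$epoch_onsets)
})
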