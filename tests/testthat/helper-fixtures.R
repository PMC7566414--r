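# Shared fixtures, memoized so expensive simulations/fits run once per suite.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

bh_design <- function() build_block_design(30, 3, 16, 44, 3,
                                           condition = "breath_hold")
task_design <- function() build_block_design(30, 3, 30, 30, 3)

# 16^3 phantom at default SNR
small_phantom <- function() fixture("small_phantom", function() {
  spec <- phantom_spec(grid_shape = c(16L, 16L, 16L))
  labels <- make_labels(c(16, 16, 16), seed = 2)
  truth <- make_truth(labels, spec)
  list(spec = spec, labels = labels, truth = truth,
       bh = simulate_bh_run(labels, spec, bh_design(), truth = truth),
       task = simulate_task_run(labels, spec, task_design(), truth = truth))
})

# 16^3 phantom, (near-)noiseless and drift-free
quiet_phantom <- function() fixture("quiet_phantom", function() {
  spec <- phantom_spec(grid_shape = c(16L, 16L, 16L), noise_sd_pct = 1e-9,
                       drift_pct_per_run = 0)
  labels <- make_labels(c(16, 16, 16), seed = 2)
  truth <- make_truth(labels, spec)
  list(spec = spec, labels = labels, truth = truth,
       bh = simulate_bh_run(labels, spec, bh_design(), truth = truth),
       task = simulate_task_run(labels, spec, task_design(), truth = truth))
})

# gamma fit of the noiseless 16^3 breath-hold run (rest-baseline percent,
# no detrend, so recovery is exact up to fit tolerance)
quiet_fit <- function() fixture("quiet_fit", function() {
  ph <- quiet_phantom()
  pct <- to_percent_change(ph$bh$bold, baseline = "rest",
                           design = bh_design())
  fit_volume(pct, bh_design())
})

# multi-epoch gamma series generator (unit-peak shape scaled to amp)
gamma_series <- function(time_s, onsets, amp, t0, r, b) {
  out <- numeric(length(time_s))
  for (on in onsets) {
    u <- time_s - on - t0
    pos <- u > 0
    out[pos] <- out[pos] + amp * (u[pos] / (r * b))^r * exp(r - u[pos] / b)
  }
  out
}
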