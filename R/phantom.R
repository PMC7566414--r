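#' Phantom generative specification
#'
#' Parameters of the synthetic 4D BOLD phantom. Defaults reproduce the
#' regime of the clinical breath-hold data the pipeline targets: gray-matter
#' breath-hold amplitude ~0.25 % signal change, white matter ~0.06 %, bright
#' large-vessel hot spots, a tumor-margin region with suppressed vascular
#' gain, Gaussian thermal noise and a slow linear drift, TR 3 s on a
#' 32 x 32 x 16 grid of 2.5 x 2.5 x 3 mm voxels.
#'
#' @param grid_shape integer length-3 voxel counts
#' @param voxel_size_mm voxel dimensions in mm
#' @param tr_s repetition time, seconds
#' @param baseline_intensity raw-signal baseline (arbitrary units)
#' @param noise_sd_pct Gaussian noise SD as percent of baseline (> 0)
#' @param drift_pct_per_run peak-to-peak linear drift over the run, percent
#' @param tissue_bh_amp_pct named vector of breath-hold peak amplitudes
#'   (percent) per tissue label
#' @param tissue_t0_s named vector of response onset times (seconds after
#'   hold onset) per tissue label
#' @param gamma_r,gamma_b gamma-variate shape and time constant of the
#'   generated response (time-to-peak after onset = `gamma_r * gamma_b` s,
#'   ~11 s, i.e. peak ~16 s after hold onset for gray matter)
#' @param gain_log_sd SD of log vascular gain across voxels (multiplicative
#'   heterogeneity)
#' @param tumor_gain_factor multiplicative gain suppression in tumor margin
#' @param neural_amp_pct neural drive (percent per unit gain) in the active
#'   task region
#' @param seed RNG seed carried through all simulations
#' @return object of class `phantom_spec`
#' @export
phantom_spec <- function(grid_shape = c(32L, 32L, 16L),
                         voxel_size_mm = c(2.5, 2.5, 3),
                         tr_s = 3,
                         baseline_intensity = 1000,
                         noise_sd_pct = 0.2,
                         drift_pct_per_run = 0.3,
                         tissue_bh_amp_pct = c(background = 0, GM = 0.25,
                                               WM = 0.06, vessel = 1.2,
                                               tumor_margin = 0.10),
                         tissue_t0_s = c(background = 0, GM = 5, WM = 8,
                                         vessel = 3, tumor_margin = 6),
                         gamma_r = 2.5, gamma_b = 4.5,
                         gain_log_sd = 0.31,
                         tumor_gain_factor = 0.4,
                         neural_amp_pct = 0.8,
                         seed = 42L) {
  tissue_bh_amp_pct <- unlist(tissue_bh_amp_pct)
  tissue_t0_s <- unlist(tissue_t0_s)
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0),
            noise_sd_pct > 0, all(tissue_bh_amp_pct >= 0), tr_s > 0,
            neural_amp_pct >= 0)
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm, tr_s = tr_s,
                 baseline_intensity = baseline_intensity,
                 noise_sd_pct = noise_sd_pct,
                 drift_pct_per_run = drift_pct_per_run,
                 tissue_bh_amp_pct = tissue_bh_amp_pct,
                 tissue_t0_s = tissue_t0_s,
                 gamma_r = gamma_r, gamma_b = gamma_b,
                 gain_log_sd = gain_log_sd,
                 tumor_gain_factor = tumor_gain_factor,
                 neural_amp_pct = neural_amp_pct,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# voxel-center coordinate arrays for a grid
grid_coords <- function(dims) {
  list(x = array(rep(seq_len(dims[1]), times = dims[2] * dims[3]), dims),
       y = array(rep(rep(seq_len(dims[2]), each = dims[1]), dims[3]), dims),
       z = array(rep(seq_len(dims[3]), each = dims[1] * dims[2]), dims))
}

in_ellipsoid <- function(co, center, semi) {
  ((co$x - center[1]) / semi[1])^2 + ((co$y - center[2]) / semi[2])^2 +
    ((co$z - center[3]) / semi[3])^2 <= 1
}

#' Deterministic tissue label volume
#'
#' Builds a nested-ellipsoid anatomy: a white-matter core inside a
#' gray-matter shell inside background, plus at least one small spherical
#' large-vessel blob in the gray matter and a tumor-margin blob straddling
#' the gray/white boundary. Blob placement is jittered deterministically by
#' `seed`. Background, GM and WM each occupy at least 10 % of the grid.
#'
#' @param grid_shape length-3 voxel counts, each >= 16
#' @param seed integer seed
#' @return 3D character array with values in
#'   `c("background", "GM", "WM", "vessel", "tumor_margin")`
#' @export
make_labels <- function(grid_shape, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 16L))
    stop("grid_shape must be three counts each >= 16 (got ",
         paste(grid_shape, collapse = "x"), ")")
  set.seed(seed)
  dims <- grid_shape
  co <- grid_coords(dims)
  center <- (dims + 1) / 2 + stats::runif(3, -1, 1)
  brain_semi <- 0.45 * dims
  core_semi <- 0.30 * dims
  labels <- array("background", dims)
  brain <- in_ellipsoid(co, center, brain_semi)
  core <- in_ellipsoid(co, center, core_semi)
  labels[brain] <- "GM"
  labels[core] <- "WM"

  # vessel: small sphere centered in the GM shell
  ang <- stats::runif(1, 0, 2 * pi)
  vc <- center + c(0.375 * dims[1] * cos(ang), 0.375 * dims[2] * sin(ang), 0)
  vessel <- in_ellipsoid(co, vc, rep(1.6, 3)) & brain
  labels[vessel] <- "vessel"

  # tumor margin: sphere straddling the GM/WM boundary, opposite side
  tc <- center + c(0.3 * dims[1] * cos(ang + pi), 0.3 * dims[2] * sin(ang + pi), 0)
  tum <- in_ellipsoid(co, tc, rep(2.5, 3)) & brain
  labels[tum] <- "tumor_margin"
  labels
}

#' Ground-truth maps for a phantom
#'
#' Per-voxel vascular gain (log-normal heterogeneity, suppressed in the
#' tumor margin), breath-hold amplitude `bh_amp_pct = tissue amplitude x
#' vascular gain`, response onset `t0` (seconds after hold onset), and the
#' neural drive map: a spherical "functional" region inside the gray-matter
#' shell with `neural_amp = neural_amp_pct`, zero elsewhere. The task
#' response amplitude is `neural_amp x vascular_gain`, the multiplicative
#' coupling under which division by the breath-hold amplitude exactly
#' cancels the vascular gain.
#'
#' @param labels label volume from [make_labels()]
#' @param spec a `phantom_spec`
#' @return object of class `truth_maps`: list of 3D arrays `labels`,
#'   `vascular_gain`, `bh_amp_pct`, `t0_s`, `neural_amp`, `Q`, and scalars
#'   `gamma_r`, `gamma_b`
#' @export
make_truth <- function(labels, spec) {
  dims <- dim(labels)
  stopifnot(identical(as.integer(dims), spec$grid_shape))
  set.seed(spec$seed)
  gain <- array(exp(stats::rnorm(prod(dims), 0, spec$gain_log_sd)), dims)
  gain[labels == "tumor_margin"] <- gain[labels == "tumor_margin"] *
    spec$tumor_gain_factor
  gain[labels == "background"] <- 1
  amp <- array(spec$tissue_bh_amp_pct[labels], dims) * gain
  t0 <- array(spec$tissue_t0_s[labels], dims)

  co <- grid_coords(dims)
  center <- (dims + 1) / 2
  ang <- stats::runif(1, 0, 2 * pi)
  fc <- center + c(0.375 * dims[1] * cos(ang + pi / 2),
                   0.375 * dims[2] * sin(ang + pi / 2), 0)
  neural <- array(0, dims)
  blob <- in_ellipsoid(co, fc, rep(0.11 * min(dims[1:2]) + 1.5, 3))
  neural[blob & labels == "GM"] <- spec$neural_amp_pct

  rb <- spec$gamma_r * spec$gamma_b
  q <- amp / (rb^spec$gamma_r * exp(-spec$gamma_r))
  structure(list(labels = labels, vascular_gain = gain, bh_amp_pct = amp,
                 t0_s = t0, neural_amp = neural, Q = q,
                 gamma_r = spec$gamma_r, gamma_b = spec$gamma_b),
            class = "truth_maps")
}

# shared drift/noise/baseline assembly; resp_pct is a V x T percent matrix
assemble_run <- function(resp_pct, labels, spec, n_volumes, seed) {
  dims <- dim(labels)
  nv <- prod(dims)
  tt <- (seq_len(n_volumes) - 1) * spec$tr_s
  drift <- spec$drift_pct_per_run * (tt / max(tt, 1) - 0.5)
  base <- ifelse(labels == "background", 0.02, 1) * spec$baseline_intensity
  set.seed(seed)
  noise <- matrix(stats::rnorm(nv * n_volumes), nv, n_volumes) *
    (spec$noise_sd_pct / 100 * spec$baseline_intensity)
  sig <- as.vector(base) * (1 + resp_pct / 100 +
                              matrix(drift / 100, nv, n_volumes,
                                     byrow = TRUE)) + noise
  bold4d(array(sig, c(dims, n_volumes)), spec$voxel_size_mm, spec$tr_s, "raw")
}

# per-label unit-peak gamma response summed over epochs; returns V x T matrix
bh_response_matrix <- function(labels, truth, design) {
  dims <- dim(labels)
  nv <- prod(dims)
  tt <- volume_times(design)
  resp <- matrix(0, nv, design$n_volumes)
  r <- truth$gamma_r; b <- truth$gamma_b; rb <- r * b
  for (lab in unique(as.vector(labels))) {
    idx <- which(labels == lab)
    t0 <- truth$t0_s[idx[1]]
    curve <- numeric(design$n_volumes)
    for (i in seq_len(nrow(design$epochs))) {
      u <- tt - design$epochs$onset_s[i] - t0
      pos <- u > 0
      curve[pos] <- curve[pos] + (u[pos] / rb)^r * exp(r - u[pos] / b)
    }
    resp[idx, ] <- truth$bh_amp_pct[idx] %o% curve
  }
  resp
}

#' Simulate a breath-hold run
#'
#' Each voxel's raw signal is
#' `baseline * (1 + drift + sum_epochs gamma(t) / 100) + noise`, where the
#' per-epoch gamma-variate response has unit peak scaled to the voxel's
#' ground-truth `bh_amp_pct`, onset at epoch onset + tissue `t0`, and shape
#' `(r, b)` from the spec. Reproducible under the spec seed.
#'
#' @param labels label volume
#' @param spec a `phantom_spec`
#' @param design breath-hold `block_design`
#' @param truth optional `truth_maps` (built from `labels`/`spec` if NULL)
#' @param seed noise seed (default `spec$seed`)
#' @return list with elements `bold` (a raw-units `bold4d`) and `truth`
#' @export
simulate_bh_run <- function(labels, spec, design, truth = NULL,
                            seed = spec$seed) {
  stopifnot(inherits(design, "block_design"))
  if (!identical(as.integer(dim(labels)), spec$grid_shape))
    stop("labels grid does not match spec grid_shape")
  if (is.null(truth)) truth <- make_truth(labels, spec)
  resp <- bh_response_matrix(labels, truth, design)
  list(bold = assemble_run(resp, labels, spec, design$n_volumes, seed),
       truth = truth)
}

#' Simulate a task run
#'
#' The task response amplitude (percent) of each voxel is
#' `neural_amp x vascular_gain`, applied to the unit-peak canonical-HRF
#' regressor of the design; noise and drift as in [simulate_bh_run()]. The
#' noise seed defaults to `spec$seed + 1` so BH and task runs drawn from the
#' same spec have independent noise.
#'
#' @inheritParams simulate_bh_run
#' @export
simulate_task_run <- function(labels, spec, design, truth = NULL,
                              seed = spec$seed + 1L) {
  stopifnot(inherits(design, "block_design"))
  if (!identical(as.integer(dim(labels)), spec$grid_shape))
    stop("labels grid does not match spec grid_shape")
  if (is.null(truth)) truth <- make_truth(labels, spec)
  reg <- convolve_regressor(boxcar(design))
  amp <- as.vector(truth$neural_amp * truth$vascular_gain)
  resp <- amp %o% reg$values
  list(bold = assemble_run(resp, labels, spec, design$n_volumes, seed),
       truth = truth)
}

#' Synthetic motion trace for a phantom run
#'
#' Small zero-mean jitter (the phantom is motion-free; the trace exercises
#' the QC path). SD chosen near the clinical sub-voxel regime (~0.05 mm).
#'
#' @param n_volumes number of volumes
#' @param sd_mm jitter SD in mm
#' @param seed integer seed
#' @return data.frame with columns x, y, z, pitch, roll, yaw
#' @export
simulate_motion_trace <- function(n_volumes, sd_mm = 0.05, seed = 1L) {
  set.seed(seed)
  out <- as.data.frame(matrix(stats::rnorm(n_volumes * 6, 0, sd_mm),
                              n_volumes, 6))
  names(out) <- c("x", "y", "z", "pitch", "roll", "yaw")
  out
}

#' Serialize a phantom spec to / from JSON
#' @param spec a `phantom_spec`
#' @param path file path
#' @export
write_phantom_spec <- function(spec, path) {
  x <- unclass(spec)
  # named vectors must go out as JSON objects, not nameless arrays
  x$tissue_bh_amp_pct <- as.list(x$tissue_bh_amp_pct)
  x$tissue_t0_s <- as.list(x$tissue_t0_s)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(phantom_spec, cfg)
}
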