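#' Pearson cross-correlation between a voxel time course and a reference
#'
#' `cc = sum((t - mu_t)(r - mu_r)) / sqrt(sum((t - mu_t)^2) sum((r - mu_r)^2))`,
#' the correlation coefficient between the reference waveform and the voxel
#' time course. Constant inputs have no defined correlation and return NA
#' with a warning.
#'
#' @param t_series numeric voxel time course
#' @param r_series numeric reference waveform, same length
#' @return correlation in `[-1, 1]`, or NA for constant input
#' @export
cross_correlation <- function(t_series, r_series) {
  if (length(t_series) != length(r_series))
    stop("series lengths differ (", length(t_series), " vs ",
         length(r_series), ")")
  if (length(t_series) < 3) stop("need at least 3 samples")
  td <- t_series - mean(t_series)
  rd <- r_series - mean(r_series)
  den <- sqrt(sum(td^2) * sum(rd^2))
  if (den == 0 || !is.finite(den)) {
    warning("constant input: correlation undefined")
    return(NA_real_)
  }
  sum(td * rd) / den
}

#' Voxel-wise cross-correlation map
#'
#' Correlates the reference waveform with every voxel time course. Voxels
#' outside the mask, or with constant time courses, are NA.
#'
#' @param bold a `bold4d`
#' @param reference a `ref_waveform` or numeric vector of length `n_volumes`
#' @param mask logical 3D array (default: all voxels with finite data)
#' @return 3D numeric array of correlations
#' @export
cc_map <- function(bold, reference, mask = NULL) {
  stopifnot(inherits(bold, "bold4d"))
  r <- if (inherits(reference, "ref_waveform")) reference$values
       else as.numeric(reference)
  n <- dim(bold)[4]
  if (length(r) != n)
    stop("reference length ", length(r), " != n_volumes ", n)
  rd <- r - mean(r)
  if (sum(rd^2) == 0) stop("reference waveform is constant")
  y <- as_voxel_matrix(bold)
  if (is.null(mask)) mask <- array(TRUE, dim(bold)[1:3])
  yd <- y - rowMeans(y)
  ss <- rowSums(yd^2)
  cc <- as.vector(yd %*% rd) / sqrt(ss * sum(rd^2))
  cc[!as.vector(mask) | ss == 0 | !is.finite(cc)] <- NA_real_
  array(cc, dim(bold)[1:3])
}

#' Rest-derived activation threshold
#'
#' Threshold = `k` times the SD of the resting-state cross-correlation
#' coefficient distribution (default k = 4, the rule under which voxels
#' above the threshold are considered active).
#'
#' @param rest_cc_values numeric vector of rest-period correlations (NA
#'   dropped); at least 100 finite values required
#' @param k SD multiplier (default 4)
#' @return list with `threshold`, `k`, `sd`, `n`, and a five-number summary
#'   of the rest distribution
#' @export
rest_null_threshold <- function(rest_cc_values, k = 4) {
  v <- rest_cc_values[is.finite(rest_cc_values)]
  if (length(v) < 100)
    stop("need at least 100 rest correlation values (got ", length(v), ")")
  s <- stats::sd(v)
  list(threshold = k * s, k = k, sd = s, n = length(v),
       summary = stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1)))
}

#' Analytic correlation threshold for a significance level
#'
#' Smallest |r| reaching one-tailed significance `p_one_tailed` for a series
#' of `n` time points, from the Student-t transform of the correlation
#' coefficient at `df = n - 2`: `r = t / sqrt(t^2 + df)` with `t` the
#' inverse-t quantile.
#'
#' @param n number of time points (>= 4)
#' @param p_one_tailed one-tailed p-value in (0, 0.5)
#' @return minimum significant |r|
#' @export
analytic_r_threshold <- function(n, p_one_tailed) {
  if (n < 4 || n != round(n)) stop("n must be an integer >= 4")
  if (p_one_tailed <= 0 || p_one_tailed >= 0.5)
    stop("p_one_tailed must be in (0, 0.5)")
  df <- n - 2
  tq <- stats::qt(1 - p_one_tailed, df)
  tq / sqrt(tq^2 + df)
}

# ---------------------------------------------------------------------------
# 3D smoothing and connected components
# ---------------------------------------------------------------------------

conv1d_axis <- function(arr, kernel, axis) {
  dims <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  n <- dims[axis]
  m <- matrix(a, nrow = n)
  r <- (length(kernel) - 1) / 2
  padded <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(kernel)) {
    out <- out + kernel[j] * padded[j:(j + n - 1), , drop = FALSE]
  }
  aperm(array(out, dims[perm]), order(perm))
}

#' Gaussian smoothing of a 3D volume
#'
#' Separable Gaussian smoothing to a target FWHM in mm, zero-padded at the
#' edges with kernel-mass renormalization (mean-preserving).
#'
#' @param arr 3D numeric array
#' @param fwhm_mm full-width-half-maximum in mm (0 = no smoothing)
#' @param voxel_size_mm length-3 voxel size
#' @return smoothed array
#' @export
gaussian_smooth_3d <- function(arr, fwhm_mm, voxel_size_mm = c(1, 1, 1)) {
  if (fwhm_mm <= 0) return(arr)
  out <- arr
  ones <- array(1, dim(arr))
  for (ax in 1:3) {
    sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm[ax]
    r <- max(1L, ceiling(3 * sigma))
    k <- stats::dnorm(-r:r, sd = sigma)
    k <- k / sum(k)
    out <- conv1d_axis(out, k, ax)
    ones <- conv1d_axis(ones, k, ax)
  }
  out / ones
}

neighbor_offsets <- function(connectivity = 26) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  if (connectivity == 6) g <- g[abs(g$dx) + abs(g$dy) + abs(g$dz) == 1, ]
  else if (connectivity == 18)
    g <- g[abs(g$dx) + abs(g$dy) + abs(g$dz) <= 2, ]
  else if (connectivity != 26) stop("connectivity must be 6, 18 or 26")
  as.matrix(g)
}

#' Label connected clusters in a 3D binary mask
#'
#' Breadth-first connected components under 26-connectivity (faces, edges
#' and corners; the conventional default for cluster-extent inference).
#' Cluster ids are assigned deterministically: descending size, ties broken
#' by the lexicographically smallest member voxel.
#'
#' @param mask logical 3D array
#' @param connectivity 6, 18 or 26
#' @return integer 3D array; 0 = background, 1..k = cluster id
#' @export
label_clusters <- function(mask, connectivity = 26) {
  dims <- dim(mask)
  stopifnot(length(dims) == 3L)
  lab <- array(0L, dims)
  idx <- which(mask)
  if (length(idx) == 0) return(lab)
  off <- neighbor_offsets(connectivity)
  inmask <- array(FALSE, dims)
  inmask[idx] <- TRUE
  comp <- integer(length(idx))
  names(comp) <- NULL
  rank <- array(0L, dims)
  rank[idx] <- seq_along(idx)
  coords <- arrayInd(idx, dims)
  cur <- 0L
  for (i in seq_along(idx)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    comp[i] <- cur
    frontier <- i
    while (length(frontier)) {
      fc <- coords[frontier, , drop = FALSE]
      nb <- fc[rep(seq_len(nrow(fc)), each = nrow(off)), , drop = FALSE] +
        off[rep(seq_len(nrow(off)), times = nrow(fc)), , drop = FALSE]
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
            nb[, 2] >= 1 & nb[, 2] <= dims[2] &
            nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + dims[1] * (nb[, 2] - 1) + dims[1] * dims[2] * (nb[, 3] - 1)
      ranks <- unique(rank[lin])
      ranks <- ranks[ranks > 0L]
      ranks <- ranks[comp[ranks] == 0L]
      comp[ranks] <- cur
      frontier <- ranks
    }
  }
  # deterministic relabeling: descending size, then smallest member index
  sizes <- tabulate(comp)
  first <- vapply(seq_len(cur), function(k) min(idx[comp == k]), integer(1))
  ord <- order(-sizes, first)
  remap <- integer(cur)
  remap[ord] <- seq_len(cur)
  lab[idx] <- remap[comp]
  lab
}

#' Monte-Carlo cluster-extent threshold
#'
#' Simulates smooth Gaussian noise fields, thresholds at the two-tailed
#' voxel-wise p, records the largest 26-connected cluster per simulation,
#' and returns the smallest cluster size whose chance probability is at most
#' `alpha` (the cluster-extent threshold controlling family-wise error).
#'
#' @param grid_shape length-3 voxel counts
#' @param smoothness_fwhm_mm noise smoothness FWHM in mm
#' @param voxel_p two-tailed voxel-wise p threshold (default 0.005)
#' @param alpha cluster-wise significance level (default 0.05)
#' @param n_sims number of Monte-Carlo simulations (>= 100)
#' @param seed RNG seed
#' @param voxel_size_mm voxel size in mm
#' @param connectivity cluster connectivity (default 26)
#' @return list with `min_cluster_size`, `max_sizes` (per simulation), and
#'   the parameters used
#' @export
cluster_threshold_mc <- function(grid_shape, smoothness_fwhm_mm = 0,
                                 voxel_p = 0.005, alpha = 0.05,
                                 n_sims = 5000, seed = 1,
                                 voxel_size_mm = c(1, 1, 1),
                                 connectivity = 26) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 2L))
    stop("degenerate grid")
  if (n_sims < 100) stop("n_sims must be at least 100")
  set.seed(seed)
  zthr <- stats::qnorm(1 - voxel_p / 2)
  max_sizes <- integer(n_sims)
  nv <- prod(grid_shape)
  for (s in seq_len(n_sims)) {
    arr <- array(stats::rnorm(nv), grid_shape)
    if (smoothness_fwhm_mm > 0)
      arr <- gaussian_smooth_3d(arr, smoothness_fwhm_mm, voxel_size_mm)
    z <- arr / stats::sd(arr)
    m <- abs(z) > zthr
    if (!any(m)) { max_sizes[s] <- 0L; next }
    lab <- label_clusters(m, connectivity)
    max_sizes[s] <- max(tabulate(lab[lab > 0L]))
  }
  k <- as.integer(stats::quantile(max_sizes, 1 - alpha, type = 1))
  k <- max(k, 1L)
  list(min_cluster_size = k, max_sizes = max_sizes,
       voxel_p = voxel_p, alpha = alpha, n_sims = n_sims,
       smoothness_fwhm_mm = smoothness_fwhm_mm, seed = seed)
}

#' Estimate noise smoothness (FWHM) from a residual volume
#'
#' Classic gradient-based estimator: FWHM per axis from the ratio of the
#' variance of spatial first differences to the field variance, averaged
#' geometrically over axes. Used to feed the Monte-Carlo cluster simulation.
#'
#' @param arr 3D residual/noise array
#' @param voxel_size_mm voxel size in mm
#' @return estimated FWHM in mm (0 if the field is rougher than voxel scale)
#' @export
estimate_fwhm <- function(arr, voxel_size_mm = c(1, 1, 1)) {
  v <- stats::var(as.vector(arr))
  if (v == 0) return(Inf)
  fw <- numeric(3)
  for (ax in 1:3) {
    d <- switch(ax,
                arr[-1, , ] - arr[-dim(arr)[1], , ],
                arr[, -1, ] - arr[, -dim(arr)[2], ],
                arr[, , -1] - arr[, , -dim(arr)[3]])
    ratio <- stats::var(as.vector(d)) / (2 * v)
    ratio <- min(ratio, 1 - 1e-12)
    fw[ax] <- voxel_size_mm[ax] * sqrt(-2 * log(2) / log(1 - ratio))
  }
  exp(mean(log(fw)))
}

#' Threshold a statistic map into an activation map
#'
#' Active voxels are those with `|statistic| > threshold` (two-sided, sign
#' retained in the statistic); clusters smaller than `min_cluster_size`
#' are removed. Cluster labels are deterministic (descending size, then
#' lexicographic seed voxel).
#'
#' @param statistic 3D numeric array (NA = outside mask)
#' @param threshold non-negative threshold on `|statistic|`
#' @param min_cluster_size minimum surviving cluster size (default 1)
#' @param connectivity cluster connectivity (default 26)
#' @return object of class `activation_map`: list with `statistic`,
#'   `threshold`, `mask` (logical), `clusters` (integer labels),
#'   `min_cluster_size`, `n_active`
#' @export
apply_threshold <- function(statistic, threshold, min_cluster_size = 1,
                            connectivity = 26) {
  stopifnot(length(dim(statistic)) == 3L, threshold >= 0)
  active <- is.finite(statistic) & abs(statistic) > threshold
  lab <- label_clusters(active, connectivity)
  if (min_cluster_size > 1 && any(lab > 0)) {
    sizes <- tabulate(lab[lab > 0L])
    drop <- which(sizes < min_cluster_size)
    if (length(drop)) {
      active[lab %in% drop] <- FALSE
      lab <- label_clusters(active, connectivity)
    }
  }
  structure(list(statistic = statistic, threshold = threshold,
                 mask = active, clusters = lab,
                 min_cluster_size = min_cluster_size,
                 n_active = sum(active)),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf(
    "activation_map: %d active voxels (|stat| > %.4g, min cluster %d, %d clusters)\n",
    x$n_active, x$threshold, x$min_cluster_size, max(x$clusters)))
  invisible(x)
}

#' Write an activation map as paired NIfTI volumes plus a JSON sidecar
#'
#' @param map an `activation_map`
#' @param prefix output path prefix; writes `<prefix>_stat.nii`,
#'   `<prefix>_mask.nii`, `<prefix>_clusters.nii`, `<prefix>.json`
#' @param voxel_size_mm voxel size for the NIfTI headers
#' @param extra named list merged into the sidecar (seed, n_sims, ...)
#' @export
write_activation <- function(map, prefix, voxel_size_mm = c(2.5, 2.5, 3),
                             extra = list()) {
  stopifnot(inherits(map, "activation_map"))
  stat <- map$statistic
  stat[!is.finite(stat)] <- 0
  write_map(stat, paste0(prefix, "_stat.nii"), voxel_size_mm)
  write_map(array(as.numeric(map$mask), dim(map$mask)),
            paste0(prefix, "_mask.nii"), voxel_size_mm)
  write_map(array(as.numeric(map$clusters), dim(map$clusters)),
            paste0(prefix, "_clusters.nii"), voxel_size_mm)
  side <- c(list(threshold = map$threshold,
                 min_cluster_size = map$min_cluster_size,
                 n_active = map$n_active, n_clusters = max(map$clusters)),
            extra)
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}
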