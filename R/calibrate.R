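#' Voxel-wise GLM beta map
#'
#' Ordinary least squares of each voxel time course on `[intercept, linear
#' drift, regressor]`. With a unit-peak regressor on percent-change data,
#' the regressor coefficient is the response amplitude in percent signal
#' change; its standard error comes from the residual variance.
#'
#' @param bold a `bold4d` in percent units
#' @param regressor a unit-peak `ref_waveform` or numeric vector of length
#'   `n_volumes`
#' @return object of class `beta_map`: list with 3D arrays `beta`, `se`,
#'   logical `mask`, and `design_label`
#' @export
glm_beta <- function(bold, regressor) {
  stopifnot(inherits(bold, "bold4d"))
  if (bold$units != "pct")
    stop("GLM estimation requires percent-change input (units = 'pct')")
  label <- if (inherits(regressor, "ref_waveform")) regressor$label else "regressor"
  r <- if (inherits(regressor, "ref_waveform")) regressor$values
       else as.numeric(regressor)
  n <- dim(bold)[4]
  if (length(r) != n) stop("regressor length != n_volumes")
  if (max(abs(r)) > 0 && abs(max(abs(r)) - 1) > 1e-6)
    warning("regressor is not unit-peak; betas will not read as percent change")
  X <- cbind(intercept = 1, drift = seq_len(n) - (n + 1) / 2, reg = r)
  if (qr(X)$rank < 3L)
    stop("rank-deficient design (regressor collinear with intercept/drift)")
  y <- as_voxel_matrix(bold)
  ok <- rowSums(!is.finite(y)) == 0L
  dims <- dim(bold)[1:3]
  beta <- array(NA_real_, dims)
  se <- array(NA_real_, dims)
  if (any(ok)) {
    Y <- t(y[ok, , drop = FALSE])               # T x V
    xtx_inv <- solve(crossprod(X))
    B <- xtx_inv %*% crossprod(X, Y)            # 3 x V
    res <- Y - X %*% B
    s2 <- colSums(res^2) / (n - 3L)
    beta[ok] <- B[3, ]
    se[ok] <- sqrt(s2 * xtx_inv[3, 3])
  }
  structure(list(beta = beta, se = se, mask = array(ok, dims),
                 design_label = label),
            class = "beta_map")
}

#' @export
print.beta_map <- function(x, ...) {
  cat(sprintf("beta_map (%s): %d voxels, beta range [%.3g, %.3g]%%\n",
              x$design_label, sum(x$mask),
              min(x$beta, na.rm = TRUE), max(x$beta, na.rm = TRUE)))
  invisible(x)
}

#' Breath-hold amplitude map
#'
#' The divisor of the calibration. Default source is the fitted
#' gamma-variate `Smax` map; the breath-hold GLM beta map is the alternative
#' source for sensitivity analysis. The source is recorded on the result.
#'
#' @param x a `gamma_param_maps` or a `beta_map` from the breath-hold run
#' @return 3D amplitude array (percent) with attribute `source`
#' @export
bh_amplitude_map <- function(x) {
  if (inherits(x, "gamma_param_maps")) {
    out <- x$Smax
    attr(out, "source") <- "gamma_smax"
  } else if (inherits(x, "beta_map")) {
    out <- x$beta
    attr(out, "source") <- "bh_glm_beta"
    attr(out, "se") <- x$se
  } else {
    stop("amplitude source must be gamma_param_maps or beta_map")
  }
  out
}

#' Scale a task beta map by the breath-hold amplitude
#'
#' The core calibration: `scaled = task_beta / bh_amplitude` wherever the
#' breath-hold amplitude is at least `floor_pct`; voxels below the floor are
#' invalid (NA), not clipped, since division by a tiny vascular amplitude is
#' unreliable rather than large. Task beta sign is preserved. The default
#' floor is 0.05 % or, when the amplitude source carries standard errors
#' (GLM source), `max(0.05, 2 * median SE)`.
#'
#' @param task_beta a `beta_map` (task run) or 3D beta array
#' @param bh_amplitude amplitude array from [bh_amplitude_map()]
#' @param floor_pct minimum valid breath-hold amplitude in percent
#' @return object of class `scaled_map`: list with `scaled` (3D,
#'   dimensionless), `valid` (logical), `floor_pct`, `source`
#' @export
scale_map <- function(task_beta, bh_amplitude, floor_pct = NULL) {
  beta <- if (inherits(task_beta, "beta_map")) task_beta$beta else task_beta
  if (!identical(dim(beta), dim(bh_amplitude)))
    stop("task beta and breath-hold amplitude grids differ")
  if (is.null(floor_pct)) {
    floor_pct <- 0.05
    se <- attr(bh_amplitude, "se")
    if (!is.null(se))
      floor_pct <- max(0.05, 2 * stats::median(se[is.finite(se)]))
  }
  valid <- is.finite(beta) & is.finite(bh_amplitude) &
    bh_amplitude >= floor_pct
  scaled <- array(NA_real_, dim(beta))
  scaled[valid] <- beta[valid] / bh_amplitude[valid]
  structure(list(scaled = scaled, valid = valid, floor_pct = floor_pct,
                 source = attr(bh_amplitude, "source")),
            class = "scaled_map")
}

#' @export
print.scaled_map <- function(x, ...) {
  cat(sprintf(
    "scaled_map (source %s, floor %.3g%%): %d valid voxels\n",
    if (is.null(x$source)) "unknown" else x$source, x$floor_pct,
    sum(x$valid)))
  invisible(x)
}

#' Compare activation maps before and after scaling
#'
#' Reports, for each map: active counts inside / outside a reference region
#' of interest, the SD of the active-voxel statistic, and cluster
#' compactness (fraction of active voxels in the largest cluster). Empty
#' activation maps are reported as zeros.
#'
#' @param before,after `activation_map` objects on the same grid
#' @param roi_mask logical 3D array marking the expected (true) region
#' @return list with one summary per map and the differences
#' @export
activation_compare <- function(before, after, roi_mask) {
  stopifnot(inherits(before, "activation_map"),
            inherits(after, "activation_map"))
  if (!identical(dim(before$mask), dim(after$mask)) ||
      !identical(dim(before$mask), dim(roi_mask)))
    stop("activation maps and ROI are not on the same grid")
  if (!any(roi_mask)) stop("empty ROI")
  summarize <- function(m) {
    act <- m$mask
    n_in <- sum(act & roi_mask)
    n_out <- sum(act & !roi_mask)
    vals <- m$statistic[act]
    sizes <- if (any(m$clusters > 0)) tabulate(m$clusters[m$clusters > 0])
             else 0L
    list(n_active = sum(act), n_in_roi = n_in, n_out_roi = n_out,
         sd_active = if (length(vals) > 1) stats::sd(vals) else 0,
         compactness = if (sum(act)) max(sizes) / sum(act) else 0)
  }
  b <- summarize(before)
  a <- summarize(after)
  list(before = b, after = a,
       delta_out_roi = a$n_out_roi - b$n_out_roi,
       delta_sd = a$sd_active - b$sd_active,
       delta_compactness = a$compactness - b$compactness)
}

#' Bartlett's test of homogeneity of variance
#'
#' `T = ((N - k) ln s_p^2 - sum (n_i - 1) ln s_i^2) / C` with the usual
#' correction factor
#' `C = 1 + (sum 1/(n_i - 1) - 1/(N - k)) / (3 (k - 1))`, referred to a
#' chi-square with `k - 1` degrees of freedom.
#'
#' @param groups list of numeric vectors (k >= 2 groups, each n >= 2)
#' @return list with `statistic`, `df`, `p_value`, `pooled_var`,
#'   `group_vars`
#' @export
bartlett_variance_test <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need a list of at least two groups")
  groups <- lapply(groups, function(g) g[is.finite(g)])
  ni <- vapply(groups, length, integer(1))
  if (any(ni < 2)) stop("each group needs at least 2 values")
  vi <- vapply(groups, stats::var, numeric(1))
  if (any(vi <= 0)) stop("non-positive group variance")
  k <- length(groups)
  N <- sum(ni)
  sp2 <- sum((ni - 1) * vi) / (N - k)
  T0 <- (N - k) * log(sp2) - sum((ni - 1) * log(vi))
  C <- 1 + (sum(1 / (ni - 1)) - 1 / (N - k)) / (3 * (k - 1))
  stat <- T0 / C
  list(statistic = stat, df = k - 1,
       p_value = stats::pchisq(stat, k - 1, lower.tail = FALSE),
       pooled_var = sp2, group_vars = vi)
}

#' Before/after distribution report
#'
#' Fixed-bin histograms on a common grid, medians, variances, and
#' Bartlett's test of variance homogeneity between the two samples - the
#' diagnostic showing whether scaling reduced the spread of activation
#' amplitudes.
#'
#' @param values_before,values_after numeric vectors (>= 10 finite values
#'   each)
#' @param n_bins histogram bins (default 30)
#' @return list with `breaks`, `counts_before`, `counts_after`, `medians`,
#'   `variances`, `bartlett`
#' @export
distribution_report <- function(values_before, values_after, n_bins = 30) {
  vb <- values_before[is.finite(values_before)]
  va <- values_after[is.finite(values_after)]
  if (length(vb) < 10 || length(va) < 10)
    stop("need at least 10 finite values in each sample")
  rng <- range(c(vb, va))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  hb <- graphics::hist(vb, breaks = breaks, plot = FALSE)
  ha <- graphics::hist(va, breaks = breaks, plot = FALSE)
  list(breaks = breaks,
       counts_before = hb$counts, counts_after = ha$counts,
       medians = c(before = stats::median(vb), after = stats::median(va)),
       variances = c(before = stats::var(vb), after = stats::var(va)),
       bartlett = bartlett_variance_test(list(before = vb, after = va)))
}

#' Write a distribution report as TSV (histogram) + JSON (summaries)
#' @param report result of [distribution_report()]
#' @param prefix output prefix (`<prefix>.tsv`, `<prefix>.json`)
#' @export
write_distribution_report <- function(report, prefix) {
  df <- data.frame(bin_lo = utils::head(report$breaks, -1),
                   bin_hi = report$breaks[-1],
                   count_before = report$counts_before,
                   count_after = report$counts_after)
  utils::write.table(df, paste0(prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(medians = as.list(report$medians),
         variances = as.list(report$variances),
         bartlett = report$bartlett[c("statistic", "df", "p_value")]),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
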