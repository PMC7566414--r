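#' Motion quality control
#'
#' A run fails QC if any displacement value exceeds `max_mm` (the 2 mm
#' clinical exclusion rule) or, when the voxel size is supplied, exceeds the
#' smallest voxel dimension (the "one voxel-shift" artifact rule). The rule
#' is applied per value (per volume, per axis), the stricter reading; the
#' per-axis mean absolute displacement is reported alongside for comparison
#' with tabulated summaries.
#'
#' @param trace data.frame with at least columns `x`, `y`, `z` (mm); one row
#'   per volume (or a single summary row)
#' @param max_mm absolute displacement limit in mm (default 2)
#' @param voxel_size_mm optional length-3 voxel size; enables the
#'   one-voxel-shift rule
#' @return list with `decision` ("pass"/"fail"), `offending` (data.frame of
#'   volume, axis, value, limit), `mean_abs` (per-axis mean absolute
#'   displacement), `max_abs`, and the limits applied
#' @export
motion_qc <- function(trace, max_mm = 2, voxel_size_mm = NULL) {
  if (!is.data.frame(trace) || nrow(trace) == 0)
    stop("motion trace must be a non-empty data.frame")
  axes <- intersect(c("x", "y", "z"), names(trace))
  if (length(axes) < 3L)
    stop("malformed motion trace: needs numeric columns x, y, z")
  disp <- as.matrix(trace[, axes])
  if (!is.numeric(disp) || anyNA(disp))
    stop("malformed motion trace: non-numeric or missing displacement values")
  limit <- max_mm
  if (!is.null(voxel_size_mm)) limit <- min(max_mm, min(voxel_size_mm))
  bad <- which(abs(disp) > limit, arr.ind = TRUE)
  offending <- data.frame(
    volume = if (nrow(bad)) bad[, 1] else integer(0),
    axis = if (nrow(bad)) axes[bad[, 2]] else character(0),
    value = if (nrow(bad)) disp[bad] else numeric(0),
    limit = if (nrow(bad)) rep(limit, nrow(bad)) else numeric(0))
  list(decision = if (nrow(bad)) "fail" else "pass",
       offending = offending,
       mean_abs = colMeans(abs(disp)),
       max_abs = apply(abs(disp), 2, max),
       max_mm = max_mm,
       voxel_limit_mm = if (is.null(voxel_size_mm)) NA_real_
                        else min(voxel_size_mm))
}

#' Write a motion QC report as JSON
#' @param qc result of [motion_qc()]
#' @param path output path
#' @export
write_qc_report <- function(qc, path) {
  jsonlite::write_json(qc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Remove per-voxel linear trends
#'
#' Fits and removes the least-squares line over time in every voxel, then
#' restores the temporal mean, so the output has the same per-voxel mean as
#' the input and zero residual slope.
#'
#' @param bold a `bold4d` with at least 3 volumes
#' @return detrended `bold4d` (units unchanged)
#' @export
detrend_linear <- function(bold) {
  stopifnot(inherits(bold, "bold4d"))
  n <- dim(bold)[4]
  if (n < 3) stop("detrending needs at least 3 volumes")
  y <- as_voxel_matrix(bold)
  tc <- seq_len(n) - (n + 1) / 2          # centered time
  slope <- (y %*% tc) / sum(tc^2)
  y <- y - slope %*% rbind(tc)
  voxel_matrix_to_bold(y, bold)
}

#' Brain mask from mean intensity
#'
#' Voxels whose temporal mean exceeds `frac` of the robust maximum (99th
#' percentile of voxel means).
#'
#' @param bold a `bold4d`
#' @param frac fraction of the robust max (default 0.1)
#' @return logical 3D array
#' @export
brain_mask <- function(bold, frac = 0.1) {
  m <- rowMeans(as_voxel_matrix(bold))
  array(m > frac * stats::quantile(m, 0.99, names = FALSE), dim(bold)[1:3])
}

#' Convert to percent signal change
#'
#' `value -> 100 * (value - baseline) / baseline` per voxel. The default
#' baseline is the temporal mean; `baseline = "rest"` uses the mean of the
#' lead-in rest volumes of `design` instead (useful when the response
#' occupies a large fraction of the run and would bias the mean). Voxels
#' outside the mask, or with near-zero baseline, are set to NA.
#'
#' @param bold a raw-units `bold4d` (re-converting percent data is an error)
#' @param mask logical 3D array (default [brain_mask()])
#' @param baseline "mean" or "rest"
#' @param design `block_design`, required for `baseline = "rest"`
#' @return `bold4d` in percent units
#' @export
to_percent_change <- function(bold, mask = brain_mask(bold),
                              baseline = c("mean", "rest"), design = NULL) {
  stopifnot(inherits(bold, "bold4d"))
  baseline <- match.arg(baseline)
  if (bold$units == "pct")
    stop("input is already in percent units; refusing to re-convert")
  y <- as_voxel_matrix(bold)
  if (baseline == "mean") {
    b <- rowMeans(y)
  } else {
    if (is.null(design)) stop("baseline = 'rest' requires a design")
    nrest <- max(2L, floor(design$lead_in_rest_s / design$tr_s))
    b <- rowMeans(y[, seq_len(nrest), drop = FALSE])
  }
  eps <- 1e-6 * max(abs(b))
  ok <- as.vector(mask) & is.finite(b) & b > eps
  if (any(as.vector(mask) & !ok))
    warning(sum(as.vector(mask) & !ok),
            " masked voxel(s) with near-zero baseline were excluded")
  y <- 100 * (y - b) / ifelse(ok, b, NA_real_)
  y[!ok, ] <- NA_real_
  voxel_matrix_to_bold(y, bold, units = "pct")
}

#' Temporal standard deviation map
#'
#' Per-voxel SD over time (denominator N - 1); the signal-variability map
#' computed on breath-hold runs.
#'
#' @param bold a `bold4d` with at least 2 volumes
#' @return 3D numeric array
#' @export
sd_map <- function(bold) {
  stopifnot(inherits(bold, "bold4d"))
  n <- dim(bold)[4]
  if (n < 2) stop("sd_map needs at least 2 volumes")
  y <- as_voxel_matrix(bold)
  m <- rowMeans(y)
  array(sqrt(rowSums((y - m)^2) / (n - 1)), dim(bold)[1:3])
}
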