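#' Block paradigm designs and reference waveforms
#'
#' A `block_design` describes a boxcar task paradigm on the acquisition time
#' grid: a lead-in rest period followed by `n_cycles` repetitions of an
#' ON block (`on_s` seconds) and an OFF block (`off_s` seconds). Volumes are
#' timestamped by acquisition onset, i.e. volume `k` (1-based) is acquired at
#' `(k - 1) * tr_s` seconds. Epochs are half-open intervals
#' `[onset, onset + duration)`.
#'
#' @param lead_in_rest_s lead-in rest duration in seconds (non-negative
#'   multiple of `tr_s`)
#' @param n_cycles number of ON/OFF cycles (>= 0)
#' @param on_s ON-block duration in seconds (positive multiple of `tr_s`)
#' @param off_s OFF-block duration in seconds (positive multiple of `tr_s`)
#' @param tr_s repetition time (seconds per volume), > 0
#' @param condition label for the ON condition
#' @return an object of class `block_design` with fields `tr_s`, `n_volumes`,
#'   `epochs` (data.frame: condition, onset_s, duration_s), `lead_in_rest_s`.
#' @examples
#' d <- build_block_design(30, 3, 30, 30, 3)   # motor/language paradigm
#' bh <- build_block_design(30, 3, 16, 44, 3)  # breath-hold paradigm
#' @export
build_block_design <- function(lead_in_rest_s, n_cycles, on_s, off_s, tr_s,
                               condition = "task") {
  if (!is.numeric(tr_s) || length(tr_s) != 1L || tr_s <= 0)
    stop("tr_s must be a positive scalar")
  if (n_cycles < 0 || n_cycles != round(n_cycles))
    stop("n_cycles must be a non-negative integer")
  chk <- function(x, name, positive = TRUE) {
    if (positive && x <= 0)
      stop(sprintf("%s = %g must be positive", name, x))
    if (x < 0) stop(sprintf("%s = %g must be non-negative", name, x))
    if (abs(x / tr_s - round(x / tr_s)) > 1e-9)
      stop(sprintf("%s = %g s is not a multiple of tr_s = %g s", name, x, tr_s))
  }
  chk(lead_in_rest_s, "lead_in_rest_s", positive = FALSE)
  if (n_cycles > 0) {
    if (on_s <= 0) stop(sprintf("on_s = %g must be positive", on_s))
    if (off_s <= 0) stop(sprintf("off_s = %g must be positive", off_s))
    # the cycle must tile the TR grid; individual blocks need not (the
    # 16 s hold / 44 s recovery cycle at TR 3 s is the canonical case)
    chk(on_s + off_s, "cycle duration (on_s + off_s)")
  }
  total_s <- lead_in_rest_s + n_cycles * (on_s + off_s)
  if (total_s <= 0) stop("design has zero duration")
  n_volumes <- as.integer(round(total_s / tr_s))
  if (n_cycles > 0) {
    onsets <- lead_in_rest_s + (seq_len(n_cycles) - 1L) * (on_s + off_s)
    epochs <- data.frame(condition = condition, onset_s = onsets,
                         duration_s = on_s, stringsAsFactors = FALSE)
  } else {
    epochs <- data.frame(condition = character(0), onset_s = numeric(0),
                         duration_s = numeric(0), stringsAsFactors = FALSE)
  }
  structure(list(tr_s = tr_s, n_volumes = n_volumes, epochs = epochs,
                 lead_in_rest_s = lead_in_rest_s,
                 n_cycles = as.integer(n_cycles),
                 on_s = if (n_cycles > 0) on_s else 0,
                 off_s = if (n_cycles > 0) off_s else 0,
                 condition = condition),
            class = "block_design")
}

#' @export
print.block_design <- function(x, ...) {
  cat(sprintf(
    "block_design: %d volumes @ TR %g s (%g s lead-in, %d x [%g s ON / %g s OFF] '%s')\n",
    x$n_volumes, x$tr_s, x$lead_in_rest_s, x$n_cycles, x$on_s, x$off_s,
    x$condition))
  invisible(x)
}

#' Volume acquisition onset times of a design
#' @param design a `block_design`
#' @return numeric vector of length `n_volumes` (seconds)
#' @export
volume_times <- function(design) {
  (seq_len(design$n_volumes) - 1) * design$tr_s
}

new_waveform <- function(values, label, tr_s, realized_delay_s = 0) {
  structure(list(values = as.numeric(values), label = label, tr_s = tr_s,
                 realized_delay_s = realized_delay_s),
            class = "ref_waveform")
}

#' @export
print.ref_waveform <- function(x, ...) {
  cat(sprintf("ref_waveform '%s': %d volumes @ TR %g s, range [%g, %g]\n",
              x$label, length(x$values), x$tr_s, min(x$values), max(x$values)))
  invisible(x)
}

#' Boxcar reference waveform for a condition
#'
#' Value 1 for volumes whose acquisition onset falls inside an epoch of the
#' condition (half-open `[onset, onset + duration)`), 0 otherwise.
#'
#' @param design a `block_design`
#' @param condition condition label (must exist in the design unless the
#'   design has no epochs at all, in which case the all-zero waveform is
#'   returned)
#' @return a `ref_waveform` with 0/1 values
#' @export
boxcar <- function(design, condition = design$condition) {
  stopifnot(inherits(design, "block_design"))
  ep <- design$epochs
  if (nrow(ep) > 0 && !condition %in% ep$condition)
    stop(sprintf("condition '%s' not present in design", condition))
  tt <- volume_times(design)
  v <- numeric(design$n_volumes)
  ep <- ep[ep$condition == condition, , drop = FALSE]
  for (i in seq_len(nrow(ep))) {
    v[tt >= ep$onset_s[i] & tt < ep$onset_s[i] + ep$duration_s[i]] <- 1
  }
  new_waveform(v, paste0("boxcar:", condition), design$tr_s)
}

#' Shift a waveform later in time
#'
#' Values are moved later by `delay_s` (zero-padded at the start, truncated at
#' the end, length unchanged). Delays that are not a multiple of the TR are
#' rounded to the nearest whole volume; the realized delay is recorded in the
#' result's `realized_delay_s` field.
#'
#' @param w a `ref_waveform`
#' @param delay_s non-negative delay in seconds; must be shorter than the run
#' @param tr_s sampling interval; defaults to the waveform's own TR
#' @return shifted `ref_waveform`
#' @export
shift_waveform <- function(w, delay_s, tr_s = w$tr_s) {
  stopifnot(inherits(w, "ref_waveform"), delay_s >= 0)
  n <- length(w$values)
  if (delay_s >= n * tr_s)
    stop(sprintf("delay %g s is not shorter than the run (%g s)",
                 delay_s, n * tr_s))
  k <- round(delay_s / tr_s)
  realized <- k * tr_s
  if (abs(realized - delay_s) > 1e-9)
    message(sprintf("delay %g s rounded to %g s (%d volumes)",
                    delay_s, realized, k))
  v <- c(numeric(k), w$values)[seq_len(n)]
  new_waveform(v, paste0(w$label, sprintf("+%gs", realized)), tr_s,
               realized_delay_s = w$realized_delay_s + realized)
}

#' Canonical double-gamma hemodynamic response kernel
#'
#' The community-default double-gamma impulse response: a positive gamma
#' density peaking near 5 s minus an undershoot gamma peaking near 15 s with
#' ratio 1/6, evaluated over a 32 s support and sampled at the TR. The kernel
#' is scaled to unit peak so that convolving a unit impulse returns the kernel
#' itself with peak 1.
#'
#' @param tr_s sampling interval in seconds, > 0
#' @param duration_s kernel support in seconds (default 32)
#' @return numeric vector of kernel samples at `t = 0, tr_s, 2 tr_s, ...`
#' @export
canonical_hrf <- function(tr_s, duration_s = 32) {
  stopifnot(tr_s > 0)
  t <- seq(0, duration_s, by = tr_s)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Convolve a boxcar with an HRF kernel
#'
#' Causal discrete convolution truncated to the run length, then rescaled to
#' unit peak (so GLM betas against the regressor read directly in percent
#' signal change). An all-zero input stays all-zero.
#'
#' @param w a `ref_waveform` (typically a boxcar)
#' @param kernel HRF samples at the waveform's TR (default
#'   `canonical_hrf(w$tr_s)`)
#' @return a `ref_waveform` regressor with unit peak
#' @export
convolve_regressor <- function(w, kernel = canonical_hrf(w$tr_s)) {
  stopifnot(inherits(w, "ref_waveform"))
  n <- length(w$values)
  full <- stats::convolve(c(w$values, numeric(length(kernel))),
                          rev(kernel), type = "open")
  v <- full[seq_len(n)]
  pk <- max(abs(v))
  if (pk > 0) v <- v / pk
  out <- new_waveform(v, paste0(w$label, "*hrf"), w$tr_s, w$realized_delay_s)
  out$peak_scale <- pk
  out
}

#' Breath-hold GLM regressor with onset delay
#'
#' The breath-hold boxcar is delayed by `delay_s` (default 8 s, the BOLD
#' response delay of breath-hold) rounded to the nearest volume, then convolved
#' with the canonical HRF and rescaled to unit peak. At TR = 3 s the 8 s delay
#' is realized as 9 s (3 volumes); the realized delay is recorded on the
#' returned waveform.
#'
#' @param design a breath-hold `block_design`
#' @param tr_s sampling interval (defaults to the design TR)
#' @param delay_s onset delay in seconds (default 8)
#' @return a `ref_waveform` regressor
#' @export
bh_delayed_regressor <- function(design, tr_s = design$tr_s, delay_s = 8) {
  b <- boxcar(design)
  if (all(b$values == 0)) return(new_waveform(b$values, "bh_regressor", tr_s))
  if (delay_s > 0) b <- shift_waveform(b, delay_s, tr_s)
  out <- convolve_regressor(b)
  out$label <- "bh_regressor"
  out
}

#' Serialize a design to / from a JSON config
#'
#' @param design a `block_design`
#' @param path file path
#' @return `read_design` returns a `block_design`
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "block_design"))
  cfg <- list(tr_s = design$tr_s, lead_in_rest_s = design$lead_in_rest_s,
              cycles = design$n_cycles, on_s = design$on_s,
              off_s = design$off_s, condition = design$condition)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("tr_s", "lead_in_rest_s", "cycles", "on_s", "off_s")
  if (!all(need %in% names(cfg)))
    stop("design config missing keys: ",
         paste(setdiff(need, names(cfg)), collapse = ", "))
  build_block_design(cfg$lead_in_rest_s, cfg$cycles, cfg$on_s, cfg$off_s,
                     cfg$tr_s,
                     condition = if (is.null(cfg$condition)) "task"
                                 else cfg$condition)
}

#' Export a waveform as a two-column TSV (time_s, value)
#' @param w a `ref_waveform`
#' @param path file path
#' @export
write_waveform_tsv <- function(w, path) {
  stopifnot(inherits(w, "ref_waveform"))
  df <- data.frame(time_s = (seq_along(w$values) - 1) * w$tr_s,
                   value = w$values)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
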