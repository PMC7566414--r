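#' 4D BOLD container
#'
#' A `bold4d` wraps a 4D array (x, y, z, time) with voxel size, TR and a units
#' tag. Units are tracked so that stages which require percent-signal-change
#' input (gamma fitting, GLM) can reject raw-intensity data.
#'
#' @param data 4D numeric array
#' @param voxel_size_mm length-3 voxel dimensions in mm
#' @param tr_s repetition time in seconds
#' @param units "raw" or "pct"
#' @return object of class `bold4d`
#' @export
bold4d <- function(data, voxel_size_mm = c(2.5, 2.5, 3), tr_s = 3,
                   units = "raw") {
  if (length(dim(data)) != 4L) stop("bold4d requires a 4D array")
  stopifnot(length(voxel_size_mm) == 3L, tr_s > 0,
            units %in% c("raw", "pct"))
  structure(list(data = data, voxel_size_mm = as.numeric(voxel_size_mm),
                 tr_s = tr_s, units = units),
            class = "bold4d")
}

#' @export
print.bold4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("bold4d: %d x %d x %d voxels x %d volumes, TR %g s, units '%s'\n",
              d[1], d[2], d[3], d[4], x$tr_s, x$units))
  invisible(x)
}

#' @export
dim.bold4d <- function(x) dim(x$data)

# Flatten voxels to a V x T matrix (V in array order).
as_voxel_matrix <- function(bold) {
  d <- dim(bold$data)
  matrix(bold$data, nrow = prod(d[1:3]), ncol = d[4])
}

voxel_matrix_to_bold <- function(mat, template, units = template$units) {
  d <- dim(template$data)
  bold4d(array(mat, dim = d), template$voxel_size_mm, template$tr_s, units)
}

# ---------------------------------------------------------------------------
# Minimal single-file NIfTI-1 (.nii) I/O.
#
# No NIfTI package is available in this environment, so the format is handled
# directly: 348-byte header + 4-byte extender, float32 data, diagonal sform
# built from the voxel size, TR stored in pixdim[4] (time step). Little-endian
# on disk; big-endian files are byte-swapped on read.
# ---------------------------------------------------------------------------

nifti_write <- function(arr, path, voxel_size_mm, tr_s = 0) {
  nd <- length(dim(arr))
  if (!nd %in% c(3L, 4L)) stop("nifti_write supports 3D or 4D arrays")
  dims <- dim(arr)
  con <- file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348L)                        # sizeof_hdr
  w_raw(36L)                         # data_type[10], db_name[18], extents,
                                     # session_error, regular, dim_info
  dim8 <- c(nd, dims, rep(1L, 7 - nd))
  w_i16(dim8)                        # dim[8]
  w_f32(c(0, 0, 0))                  # intent_p1..p3
  w_i16(0L)                          # intent_code
  w_i16(16L)                         # datatype: float32
  w_i16(32L)                         # bitpix
  w_i16(0L)                          # slice_start
  pixdim <- c(1, voxel_size_mm, tr_s, 0, 0, 0)
  w_f32(pixdim)                      # pixdim[8]
  w_f32(352)                         # vox_offset
  w_f32(c(1, 0))                     # scl_slope, scl_inter
  w_i16(0L)                          # slice_end
  writeBin(as.raw(c(0L, 10L)), con)  # slice_code; xyzt_units = mm | sec
  w_f32(c(0, 0))                     # cal_max, cal_min
  w_f32(c(0, 0))                     # slice_duration, toffset
  w_i32(c(0L, 0L))                   # glmax, glmin
  w_raw(104L)                        # descrip[80] + aux_file[24]
  w_i16(c(0L, 1L))                   # qform_code=0, sform_code=1
  w_f32(rep(0, 6))                   # quatern b,c,d + qoffset x,y,z
  w_f32(c(voxel_size_mm[1], 0, 0, 0))  # srow_x
  w_f32(c(0, voxel_size_mm[2], 0, 0))  # srow_y
  w_f32(c(0, 0, voxel_size_mm[3], 0))  # srow_z
  w_raw(16L)                         # intent_name[16]
  writeChar("n+1", con, nchars = 3, eos = NULL); w_raw(1L)  # magic
  w_raw(4L)                          # extender
  writeBin(as.numeric(arr), con, size = 4, endian = "little")
  invisible(path)
}

nifti_read <- function(path) {
  if (!file.exists(path)) stop("cannot read NIfTI file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- "little"
  hdrsize <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (hdrsize != 348L) {
    endian <- "big"
    seek(con, 0)
    hdrsize <- readBin(con, "integer", 1, size = 4, endian = endian)
    if (hdrsize != 348L)
      stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  seek(con, 40)
  dim8 <- readBin(con, "integer", 8, size = 2, endian = endian)
  nd <- dim8[1]
  if (!nd %in% c(3L, 4L)) stop("expected a 3D or 4D NIfTI, got ", nd, "D")
  dims <- dim8[2:(1 + nd)]
  seek(con, 70)
  datatype <- readBin(con, "integer", 1, size = 2, endian = endian)
  seek(con, 76)
  pixdim <- readBin(con, "numeric", 8, size = 4, endian = endian)
  vox_offset <- readBin(con, "numeric", 1, size = 4, endian = endian)
  scl <- readBin(con, "numeric", 2, size = 4, endian = endian)
  n <- prod(dims)
  seek(con, round(vox_offset))
  vals <- switch(as.character(datatype),
    "16" = readBin(con, "numeric", n, size = 4, endian = endian),
    "64" = readBin(con, "numeric", n, size = 8, endian = endian),
    "4"  = readBin(con, "integer", n, size = 2, endian = endian),
    "8"  = readBin(con, "integer", n, size = 4, endian = endian),
    "2"  = readBin(con, "integer", n, size = 1, signed = FALSE,
                   endian = endian),
    stop("unsupported NIfTI datatype: ", datatype))
  if (length(vals) < n) stop("truncated NIfTI data in ", path)
  if (scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0))
    vals <- vals * scl[1] + scl[2]
  list(data = array(as.numeric(vals), dim = dims),
       voxel_size_mm = pixdim[2:4], tr_s = pixdim[5])
}

#' Write / read a 4D BOLD run as NIfTI-1
#'
#' Single-file uncompressed `.nii`, float32, with the TR in the time pixdim
#' slot and a diagonal sform affine from the voxel size. The units tag is not
#' part of NIfTI; `read_run` takes it as an argument (default "raw").
#'
#' @param bold a `bold4d`
#' @param path output `.nii` path
#' @export
write_run <- function(bold, path) {
  stopifnot(inherits(bold, "bold4d"))
  nifti_write(bold$data, path, bold$voxel_size_mm, bold$tr_s)
}

#' @rdname write_run
#' @param units units tag to attach on read ("raw" or "pct")
#' @export
read_run <- function(path, units = "raw") {
  x <- nifti_read(path)
  if (length(dim(x$data)) != 4L)
    stop("expected a 4D run, got ", length(dim(x$data)), "D: ", path)
  bold4d(x$data, x$voxel_size_mm, x$tr_s, units)
}

#' Write / read a 3D map as NIfTI-1
#' @param map 3D numeric array
#' @param path `.nii` path
#' @param voxel_size_mm voxel dimensions
#' @export
write_map <- function(map, path, voxel_size_mm = c(2.5, 2.5, 3)) {
  if (length(dim(map)) != 3L) stop("write_map requires a 3D array")
  storage.mode(map) <- "double"
  nifti_write(map, path, voxel_size_mm, 0)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  x <- nifti_read(path)
  if (length(dim(x$data)) != 3L)
    stop("expected a 3D map, got ", length(dim(x$data)), "D: ", path)
  structure(x$data, voxel_size_mm = x$voxel_size_mm)
}

#' Write / read a motion trace TSV
#'
#' Six columns per volume: translations `x`, `y`, `z` (mm) and rotations
#' `pitch`, `roll`, `yaw` (degrees), with a header row.
#'
#' @param trace data.frame with columns x, y, z, pitch, roll, yaw
#' @param path TSV path
#' @export
write_motion_trace <- function(trace, path) {
  need <- c("x", "y", "z", "pitch", "roll", "yaw")
  if (!all(need %in% names(trace)))
    stop("motion trace must have columns: ", paste(need, collapse = ", "))
  utils::write.table(trace[, need], path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_motion_trace
#' @export
read_motion_trace <- function(path) {
  tr <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("x", "y", "z") %in% names(tr)))
    stop("malformed motion trace (needs at least x, y, z columns): ", path)
  tr
}
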