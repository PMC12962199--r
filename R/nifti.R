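# Minimal NIfTI-1 single-file (.nii) I/O. No NIfTI package is available in
# the target environment, so the subset needed here — uncompressed 2D/3D/4D
# float32/float64/uint8 volumes with pixel dimensions — is implemented
# directly against the NIfTI-1 header layout (348-byte header, vox_offset
# 352). Data are stored in little-endian order. This is deliberately not a
# general-purpose reader: scaling slopes, extensions and orientation codes
# beyond pixdim are ignored on read.

NIFTI_DTYPES <- c(uint8 = 2L, float32 = 16L, float64 = 64L)
NIFTI_SIZES <- c(uint8 = 1L, float32 = 4L, float64 = 8L)

#' Write an array as a NIfTI-1 file
#'
#' @param data numeric/logical array (2D matrix, 3D or 4D array). Dimension
#'   order is (rows, cols, slices, volumes); a 2D matrix is written as a
#'   single-slice volume.
#' @param path output path ending in `.nii`.
#' @param pixdim_mm voxel size per dimension (mm; time units for dim 4 are
#'   left at 0).
#' @param datatype one of "float32", "float64", "uint8".
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, pixdim_mm = c(1, 1, 1), datatype = "float32") {
  if (is.logical(data)) data <- array(as.numeric(data), dim = dim(data))
  dims <- dim(data)
  if (is.null(dims)) dims <- length(data)
  ndim <- length(dims)
  if (ndim > 7) stop("too many dimensions for NIfTI", call. = FALSE)
  dtype <- match.arg(datatype, names(NIFTI_DTYPES))
  dim_field <- rep(1L, 8)
  dim_field[1] <- ndim
  dim_field[seq_len(ndim) + 1] <- as.integer(dims)
  pixdim_field <- rep(0, 8)
  pixdim_field[2:4] <- c(pixdim_mm, 1, 1, 1)[1:3]

  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)

  wi(348L, 4)                     # sizeof_hdr
  wraw(34)                        # data_type[10], db_name[18], extents, session_error
  writeBin(charToRaw("r"), con)   # regular = 'r'
  wraw(1)                         # dim_info
  wi(dim_field, 2)                # dim[8]
  wf(c(0, 0, 0))                  # intent_p1..p3
  wi(0L, 2)                       # intent_code
  wi(NIFTI_DTYPES[[dtype]], 2)    # datatype
  wi(8L * NIFTI_SIZES[[dtype]], 2) # bitpix
  wi(0L, 2)                       # slice_start
  wf(pixdim_field)                # pixdim[8]
  wf(352)                         # vox_offset
  wf(c(1, 0))                     # scl_slope, scl_inter
  wi(0L, 2); wraw(2)              # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0))                  # cal_max, cal_min, slice_duration
  wf(0)                           # toffset
  wi(c(0L, 0L), 4)                # glmax, glmin
  wraw(80 + 24)                   # descrip, aux_file
  wi(c(0L, 0L), 2)                # qform_code, sform_code
  wf(rep(0, 6))                   # quatern b,c,d, qoffset x,y,z
  wf(rep(0, 12))                  # srow_x/y/z
  wraw(16)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)  # magic
  wraw(4)                         # extender
  if (dtype == "uint8") {
    writeBin(as.integer(round(data)), con, size = 1, endian = "little")
  } else {
    writeBin(as.numeric(data), con, size = NIFTI_SIZES[[dtype]],
             endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 file written by [write_nifti()]
#'
#' @param path path to an uncompressed `.nii` file.
#' @return numeric array with attribute `pixdim_mm`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n, size) readBin(con, "integer", n = n, size = size, endian = "little")
  rf <- function(n, size = 4) readBin(con, "double", n = n, size = size, endian = "little")
  hdr_size <- ri(1, 4)
  if (length(hdr_size) == 0 || hdr_size != 348) {
    stop("not a NIfTI-1 file (bad header size): ", path, call. = FALSE)
  }
  invisible(readBin(con, "raw", 36))
  dims <- ri(8, 2)
  invisible(rf(3)); invisible(ri(1, 2))
  datatype <- ri(1, 2)
  invisible(ri(1, 2)); invisible(ri(1, 2))
  pixdim <- rf(8)
  vox_offset <- rf(1)
  seek(con, vox_offset)
  ndim <- dims[1]
  shape <- dims[seq_len(ndim) + 1]
  n <- prod(shape)
  data <- switch(as.character(datatype),
    "2" = readBin(con, "integer", n = n, size = 1, signed = FALSE, endian = "little"),
    "4" = readBin(con, "integer", n = n, size = 2, endian = "little"),
    "8" = readBin(con, "integer", n = n, size = 4, endian = "little"),
    "16" = readBin(con, "double", n = n, size = 4, endian = "little"),
    "64" = readBin(con, "double", n = n, size = 8, endian = "little"),
    stop("unsupported NIfTI datatype code: ", datatype, call. = FALSE)
  )
  arr <- array(as.numeric(data), dim = shape)
  attr(arr, "pixdim_mm") <- pixdim[2:4]
  arr
}

#' Write an echo series as NIfTI magnitude/phase pairs plus a JSON sidecar
#'
#' One 4D magnitude file and one 4D phase file per repetition
#' (`mag_rep<r>.nii`, `phase_rep<r>.nii`, echoes along the 4th dimension),
#' plus `sidecar.json` holding the echo-time list (us), spacing and geometry.
#'
#' @param series an `echo_series`.
#' @param dir output directory (created if needed).
#' @return the sidecar path, invisibly.
#' @export
write_echo_series <- function(series, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- series$geometry
  pd <- c(g$pixel_mm, 1)
  for (r in seq_len(series$n_reps)) {
    vol <- series$data[, , , r, drop = FALSE]
    dim(vol) <- c(dim(vol)[1:2], 1L, dim(vol)[3])   # rows, cols, slice, echo
    write_nifti(Mod(vol), file.path(dir, sprintf("mag_rep%d.nii", r)), pd)
    write_nifti(Arg(vol), file.path(dir, sprintf("phase_rep%d.nii", r)), pd)
  }
  sidecar <- file.path(dir, "sidecar.json")
  jsonlite::write_json(list(
    te_list_us = series$te_list, delta_t_us = series$delta_t,
    n_echoes = series$n_echoes, n_reps = series$n_reps,
    matrix = g$matrix, fov_mm = g$fov_mm, slice_y_mm = g$slice_y_mm
  ), sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read an echo series from NIfTI magnitude/phase pairs and a JSON sidecar
#'
#' @param dir directory written by [write_echo_series()].
#' @return an `echo_series`.
#' @export
read_echo_series <- function(dir) {
  sc <- jsonlite::read_json(file.path(dir, "sidecar.json"), simplifyVector = TRUE)
  g <- geometry2d(sc$matrix, sc$fov_mm, sc$slice_y_mm)
  data <- array(complex(real = 0),
                dim = c(g$matrix[1], g$matrix[2], sc$n_echoes, sc$n_reps))
  for (r in seq_len(sc$n_reps)) {
    mag <- read_nifti(file.path(dir, sprintf("mag_rep%d.nii", r)))
    ph <- read_nifti(file.path(dir, sprintf("phase_rep%d.nii", r)))
    for (j in seq_len(sc$n_echoes)) {
      data[, , j, r] <- mag[, , 1, j] * exp(1i * ph[, , 1, j])
    }
  }
  echo_series(data, sc$te_list_us, sc$delta_t_us, g)
}

#' Write phantom ground truth as NIfTI maps
#'
#' @param truth a `phantom_truth`.
#' @param geometry the matching [geometry2d()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_phantom_truth <- function(truth, geometry, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pd <- c(geometry$pixel_mm, 1)
  write_nifti(truth$m0_map, file.path(dir, "m0.nii"), pd)
  write_nifti(truth$t2star_map, file.path(dir, "t2star_us.nii"), pd)
  write_nifti(truth$nu_map, file.path(dir, "nu_hz.nii"), pd)
  write_nifti(truth$phi0_map, file.path(dir, "phi0_rad.nii"), pd)
  write_nifti(truth$lung_mask, file.path(dir, "lung_mask.nii"), pd,
              datatype = "uint8")
  invisible(dir)
}
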