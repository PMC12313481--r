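# Minimal NIfTI-1 I/O (uncompressed .nii, single file).
#
# No NIfTI package ships with this environment, so the pipeline carries its
# own reader/writer for the small subset it needs: 3-D scalar volumes,
# float32 or uint8/uint16/int16/int32/float64 data, pixdim spacing, and a
# canonical RAS-aligned sform. Enough for phantom volumes, masks and
# subregion maps to round-trip and to be readable by nibabel/ITK-SNAP.

nifti_datatypes <- list(
  uint8   = list(code = 2L,   bitpix = 8L,  what = "integer", size = 1L, signed = FALSE),
  int16   = list(code = 4L,   bitpix = 16L, what = "integer", size = 2L, signed = TRUE),
  int32   = list(code = 8L,   bitpix = 32L, what = "integer", size = 4L, signed = TRUE),
  float32 = list(code = 16L,  bitpix = 32L, what = "double",  size = 4L, signed = TRUE),
  float64 = list(code = 64L,  bitpix = 64L, what = "double",  size = 8L, signed = TRUE),
  uint16  = list(code = 512L, bitpix = 16L, what = "integer", size = 2L, signed = FALSE)
)

#' Write a 3-D volume as an uncompressed NIfTI-1 file
#'
#' @param vol 3-D numeric array.
#' @param path output path, conventionally ending in `.nii`.
#' @param spacing voxel spacing in mm (length 3).
#' @param datatype one of `"float32"`, `"float64"`, `"uint8"`, `"uint16"`,
#'   `"int16"`, `"int32"`. Masks and label maps should use an integer type.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, spacing = c(1, 1, 1),
                        datatype = "float32") {
  d <- dim(vol)
  if (is.null(d) || length(d) != 3L) stop("vol must be a 3-D array", call. = FALSE)
  dt <- nifti_datatypes[[datatype]]
  if (is.null(dt)) stop("unsupported datatype: ", datatype, call. = FALSE)
  spacing <- as.numeric(spacing)

  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")

  wi(348L, 4)                                   # sizeof_hdr
  writeBin(raw(35), con)                        # data_type, db_name, extents, session_error, regular=0
  writeBin(as.raw(0L), con)                     # dim_info
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2)              # dim[8]
  wf(c(0, 0, 0))                                # intent_p1..p3
  wi(0L, 2)                                     # intent_code
  wi(dt$code, 2)                                # datatype
  wi(dt$bitpix, 2)                              # bitpix
  wi(0L, 2)                                     # slice_start
  wf(c(1, spacing, 1, 1, 1, 1))                 # pixdim[8] (qfac=1)
  wf(352)                                       # vox_offset
  wf(1); wf(0)                                  # scl_slope, scl_inter
  wi(0L, 2); writeBin(raw(2), con)              # slice_end, slice_code+xyzt_units... (see below)
  # careful with layout: slice_end int16, slice_code char, xyzt_units char
  wf(0); wf(0)                                  # cal_max, cal_min
  wf(0); wf(0)                                  # slice_duration, toffset
  wi(c(0L, 0L), 4)                              # glmax, glmin
  writeBin(raw(80), con)                        # descrip
  writeBin(raw(24), con)                        # aux_file
  wi(0L, 2)                                     # qform_code
  wi(1L, 2)                                     # sform_code
  wf(c(0, 0, 0, 0, 0, 0))                       # quatern b,c,d + qoffset x,y,z
  wf(c(spacing[1], 0, 0, 0))                    # srow_x
  wf(c(0, spacing[2], 0, 0))                    # srow_y
  wf(c(0, 0, spacing[3], 0))                    # srow_z
  writeBin(raw(16), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con) # magic
  writeBin(raw(4), con)                         # extension flag

  vals <- as.vector(vol)
  if (dt$what == "integer") {
    vals <- as.integer(round(vals))
    if (!dt$signed && dt$size == 2L) {
      # writeBin has no unsigned 16-bit: re-encode via signed representation
      vals <- ifelse(vals >= 32768L, vals - 65536L, vals)
    }
    writeBin(vals, con, size = dt$size, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' Read an uncompressed NIfTI-1 file written by this package
#'
#' Supports single-file `.nii` volumes with 3-D data in any of the datatypes
#' [write_nifti()] emits.
#'
#' @param path path to a `.nii` file.
#' @return 3-D array with attribute `spacing` (mm).
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  ri <- function(off, size, n = 1L)
    readBin(hdr[(off + 1L):(off + size * n)], "integer",
            n = n, size = size, endian = "little")
  rf <- function(off, n = 1L)
    readBin(hdr[(off + 1L):(off + 4L * n)], "double",
            n = n, size = 4L, endian = "little")
  if (ri(0L, 4L) != 348L) stop("not a NIfTI-1 file: ", path, call. = FALSE)
  dims <- ri(40L, 2L, 8L)
  if (dims[1L] != 3L) stop("only 3-D NIfTI volumes are supported", call. = FALSE)
  d <- dims[2:4]
  dtcode <- ri(70L, 2L)
  dt <- NULL
  for (nm in names(nifti_datatypes))
    if (nifti_datatypes[[nm]]$code == dtcode) dt <- nifti_datatypes[[nm]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", dtcode, call. = FALSE)
  spacing <- rf(76L, 8L)[2:4]
  vox_offset <- rf(108L)
  seek(con, where = vox_offset, origin = "start")
  n <- prod(d)
  vals <- readBin(con, dt$what, n = n, size = dt$size,
                  signed = dt$signed || dt$size > 2L, endian = "little")
  vol <- array(vals, dim = d)
  attr(vol, "spacing") <- spacing
  vol
}

#' Write a DCE series as one NIfTI file per phase
#'
#' Files are named `<prefix>_phase00.nii` (pre-contrast) through
#' `<prefix>_phaseNN.nii` with zero-padded phase indices.
#'
#' @param series a [dce_series()].
#' @param dir output directory (created if missing).
#' @param prefix filename prefix.
#' @return character vector of written paths, invisibly.
#' @export
write_dce_series <- function(series, dir, prefix = "dce") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- length(series$phases)
  paths <- file.path(dir, sprintf("%s_phase%02d.nii", prefix, seq_len(n) - 1L))
  for (i in seq_len(n))
    write_nifti(series$phases[[i]], paths[i], spacing = series$spacing)
  invisible(paths)
}
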