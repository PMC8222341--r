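# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# The target environment ships no NIfTI package, so the small subset of the
# format this package needs is implemented here: 3D images, scalar dtypes
# (uint8, int16, int32, uint16, float32, float64), pixdim voxel spacing, and
# the scl_slope/scl_inter intensity transform.  Orientation metadata
# (qform/sform) is written as an identity scaled by the spacing and ignored
# on read: volumes are treated on their voxel grid, which is all the
# downstream pipeline requires of co-registered phases.

NIFTI_DTYPES <- list(
  `2`   = list(what = "integer", size = 1, signed = FALSE),
  `4`   = list(what = "integer", size = 2, signed = TRUE),
  `8`   = list(what = "integer", size = 4, signed = TRUE),
  `16`  = list(what = "double",  size = 4, signed = TRUE),
  `64`  = list(what = "double",  size = 8, signed = TRUE),
  `512` = list(what = "integer", size = 2, signed = FALSE)
)

#' Read a 3D NIfTI-1 volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return list with `data` (3D numeric array) and `spacing` (dx, dy, dz in mm).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("not a NIfTI-1 file: ", path)
  endian <- "little"
  sz <- readBin(hdr_raw[1:4], "integer", size = 4, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr_raw[1:4], "integer", size = 4, endian = endian)
    if (sz != 348L) stop("not a NIfTI-1 file: ", path)
  }
  rd <- function(off, what, size, n = 1L, signed = TRUE) {
    readBin(hdr_raw[(off + 1L):(off + n * size)], what,
            size = size, n = n, endian = endian, signed = signed)
  }
  dim8 <- rd(40, "integer", 2, 8)
  datatype <- rd(70, "integer", 2)
  pixdim <- rd(76, "double", 4, 8)
  vox_offset <- rd(108, "double", 4)
  scl_slope <- rd(112, "double", 4)
  scl_inter <- rd(116, "double", 4)
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file: ", path)
  ndim <- dim8[1]
  if (ndim < 3L) stop("expected a 3D volume: ", path)
  dims <- dim8[2:(ndim + 1L)]
  if (ndim > 3L && any(dims[4:length(dims)] > 1L))
    stop("expected a 3D volume: ", path)
  dims <- dims[1:3]

  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype: ", datatype)
  # skip to the data (vox_offset counts from file start)
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n <- prod(dims)
  vals <- readBin(con, dt$what, n = n, size = dt$size, endian = endian,
                  signed = dt$signed)
  if (length(vals) != n) stop("truncated NIfTI data: ", path)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(data = array(vals, dim = dims),
       spacing = abs(pixdim[2:4]))
}

#' Write a 3D volume as NIfTI-1
#'
#' Data are stored as float64 (or uint8 when `data` is a logical/binary
#' mask), with voxel spacing in `pixdim` and an axis-aligned sform.
#'
#' @param data 3D numeric or logical array.
#' @param path output path; compressed when it ends in `.gz`.
#' @param spacing voxel spacing (dx, dy, dz) in mm.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, spacing = c(1, 1, 1)) {
  stopifnot(length(dim(data)) == 3L, length(spacing) == 3L)
  binary <- is.logical(data) || all(data %in% c(0, 1))
  datatype <- if (binary) 2L else 64L
  bitpix <- if (binary) 8L else 64L

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(x, con, size = size, endian = "little")
  w(348L, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                       # data_type..regular, dim_info
  w(as.integer(c(3L, dim(data), 1L, 1L, 1L, 1L)), 2)  # dim[8]
  w(numeric(3), 4)                             # intent_p1..p3
  w(c(0L, datatype, bitpix, 0L), 2)            # intent_code, datatype, bitpix, slice_start
  w(c(1, spacing, 0, 0, 0, 0), 4)              # pixdim[8]
  w(c(352, 0, 0), 4)                           # vox_offset, scl_slope=0, scl_inter
  w(0L, 2)                                     # slice_end
  writeBin(raw(2), con)                        # slice_code, xyzt_units
  w(numeric(4), 4)                             # cal_max, cal_min, slice_duration, toffset
  w(c(0L, 0L), 4)                              # glmax, glmin
  writeBin(raw(104), con)                      # descrip, aux_file
  w(c(0L, 1L), 2)                              # qform_code, sform_code
  w(numeric(6), 4)                             # quatern, qoffset
  w(c(spacing[1], 0, 0, 0), 4)                 # srow_x
  w(c(0, spacing[2], 0, 0), 4)                 # srow_y
  w(c(0, 0, spacing[3], 0), 4)                 # srow_z
  writeBin(raw(16), con)                       # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)  # magic
  writeBin(raw(4), con)                        # extension flag
  if (binary) {
    writeBin(as.integer(data != 0), con, size = 1)
  } else {
    writeBin(as.double(data), con, size = 8, endian = "little")
  }
  invisible(path)
}
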