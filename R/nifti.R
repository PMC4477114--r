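# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
# No NIfTI package ships with this environment, so the format support the
# pipeline needs is implemented here directly against the NIfTI-1 layout:
# a 348-byte header, a 4-byte extension flag, then the voxel data at
# vox_offset. Only the fields the pipeline consumes are interpreted
# (dim, datatype, pixdim, scl_slope/scl_inter, xyzt_units, vox_offset).

.nifti_datatypes <- list(
  `2`   = list(what = "integer", size = 1, signed = FALSE), # uint8
  `4`   = list(what = "integer", size = 2, signed = TRUE),  # int16
  `8`   = list(what = "integer", size = 4, signed = TRUE),  # int32
  `16`  = list(what = "double",  size = 4, signed = TRUE),  # float32
  `64`  = list(what = "double",  size = 8, signed = TRUE),  # float64
  `256` = list(what = "integer", size = 1, signed = TRUE),  # int8
  `512` = list(what = "integer", size = 2, signed = FALSE)  # uint16
)

#' Read a NIfTI-1 image
#'
#' Reads a single-file NIfTI-1 image (`.nii`, optionally gzip-compressed as
#' `.nii.gz`) and returns the voxel array together with the header fields the
#' pipeline uses. Data are returned in the file's native array order
#' (first axis fastest), with `scl_slope`/`scl_inter` scaling applied when
#' present.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with elements `data` (numeric array), `dim` (integer
#'   dimensions), `pixdim` (voxel sizes, time step last), `tr_seconds`
#'   (time step converted to seconds, `NA` for 3D images) and `datatype`
#'   (NIfTI datatype code).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  endian <- "little"
  sizeof_hdr <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  if (!identical(sizeof_hdr, 348L)) {
    endian <- "big"
    alt <- .swap_int32(sizeof_hdr)
    if (!identical(alt, 348L)) stop("not a NIfTI-1 file (sizeof_hdr != 348): ", path)
  }
  readBin(con, "raw", 36L)                                  # skip to dim at offset 40
  dim_field <- readBin(con, "integer", 8L, size = 2L, endian = endian)
  readBin(con, "raw", 14L)                                  # intent_p1..intent_code
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  readBin(con, "integer", 1L, size = 2L, endian = endian)   # bitpix
  readBin(con, "integer", 1L, size = 2L, endian = endian)   # slice_start
  pixdim <- readBin(con, "double", 8L, size = 4L, endian = endian)
  vox_offset <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_slope <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_inter <- readBin(con, "double", 1L, size = 4L, endian = endian)
  readBin(con, "raw", 3L)                                   # slice_end, slice_code
  xyzt_units <- readBin(con, "integer", 1L, size = 1L, signed = FALSE)
  pos <- 124L
  readBin(con, "raw", 344L - pos)
  magic <- rawToChar(readBin(con, "raw", 4L)[1:3])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file (bad magic): ", path)
  if (magic == "ni1") stop("two-file (.hdr/.img) NIfTI not supported: ", path)

  ndim <- dim_field[1]
  if (ndim < 1L || ndim > 7L) stop("invalid NIfTI dim[0]: ", ndim)
  dims <- pmax(dim_field[2:(1 + ndim)], 1L)
  spec <- .nifti_datatypes[[as.character(datatype)]]
  if (is.null(spec)) stop("unsupported NIfTI datatype code: ", datatype)

  # seek to vox_offset relative to current position (348 bytes consumed)
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", skip)
  n <- prod(dims)
  vals <- readBin(con, spec$what, n, size = spec$size, signed = spec$signed,
                  endian = endian)
  if (length(vals) != n) stop("truncated NIfTI data in ", path)
  vals <- as.double(vals)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  arr <- array(vals, dim = dims)

  tr <- NA_real_
  if (ndim >= 4L) {
    tr <- pixdim[5]
    tunit <- bitwAnd(xyzt_units, 0x38L)
    if (tunit == 16L) tr <- tr / 1000      # msec
    else if (tunit == 24L) tr <- tr / 1e6  # usec
  }
  list(data = arr, dim = dims, pixdim = pixdim[2:(1 + ndim)],
       tr_seconds = tr, datatype = datatype)
}

#' Write a NIfTI-1 image
#'
#' Writes a numeric array as a single-file NIfTI-1 image. Arrays are written
#' in native order; `.nii.gz` paths are gzip-compressed automatically.
#'
#' @param data Numeric array with 1 to 7 dimensions.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param tr_seconds Time step for the 4th dimension, in seconds (stored in
#'   `pixdim[4]` with second time units). Ignored for 3D images.
#' @param voxdim Voxel sizes for the three spatial axes, in mm.
#' @param datatype `"float32"` (default) or `"float64"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, tr_seconds = NULL, voxdim = c(1, 1, 1),
                        datatype = c("float32", "float64")) {
  datatype <- match.arg(datatype)
  dims <- dim(data)
  if (is.null(dims)) dims <- length(data)
  ndim <- length(dims)
  if (ndim > 7L) stop("NIfTI supports at most 7 dimensions")
  dt_code <- if (datatype == "float32") 16L else 64L
  bitpix <- if (datatype == "float32") 32L else 64L
  size <- bitpix %/% 8L

  dim_field <- rep(1L, 8L)
  dim_field[1] <- ndim
  dim_field[2:(1 + ndim)] <- as.integer(dims)
  pixdim <- rep(1, 8)
  pixdim[1] <- 1
  pixdim[2:4] <- voxdim[seq_len(min(3, length(voxdim)))]
  if (ndim >= 4L) pixdim[5] <- if (is.null(tr_seconds)) 1 else tr_seconds

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4L)                      # sizeof_hdr
  writeBin(raw(36L), con)                             # unused through offset 40
  writeBin(dim_field, con, size = 2L)                 # dim
  writeBin(raw(14L), con)                             # intent fields
  writeBin(dt_code, con, size = 2L)                   # datatype
  writeBin(bitpix, con, size = 2L)                    # bitpix
  writeBin(0L, con, size = 2L)                        # slice_start
  writeBin(pixdim, con, size = 4L)                    # pixdim
  writeBin(352, con, size = 4L)                       # vox_offset
  writeBin(1, con, size = 4L)                         # scl_slope
  writeBin(0, con, size = 4L)                         # scl_inter
  writeBin(raw(3L), con)                              # slice_end, slice_code
  writeBin(as.raw(bitwOr(2L, 8L)), con)               # xyzt_units: mm | sec
  writeBin(raw(344L - 124L), con)                     # cal_max .. intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)      # magic
  writeBin(raw(4L), con)                              # no extensions
  writeBin(as.double(data), con, size = size)
  invisible(path)
}

.swap_int32 <- function(x) {
  b <- writeBin(as.integer(x), raw(), size = 4L)
  readBin(rev(b), "integer", 1L, size = 4L)
}
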