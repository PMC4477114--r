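# Volume4D: one subject's masked 4D scan plus repetition time. Every spatial
# and temporal operation in the pipeline consumes this container, and all
# voxel statistics are computed over in-mask voxels only, flattened in the
# array's native order.

#' Construct a Volume4D
#'
#' @param data 4D numeric array (X x Y x Z x T).
#' @param tr_seconds Positive repetition time in seconds.
#' @param mask Optional 3D logical/0-1 array matching the spatial grid.
#'   Defaults to voxels whose time series has nonzero variance.
#' @return An object of class `volume4d` with fields `data`, `tr_seconds`,
#'   `mask`.
#' @export
volume4d <- function(data, tr_seconds, mask = NULL) {
  if (length(dim(data)) != 4L) stop("not a 4D time series")
  if (dim(data)[4] < 2L) stop("need at least 2 time points")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || !is.finite(tr_seconds) ||
      tr_seconds <= 0) {
    stop("non-positive TR")
  }
  sdim <- dim(data)[1:3]
  if (is.null(mask)) {
    v <- matrix(data, prod(sdim), dim(data)[4])
    mask <- array(matrixStats_rowVars(v) > 0, dim = sdim)
  } else {
    mask <- array(as.logical(mask != 0), dim = dim(mask))
    if (!identical(dim(mask), sdim)) stop("mask shape does not match data")
  }
  structure(list(data = data, tr_seconds = as.numeric(tr_seconds), mask = mask),
            class = "volume4d")
}

# rowVars without a matrixStats dependency
matrixStats_rowVars <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

#' @export
print.volume4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume4d: %d x %d x %d grid, %d volumes, TR = %g s, %d in-mask voxels\n",
              d[1], d[2], d[3], d[4], x$tr_seconds, sum(x$mask)))
  invisible(x)
}

#' Read a 4D NIfTI file as a Volume4D
#'
#' @param path Path to a 4D `.nii`/`.nii.gz` file.
#' @param mask_path Optional path to a 3D mask image; nonzero voxels are
#'   in-mask. When absent the mask defaults to nonzero-variance voxels.
#' @param tr_seconds Optional TR override; otherwise taken from the file's
#'   time-step metadata.
#' @return A [volume4d()] object.
#' @export
read_volume4d <- function(path, mask_path = NULL, tr_seconds = NULL) {
  img <- read_nifti(path)
  if (length(img$dim) != 4L) stop("not a 4D time series: ", path)
  tr <- if (!is.null(tr_seconds)) tr_seconds else img$tr_seconds
  if (is.na(tr) || tr <= 0) stop("non-positive TR in ", path,
                                 " (override with tr_seconds)")
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- read_nifti(mask_path)
    if (length(m$dim) != 3L) stop("mask is not 3D: ", mask_path)
    mask <- m$data
  }
  volume4d(img$data, tr, mask)
}

#' Write a Volume4D to NIfTI
#'
#' @param vol A [volume4d()] object.
#' @param path Output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume4d <- function(vol, path) {
  write_nifti(vol$data, path, tr_seconds = vol$tr_seconds)
}

# T x V matrix of in-mask voxel series, columns in native flattened voxel order
vol_matrix <- function(vol) {
  d <- dim(vol$data)
  m <- matrix(vol$data, prod(d[1:3]), d[4])
  t(m[as.vector(vol$mask), , drop = FALSE])
}

# inverse of vol_matrix: put a T x V matrix back into a 4D array (out-of-mask 0)
vol_unmatrix <- function(series, mask, template_dim) {
  d <- c(dim(mask), nrow(series))
  out <- matrix(0, prod(dim(mask)), nrow(series))
  out[as.vector(mask), ] <- t(series)
  array(out, dim = d)
}

# put an in-mask voxel vector back into a 3D array (out-of-mask 0)
map_unflatten <- function(values, mask) {
  out <- array(0, dim = dim(mask))
  out[as.vector(mask)] <- values
  out
}
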