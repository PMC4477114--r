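# Temporal preprocessing applied after registration (which is out of scope
# here; phantoms are generated aligned): nuisance regression of motion-like
# parameters plus mean white-matter and CSF signals, then retention of
# frequencies below the low-pass cutoff. Order follows the published chain:
# regression first, filtering second.

#' Mean time series over a tissue mask
#'
#' @param vol A [volume4d()].
#' @param tissue_mask 3D binary array on the volume's grid.
#' @return Numeric vector of length T: the spatial mean over mask voxels at
#'   each time point.
#' @export
extract_tissue_signal <- function(vol, tissue_mask) {
  tissue_mask <- tissue_mask != 0
  if (!identical(dim(tissue_mask), dim(vol$data)[1:3])) {
    stop("tissue mask grid does not match volume")
  }
  if (!any(tissue_mask)) stop("empty tissue mask")
  d <- dim(vol$data)
  m <- matrix(vol$data, prod(d[1:3]), d[4])
  colMeans(m[as.vector(tissue_mask), , drop = FALSE])
}

#' Regress confounds out of a time-series matrix
#'
#' Ordinary least squares with an intercept always included, so residuals
#' are mean-zero and orthogonal to every (demeaned) confound column.
#'
#' @param series_matrix T x V numeric matrix (columns are voxel series).
#' @param confounds T x C numeric matrix; column names are used in error
#'   messages.
#' @return T x V residual matrix.
#' @export
regress_out <- function(series_matrix, confounds) {
  series_matrix <- as.matrix(series_matrix)
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != nrow(series_matrix)) {
    stop("confound rows do not match time points")
  }
  x <- cbind(intercept = 1, confounds)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stop("rank-deficient confounds; dependent column(s): ",
         paste(bad, collapse = ", "))
  }
  series_matrix - x %*% qr.coef(qx, series_matrix)
}

#' Low-pass filter a time-series matrix
#'
#' The default is an ideal FFT-domain brick-wall filter: Fourier
#' coefficients at frequencies at or above `cutoff_hz` are zeroed, DC is
#' retained, and frequencies strictly below the cutoff pass unchanged. It
#' is linear and exactly idempotent. An order-4 Butterworth (applied
#' forward and backward for zero phase) is available for users who prefer a
#' smooth rolloff.
#'
#' @param series_matrix T x V numeric matrix.
#' @param tr_seconds Sampling interval in seconds.
#' @param cutoff_hz Cutoff frequency; must be below Nyquist `1/(2 tr)`.
#' @param type `"ideal"` (default) or `"butterworth"`.
#' @return Filtered T x V matrix.
#' @export
lowpass_filter <- function(series_matrix, tr_seconds, cutoff_hz,
                           type = c("ideal", "butterworth")) {
  type <- match.arg(type)
  series_matrix <- as.matrix(series_matrix)
  nyquist <- 1 / (2 * tr_seconds)
  if (cutoff_hz >= nyquist) {
    stop(sprintf("cutoff %.4g Hz is at or above Nyquist %.4g Hz",
                 cutoff_hz, nyquist))
  }
  if (type == "butterworth") {
    return(butterworth_filtfilt(series_matrix, tr_seconds, cutoff_hz))
  }
  t_points <- nrow(series_matrix)
  freqs <- seq_len(t_points) - 1L
  freqs <- pmin(freqs, t_points - freqs) / (t_points * tr_seconds)
  keep <- freqs < cutoff_hz
  ft <- stats::mvfft(series_matrix)
  ft[!keep, ] <- 0
  Re(stats::mvfft(ft, inverse = TRUE)) / t_points
}

# order-4 Butterworth low-pass via bilinear transform, applied forward and
# backward (zero phase, squared magnitude response, exact DC gain 1)
butterworth_filtfilt <- function(x, tr_seconds, cutoff_hz, order = 4L) {
  fs <- 1 / tr_seconds
  wc <- tan(pi * cutoff_hz / fs)               # prewarped analog cutoff
  k <- seq_len(order)
  poles_a <- wc * exp(1i * pi * (2 * k + order - 1) / (2 * order))
  poles_z <- (1 + poles_a) / (1 - poles_a)
  a <- Re(poly_from_roots(poles_z))            # denominator, a[1] = 1
  b <- Re(poly_from_roots(rep(-1 + 0i, order)))  # zeros at z = -1
  gain <- sum(a) / sum(b)                      # DC gain 1
  b <- b * gain
  run <- function(m) {
    t_points <- nrow(m)
    y <- matrix(0, t_points, ncol(m))
    xp <- rbind(matrix(rep(m[1, ], each = order), order), m)  # constant padding
    yp <- matrix(rep(m[1, ], each = order), order)
    for (t in seq_len(t_points)) {
      acc <- b[1] * xp[t + order, ]
      for (j in seq_len(order)) {
        xv <- xp[t + order - j, ]
        yv <- if (t - j >= 1L) y[t - j, ] else yp[order + t - j, ]
        acc <- acc + b[j + 1] * xv - a[j + 1] * yv
      }
      y[t, ] <- acc
    }
    y
  }
  fwd <- run(x)
  rev2 <- run(fwd[nrow(fwd):1, , drop = FALSE])
  rev2[nrow(rev2):1, , drop = FALSE]
}

# monic polynomial coefficients from roots (descending powers)
poly_from_roots <- function(r) {
  coefs <- 1 + 0i
  for (root in r) coefs <- c(coefs, 0) - c(0, coefs * root)
  coefs
}

#' Preprocess one subject
#'
#' Chains [extract_tissue_signal()] (WM and CSF means appended to the
#' confound matrix), [regress_out()], and [lowpass_filter()], operating on
#' in-mask voxels only.
#'
#' @param vol A [volume4d()].
#' @param confounds T x C confound matrix (e.g. motion-like series); may be
#'   `NULL` for filtering-only runs.
#' @param wm_mask,csf_mask Optional 3D tissue masks whose mean signals are
#'   appended as confounds.
#' @param cutoff_hz Low-pass cutoff (default 0.08 Hz).
#' @param filter_type Passed to [lowpass_filter()].
#' @return A preprocessed [volume4d()] (same grid, mask and TR).
#' @export
preprocess_subject <- function(vol, confounds = NULL, wm_mask = NULL,
                               csf_mask = NULL, cutoff_hz = 0.08,
                               filter_type = "ideal") {
  conf <- confounds
  if (!is.null(wm_mask)) conf <- cbind(conf, wm = extract_tissue_signal(vol, wm_mask))
  if (!is.null(csf_mask)) conf <- cbind(conf, csf = extract_tissue_signal(vol, csf_mask))
  y <- vol_matrix(vol)
  if (is.null(conf)) {
    y <- sweep(y, 2L, colMeans(y))
  } else {
    y <- regress_out(y, conf)
  }
  y <- lowpass_filter(y, vol$tr_seconds, cutoff_hz, type = filter_type)
  volume4d(vol_unmatrix(y, vol$mask, dim(vol$data)), vol$tr_seconds, vol$mask)
}
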