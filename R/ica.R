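# Temporally concatenated group spatial ICA. Subjects' voxel series are
# variance-normalized, stacked along time, PCA-reduced to the requested
# model order, and unmixed with a fixed-point (FastICA-style) algorithm
# using the logcosh contrast. Components are spatial maps (independent over
# voxels) with a temporal mixing matrix; each map is z-scored over the mask
# and sign-oriented so its skewness is non-negative.

#' Stack subjects into a concatenated group matrix
#'
#' Each subject's block is voxelwise variance-normalized (demeaned, unit
#' SD per voxel) before stacking, so high-variance subjects cannot dominate
#' the group decomposition.
#'
#' @param volumes List of [volume4d()] objects on identical grids/masks.
#' @return (sum of T) x V matrix; attribute `block_rows` records each
#'   subject's row range.
#' @export
concatenate_subjects <- function(volumes) {
  stopifnot(length(volumes) >= 1L)
  ref_mask <- volumes[[1]]$mask
  blocks <- vector("list", length(volumes))
  for (i in seq_along(volumes)) {
    v <- volumes[[i]]
    if (!identical(dim(v$data)[1:3], dim(ref_mask)) ||
        !identical(v$mask, ref_mask)) {
      stop("grid/mask mismatch at subject ", i)
    }
    y <- vol_matrix(v)
    if (nrow(y) < 2L) stop("subject ", i, " has fewer than 2 time points")
    y <- sweep(y, 2L, colMeans(y))
    sds <- sqrt(colMeans(y^2))
    # voxels with (numerically) no variance carry no signal; zero them
    # rather than amplifying round-off (e.g. confound-file precision
    # residue after nuisance regression) to unit variance
    dead <- sds <= max(sds) * 1e-6
    y[, dead] <- 0
    sds[dead] <- 1
    blocks[[i]] <- sweep(y, 2L, sds, "/")
  }
  out <- do.call(rbind, blocks)
  ends <- cumsum(vapply(blocks, nrow, 0L))
  attr(out, "block_rows") <- cbind(start = c(1L, utils::head(ends, -1) + 1L),
                                   end = ends)
  out
}

#' Z-score a spatial map over a mask
#'
#' Normalizes each in-mask voxel's intensity with respect to all in-mask
#' voxels of the map: `(v - mean) / sd`, using the population (1/N) SD.
#' Out-of-mask voxels are set to 0.
#'
#' @param map 3D numeric array.
#' @param mask 3D binary array; at least 2 in-mask voxels with nonzero
#'   spread.
#' @return Z-scored 3D array.
#' @export
zscore_map <- function(map, mask) {
  mask <- mask != 0
  v <- map[mask]
  if (length(v) < 2L) stop("need at least 2 in-mask voxels")
  mu <- mean(v)
  sdev <- sqrt(mean((v - mu)^2))
  if (sdev == 0) stop("zero in-mask variance; cannot z-score a constant map")
  out <- array(0, dim = dim(map))
  out[mask] <- (v - mu) / sdev
  out
}

#' Fit group spatial ICA
#'
#' PCA reduction of the concatenated matrix to `n_components`, then
#' symmetric fixed-point ICA with the logcosh contrast on the whitened
#' spatial data. Restarts up to 5 times with derived seeds on
#' non-convergence; if no restart reaches the tolerance (typical when the
#' model order exceeds the true source rank, so some components are pure
#' noise), the lowest-delta iterate is returned with a warning, matching
#' the behavior of packaged FastICA implementations.
#'
#' @param concatenated (sum of T) x V matrix from [concatenate_subjects()].
#' @param n_components Model order K (<= min(rows, columns)).
#' @param seed Integer seed (initial unmixing rotation).
#' @param mask 3D mask used to fold maps back into volumes.
#' @param max_iter,tol Fixed-point iteration controls (tol on the change in
#'   the unmixing rotation, the usual 1e-4 of packaged FastICA
#'   implementations).
#' @return A `group_ics` list: `maps` (K z-scored 3D arrays), `mixing`
#'   ((sum of T) x K), `n_components`, `explained_variance`,
#'   `map_matrix` (K x V z-scored, for internal reuse), `mask`.
#' @export
fit_spatial_ica <- function(concatenated, n_components, seed = 1L, mask,
                            max_iter = 500L, tol = 1e-4) {
  x <- as.matrix(concatenated)
  nt <- nrow(x)
  nv <- ncol(x)
  k <- as.integer(n_components)
  if (k > min(nt, nv)) stop("n_components exceeds min(time, voxels)")
  x <- sweep(x, 2L, colMeans(x))

  red <- pca_reduce(x, k, seed = derive_seed(seed, "pca"))
  # whitened spatial data: K x V, rows orthonormal * sqrt(V)
  z <- red$scores
  total_var <- sum(x^2)
  explained <- red$values / sum(red$all_values)

  # When the model order exceeds the data's true source rank, the extra
  # components sit in a Gaussian noise subspace where the fixed point has no
  # stable solution; packaged FastICA tools return the current estimate with
  # a warning in that case, and so do we (after restarts), using the
  # lowest-delta iterate seen.
  s <- NULL
  best <- NULL
  converged <- FALSE
  for (restart in 0:4) {
    rseed <- if (restart == 0) seed else derive_seed(seed, paste0("restart", restart))
    local_rng(rseed)
    w <- qr.Q(qr(matrix(stats::rnorm(k * k), k, k)))
    res <- fastica_symmetric(z, w, max_iter = max_iter, tol = tol)
    if (is.null(best) || res$best_delta < best$best_delta) best <- res
    if (res$converged) {
      best <- res
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf(paste0("ICA did not fully converge after 5 restarts of %d ",
                           "iterations (best delta %.2e > tol %.1e); ",
                           "returning the best iterate"),
                    max_iter, best$best_delta, tol))
  }
  w <- best$best_w
  s <- w %*% z

  # orient: non-negative skewness per component
  skew <- rowMeans(s^3)
  flip <- ifelse(skew < 0, -1, 1)
  s <- s * flip
  # mixing: least-squares fit of the data on the source maps
  mixing <- x %*% t(s) %*% solve(tcrossprod(s))

  maps <- vector("list", k)
  map_matrix <- matrix(0, k, nv)
  for (j in seq_len(k)) {
    m3 <- map_unflatten(s[j, ], mask)
    zm <- zscore_map(m3, mask)
    maps[[j]] <- zm
    map_matrix[j, ] <- zm[mask != 0]
  }
  structure(list(maps = maps, mixing = mixing, n_components = k,
                 explained_variance = explained, map_matrix = map_matrix,
                 mask = mask != 0, reduced = red),
            class = "group_ics")
}

# PCA reduction of an n x V matrix to K spatial components.
# Returns scores: K x V whitened spatial data (rows: mean 0, variance 1
# across voxels, mutually uncorrelated).
pca_reduce <- function(x, k, seed = 1L) {
  nt <- nrow(x)
  nv <- ncol(x)
  if (nt <= 2000L) {
    cc <- tcrossprod(x)                       # n x n
    ev <- eigen(cc, symmetric = TRUE)
    vals <- ev$values
    u <- ev$vectors[, seq_len(k), drop = FALSE]
    d <- sqrt(pmax(vals[seq_len(k)], .Machine$double.eps))
    scores <- t(u) %*% x                      # K x V, row j has norm d_j
    scores <- scores / d * sqrt(nv)
    list(scores = scores, values = vals[seq_len(k)], all_values = pmax(vals, 0),
         basis = u)
  } else {
    # seeded randomized range finder (Halko et al. style), 2 power iterations
    local_rng(seed)
    p <- min(nv, k + 10L)
    omega <- matrix(stats::rnorm(nv * p), nv, p)
    y <- x %*% omega
    for (it in 1:2) {
      y <- qr.Q(qr(y))
      y <- x %*% crossprod(x, y)
    }
    q <- qr.Q(qr(y))
    b <- crossprod(q, x)                      # p x V
    sb <- svd(b, nu = k, nv = 0)
    u <- q %*% sb$u
    d <- sb$d[seq_len(k)]
    scores <- t(u) %*% x
    scores <- scores / d * sqrt(nv)
    all_vals <- rep(0, min(nt, nv))
    all_vals[seq_along(sb$d)] <- sb$d^2
    # approximate spectrum tail with the residual energy spread uniformly
    resid <- max(sum(x^2) - sum(sb$d^2), 0)
    if (length(all_vals) > length(sb$d)) {
      all_vals[(length(sb$d) + 1):length(all_vals)] <-
        resid / (length(all_vals) - length(sb$d))
    }
    list(scores = scores, values = d[seq_len(k)]^2, all_values = all_vals,
         basis = u)
  }
}

# symmetric fixed-point ICA with logcosh contrast on whitened K x V data
fastica_symmetric <- function(z, w, max_iter = 500L, tol = 1e-4) {
  k <- nrow(z)
  nv <- ncol(z)
  sym_decorrelate <- function(w) {
    e <- eigen(tcrossprod(w), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, .Machine$double.eps)), k) %*%
      t(e$vectors) %*% w
  }
  w <- sym_decorrelate(w)
  it <- 0L
  converged <- FALSE
  best_w <- w
  best_delta <- Inf
  while (it < max_iter) {
    it <- it + 1L
    wx <- w %*% z                                  # K x V current sources
    gwx <- tanh(wx)
    g1 <- rowMeans(1 - gwx^2)
    w_new <- gwx %*% t(z) / nv - diag(g1, k) %*% w
    w_new <- sym_decorrelate(w_new)
    delta <- max(abs(abs(rowSums(w_new * w)) - 1))
    w <- w_new
    if (delta < best_delta) {
      best_delta <- delta
      best_w <- w
    }
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(w = w, s = w %*% z, converged = converged, iterations = it,
       best_w = best_w, best_delta = best_delta)
}

#' Write group ICA results
#'
#' Component maps go to one 4D NIfTI (K volumes) plus per-component 3D
#' files; the mixing matrix to TSV.
#'
#' @param ics A `group_ics`.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_group_ics <- function(ics, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- dim(ics$maps[[1]])
  stack <- array(0, dim = c(grid, ics$n_components))
  for (j in seq_len(ics$n_components)) {
    stack[, , , j] <- ics$maps[[j]]
    write_nifti(ics$maps[[j]], file.path(out_dir, sprintf("ic%02d.nii", j)))
  }
  write_nifti(stack, file.path(out_dir, "group_ics.nii"), tr_seconds = 1)
  utils::write.table(ics$mixing, file.path(out_dir, "mixing.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     col.names = sprintf("ic%02d", seq_len(ics$n_components)))
  invisible(out_dir)
}
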