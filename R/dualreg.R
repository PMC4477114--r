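# Dual regression: stage 1 regresses the group spatial maps (as spatial
# regressors, jointly, with an intercept) into each subject's 4D data,
# giving one time course per group map; stage 2 regresses those time
# courses (as temporal regressors, jointly, with an intercept) back into
# the same data, giving subject-specific spatial maps, z-scored per map.

#' Stage 1: subject-specific network time courses
#'
#' For each time point the in-mask voxel vector is regressed on the K group
#' maps plus an intercept; coefficient k at time t is network k's time
#' course value at t.
#'
#' @param vol A [volume4d()] on the same grid/mask as the group maps.
#' @param group_maps A `group_ics`, or a K x V matrix of in-mask map
#'   values.
#' @param variance_normalize Scale each output column to unit variance
#'   (default TRUE, mirroring the standard dual-regression `des_norm`
#'   behavior; Pearson inter-network correlations are unaffected).
#' @return A `subject_timecourses` list: `values` (T x K), `component_ids`,
#'   `variance_normalized`.
#' @export
spatial_regression <- function(vol, group_maps, variance_normalize = TRUE) {
  mm <- if (inherits(group_maps, "group_ics")) group_maps$map_matrix
        else as.matrix(group_maps)
  y <- t(vol_matrix(vol))                        # V x T
  if (ncol(mm) != nrow(y)) stop("group maps and volume disagree on voxel count")
  k <- nrow(mm)
  if (k > nrow(y)) stop("more maps than in-mask voxels")
  x <- cbind(1, t(mm))                           # V x (K+1)
  qx <- qr(x)
  if (qx$rank < ncol(x)) stop("collinear group maps")
  cond <- kappa(qr.R(qx), exact = TRUE)
  if (cond > 1e8) stop("collinear group maps (condition number ", format(cond), ")")
  beta <- qr.coef(qx, y)                         # (K+1) x T
  tcs <- t(beta[-1, , drop = FALSE])             # T x K
  if (variance_normalize) {
    sds <- apply(tcs, 2L, stats::sd)
    if (any(sds == 0)) stop("constant stage-1 time course")
    tcs <- sweep(tcs, 2L, sds, "/")
  }
  structure(list(values = tcs,
                 component_ids = sprintf("ic%02d", seq_len(k)),
                 variance_normalized = isTRUE(variance_normalize)),
            class = "subject_timecourses")
}

#' Stage 2: subject-specific spatial maps
#'
#' Each in-mask voxel's series is regressed on the K time courses plus an
#' intercept; coefficient map k is z-scored over the mask.
#'
#' @param vol A [volume4d()].
#' @param tcs A `subject_timecourses` (or T x K matrix).
#' @return A `subject_maps` list: `maps` (K z-scored 3D arrays),
#'   `map_matrix` (K x V), `component_ids`.
#' @export
temporal_regression <- function(vol, tcs) {
  tm <- if (inherits(tcs, "subject_timecourses")) tcs$values else as.matrix(tcs)
  y <- vol_matrix(vol)                           # T x V
  if (nrow(tm) != nrow(y)) stop("time courses and volume disagree on T")
  x <- cbind(1, tm)
  qx <- qr(x)
  if (qx$rank < ncol(x)) stop("collinear time courses")
  beta <- qr.coef(qx, y)[-1, , drop = FALSE]     # K x V
  k <- nrow(beta)
  maps <- vector("list", k)
  map_matrix <- matrix(0, k, ncol(beta))
  for (j in seq_len(k)) {
    zm <- zscore_map(map_unflatten(beta[j, ], vol$mask), vol$mask)
    maps[[j]] <- zm
    map_matrix[j, ] <- zm[vol$mask]
  }
  structure(list(maps = maps, map_matrix = map_matrix,
                 component_ids = sprintf("ic%02d", seq_len(k))),
            class = "subject_maps")
}

#' Both dual-regression stages
#'
#' @inheritParams spatial_regression
#' @return List with `timecourses` and `maps`.
#' @export
dual_regress <- function(vol, group_maps, variance_normalize = TRUE) {
  tcs <- spatial_regression(vol, group_maps, variance_normalize)
  maps <- temporal_regression(vol, tcs)
  list(timecourses = tcs, maps = maps)
}

#' Write subject time courses as TSV
#'
#' @param tcs A `subject_timecourses`.
#' @param path Output path (T rows, K named columns).
#' @return `path`, invisibly.
#' @export
write_timecourses <- function(tcs, path) {
  m <- tcs$values
  colnames(m) <- tcs$component_ids
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
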