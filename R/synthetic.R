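# Synthetic resting-state phantom generator. Plants K network spatial maps
# (disjoint Gaussian blobs), latent low-frequency network time courses with
# an exactly realized inter-network correlation matrix, nuisance signals
# (6 smooth motion-like series, WM and CSF tissue signals), white noise, and
# behavior scores linearly tied to a chosen network pair's correlation.
# Everything is deterministic given a seed, and the ground truth is recorded
# so recovery can be scored.

#' Generate disjoint network template masks
#'
#' Places `k` spherical Gaussian blobs on the grid, thresholded into binary
#' masks, all strictly inside a brain mask (the grid minus a 1-voxel
#' border). Two additional blobs serve as white-matter and CSF tissue masks
#' for confound extraction; they are disjoint from the network masks.
#'
#' @param grid Integer 3-vector of grid dimensions.
#' @param k Number of network templates.
#' @param blob_radius Blob radius in voxels (default 2.5).
#' @param seed Integer seed.
#' @param names Optional network labels (default `DMN`, `CEN`, `CAN`, `SN`,
#'   `AN`, then `NET6`, ...).
#' @param max_overlap Maximum allowed pairwise overlap fraction (default 0:
#'   masks must be disjoint).
#' @return A `template_set` list: `names`, `masks` (list of 3D logical
#'   arrays), `grid`, `brain_mask`, `wm_mask`, `csf_mask`.
#' @export
make_templates <- function(grid, k, blob_radius = 2.5, seed = 1L,
                           names = NULL, max_overlap = 0) {
  stopifnot(length(grid) == 3L, k >= 1L)
  if (is.null(names)) {
    canonical <- c("DMN", "CEN", "CAN", "SN", "AN")
    names <- if (k <= 5L) canonical[seq_len(k)] else
      c(canonical, paste0("NET", 6:k))[seq_len(k)]
  }
  stopifnot(length(names) == k)
  brain <- array(TRUE, dim = grid)
  for (ax in 1:3) {
    idx <- slice.index(brain, ax)
    brain[idx == 1L | idx == grid[ax]] <- FALSE
  }
  rng <- local_rng(seed)
  lo <- 2L + floor(blob_radius)              # blob stays inside the brain mask
  hi <- grid - 1L - floor(blob_radius)
  if (any(hi < lo)) stop("grid too small for blob_radius")
  coords <- expand.grid(x = seq_len(grid[1]), y = seq_len(grid[2]),
                        z = seq_len(grid[3]))
  place <- function(existing, n_blobs, radius = blob_radius) {
    masks <- list()
    for (i in seq_len(n_blobs)) {
      ok <- FALSE
      for (try in seq_len(500L)) {
        ctr <- lo + vapply(hi - lo + 1L, sample.int, integer(1), size = 1L)
        ctr <- ctr - 1L
        d2 <- (coords$x - ctr[1])^2 + (coords$y - ctr[2])^2 + (coords$z - ctr[3])^2
        m <- array(d2 <= radius^2, dim = grid)
        overlaps <- vapply(c(existing, masks), function(e) {
          sum(e & m) / sum(m)
        }, 0)
        if (sum(m) > 0L && all(brain[m]) &&
            (length(overlaps) == 0L || all(overlaps <= max_overlap))) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("cannot place ", n_blobs, " blobs with allowed overlap; ",
                    "grid too crowded")
      masks[[i]] <- m
    }
    masks
  }
  net <- place(list(), k)
  tissue <- place(net, 2L, radius = min(blob_radius, 1.5))  # small tissue blobs
  structure(list(names = names, masks = stats::setNames(net, names),
                 grid = as.integer(grid), brain_mask = brain,
                 wm_mask = tissue[[1]], csf_mask = tissue[[2]]),
            class = "template_set")
}

# seed the RNG for a deterministic draw (every stochastic entry point calls
# this with a seed derived from the global one)
local_rng <- function(seed) {
  set.seed(as.integer(seed %% 2147483647))
  invisible(seed)
}

#' Sample latent network time courses with an exact correlation structure
#'
#' Construction: K i.i.d. Gaussian series are low-pass filtered (ideal
#' brick wall below `lowfreq_cutoff_hz`), empirically decorrelated, then
#' multiplied by a symmetric square root of `corr`. The sample correlation
#' of the output therefore equals `corr` exactly (not just in expectation),
#' which matters at 150-volume scan lengths where sampling error in r is
#' otherwise comparable to the effects under study.
#'
#' @param t_points Number of time points (>= 2K + 2).
#' @param tr_seconds Repetition time in seconds.
#' @param corr K x K symmetric positive semi-definite matrix, unit diagonal.
#' @param lowfreq_cutoff_hz Frequency below which power is concentrated
#'   (default 0.08).
#' @param seed Integer seed.
#' @return T x K matrix; columns have mean 0 and sample variance 1.
#' @export
sample_network_timecourses <- function(t_points, tr_seconds, corr,
                                       lowfreq_cutoff_hz = 0.08, seed = 1L) {
  corr <- as.matrix(corr)
  k <- nrow(corr)
  if (!isSymmetric(corr, tol = 1e-8)) stop("corr must be symmetric")
  if (max(abs(diag(corr) - 1)) > 1e-8) stop("corr must have unit diagonal")
  ev <- eigen(corr, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    stop(sprintf("corr is not positive semi-definite (smallest eigenvalue %.3g)",
                 min(ev$values)))
  }
  if (t_points < 2L * k + 2L) stop("t_points too small for ", k, " series")
  rng <- local_rng(seed)
  raw <- matrix(stats::rnorm(t_points * k), t_points, k)
  f <- lowpass_filter(raw, tr_seconds, lowfreq_cutoff_hz)
  f <- sweep(f, 2L, colMeans(f))
  # empirical whitening: sample covariance of e is exactly the identity
  cf <- crossprod(f) / t_points
  ef <- eigen(cf, symmetric = TRUE)
  if (min(ef$values) < 1e-12 * max(ef$values)) {
    stop("filtered noise series are collinear; increase t_points or cutoff")
  }
  whiten <- ef$vectors %*% diag(1 / sqrt(ef$values), k) %*% t(ef$vectors)
  e <- f %*% whiten
  root <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), k) %*% t(ev$vectors)
  e %*% root
}

#' Synthesize one subject's 4D volume
#'
#' In-mask signal is `sum_k map_k * tc_k(t) + sum_c weight_c * confound_c(t)
#' + N(0, noise_sd)`; voxels outside the brain mask are zero.
#'
#' @param templates A `template_set` from [make_templates()].
#' @param maps List of K 3D loading arrays (supported in the template
#'   masks).
#' @param timecourses T x K matrix of latent series.
#' @param noise_sd Gaussian noise SD (0 for noise-free phantoms).
#' @param confounds Optional T x C matrix of nuisance series.
#' @param confound_weights Optional list of C 3D spatial weight arrays.
#' @param tr_seconds Repetition time (default 2).
#' @param seed Integer seed for the noise draw.
#' @return A [volume4d()] with the brain mask attached.
#' @export
synthesize_subject <- function(templates, maps, timecourses, noise_sd = 1,
                               confounds = NULL, confound_weights = NULL,
                               tr_seconds = 2, seed = 1L) {
  grid <- templates$grid
  t_points <- nrow(timecourses)
  k <- ncol(timecourses)
  if (length(maps) != k) stop("shape mismatch: ", length(maps), " maps for ",
                              k, " time courses")
  nvox <- prod(grid)
  loadings <- vapply(maps, function(m) {
    if (!identical(dim(m), as.integer(grid))) stop("shape mismatch: map grid")
    as.vector(m)
  }, numeric(nvox))
  sig <- loadings %*% t(timecourses)                       # V x T
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != t_points) stop("shape mismatch: confound length")
    cw <- vapply(confound_weights, as.vector, numeric(nvox))
    if (ncol(cw) != ncol(confounds)) stop("shape mismatch: confound weights")
    sig <- sig + cw %*% t(confounds)
  }
  if (noise_sd > 0) {
    local_rng(seed)
    sig <- sig + matrix(stats::rnorm(length(sig), sd = noise_sd),
                        nrow(sig), ncol(sig))
  }
  sig[!as.vector(templates$brain_mask), ] <- 0
  volume4d(array(sig, dim = c(grid, t_points)), tr_seconds,
           mask = templates$brain_mask)
}

#' Default synthetic ground truth
#'
#' Encodes the published between-group pattern: in controls the affective
#' network (AN) correlates 0.30 with CEN, -0.39 with CAN, and -0.18 with
#' SN; in the depression group those correlations shrink toward zero
#' (0.15, -0.22, -0.02). Subject-level correlation matrices are drawn
#' around the group matrix with between-subject SD `subject_r_sd` and
#' projected back to the nearest correlation matrix. The behavior model
#' plants a negative linear association between the SN-AN correlation and
#' the executive score in the depression group only.
#'
#' @param templates A `template_set` with the canonical five network names.
#' @param noise_sd Voxel noise SD (default 1).
#' @param subject_r_sd Between-subject SD of edge correlations
#'   (default 0.27, the scale of the published per-group SDs).
#' @param corr_by_group Optional named list of K x K group correlation
#'   matrices overriding the default pattern.
#' @param behavior Optional behavior model override; a list with `edge`
#'   (two network names), per-group `intercept`, `slope`, `noise_sd`.
#' @return A `synthetic_truth` list.
#' @export
default_truth <- function(templates, noise_sd = 1, subject_r_sd = 0.27,
                          corr_by_group = NULL, behavior = NULL) {
  k <- length(templates$names)
  nm <- templates$names
  if (is.null(corr_by_group)) {
    base <- function(an_cen, an_can, an_sn) {
      m <- diag(k)
      dimnames(m) <- list(nm, nm)
      set <- function(m, a, b, v) {
        if (a %in% nm && b %in% nm) m[a, b] <- m[b, a] <- v
        m
      }
      m <- set(m, "AN", "CEN", an_cen)
      m <- set(m, "AN", "CAN", an_can)
      m <- set(m, "AN", "SN", an_sn)
      m
    }
    corr_by_group <- list(control = base(0.30, -0.39, -0.18),
                          depression = base(0.15, -0.22, -0.02))
  }
  for (g in names(corr_by_group)) {
    ev <- eigen(corr_by_group[[g]], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop("group correlation matrix for '", g,
                              "' is not positive semi-definite")
  }
  if (is.null(behavior)) {
    behavior <- list(
      edge = c("SN", "AN"),
      intercept = c(control = 0.24, depression = -0.10),
      slope = c(control = 0, depression = -1.5),
      noise_sd = c(control = 0.71, depression = 0.70)
    )
  }
  maps <- lapply(templates$masks, function(m) gaussian_profile(m))
  structure(list(networks = nm, maps = maps, corr_by_group = corr_by_group,
                 noise_sd = noise_sd, subject_r_sd = subject_r_sd,
                 behavior = behavior,
                 depression_model = list(
                   control = c(mean = 0, sd = 0.9),
                   depression = c(mean = 7, sd = 9.2))),
            class = "synthetic_truth")
}

# smooth loading profile inside a binary mask: Gaussian falloff from centroid
gaussian_profile <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  ctr <- colMeans(idx)
  d2 <- rowSums(sweep(idx, 2L, ctr)^2)
  sigma2 <- max(mean(d2), 0.5)
  out <- array(0, dim = dim(mask))
  out[mask] <- exp(-d2 / (2 * sigma2))
  out
}

#' Generate a study design table
#'
#' Ages are drawn per group from the published cohort profile (depression
#' 68.3 +/- 6.5 years, control 71.8 +/- 8.2); scores are filled in by
#' [synthesize_study()] from the behavior model.
#'
#' @param n_per_group Subjects per group (default 32).
#' @param groups Group labels (default `control`, `depression`).
#' @param seed Integer seed.
#' @return A design `data.frame`.
#' @export
make_design <- function(n_per_group = 32L, groups = c("control", "depression"),
                        seed = 1L) {
  local_rng(seed)
  age_model <- list(control = c(71.8, 8.2), depression = c(68.3, 6.5))
  rows <- lapply(groups, function(g) {
    am <- if (g %in% names(age_model)) age_model[[g]] else c(70, 7)
    data.frame(
      subject_id = sprintf("%s%02d", substr(g, 1, 3), seq_len(n_per_group)),
      group = g,
      age = round(stats::rnorm(n_per_group, am[1], am[2]), 1),
      depression_score = NA_real_,
      executive_score = NA_real_,
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$group <- factor(df$group, levels = groups)
  df
}

#' Synthesize a full group study to disk
#'
#' Writes one 4D NIfTI per subject, a confound TSV per subject, the
#' completed design TSV, the template/tissue masks, and a ground-truth JSON
#' record sufficient to regenerate the study byte-identically from the same
#' seed.
#'
#' @param design Design table ([make_design()] or [read_design()]); each
#'   group must have a correlation matrix in `truth$corr_by_group`.
#' @param truth A `synthetic_truth` ([default_truth()]).
#' @param templates The `template_set` the truth was built from.
#' @param out_dir Output directory (created if needed).
#' @param t_points Volumes per subject (default 150).
#' @param tr_seconds Repetition time (default 2).
#' @param seed Integer global seed; per-subject seeds are derived from it.
#' @param with_confounds Plant motion-like and tissue nuisance signals
#'   (default TRUE). Set FALSE for pure-signal phantoms: confound
#'   projection in preprocessing perturbs in-sample correlations by design,
#'   so exact-recovery checks need a confound-free world (no confound TSVs
#'   or tissue masks are written).
#' @return A list: the updated `design`, `paths` (per-subject NIfTI and
#'   confound files), `subject_corr` (per-subject planted K x K matrices),
#'   and `truth_json` path.
#' @export
synthesize_study <- function(design, truth, templates, out_dir,
                             t_points = 150L, tr_seconds = 2,
                             seed = 1L, with_confounds = TRUE) {
  missing_groups <- setdiff(levels(design$group), names(truth$corr_by_group))
  if (length(missing_groups)) {
    stop("group(s) in design missing from truth: ",
         paste(missing_groups, collapse = ", "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  k <- length(truth$networks)
  edge_i <- match(truth$behavior$edge[1], truth$networks)
  edge_j <- match(truth$behavior$edge[2], truth$networks)
  n <- nrow(design)
  paths <- data.frame(subject_id = design$subject_id,
                      bold = file.path(out_dir, paste0(design$subject_id, ".nii")),
                      confounds = file.path(out_dir,
                                            paste0(design$subject_id, "_confounds.tsv")),
                      stringsAsFactors = FALSE)
  subject_corr <- vector("list", n)
  names(subject_corr) <- design$subject_id
  edge_r <- numeric(n)
  for (i in seq_len(n)) {
    g <- as.character(design$group[i])
    sseed <- derive_seed(seed, paste0("subject:", design$subject_id[i]))
    local_rng(sseed)
    target <- perturb_correlation(truth$corr_by_group[[g]], truth$subject_r_sd)
    subject_corr[[i]] <- target
    edge_r[i] <- target[edge_i, edge_j]
    tcs <- sample_network_timecourses(t_points, tr_seconds, target,
                                      seed = derive_seed(sseed, "tcs"))
    if (with_confounds) {
      conf <- make_confounds(t_points, tr_seconds,
                             seed = derive_seed(sseed, "confounds"))
      cw <- confound_weights(templates)
    } else {
      conf <- NULL
      cw <- NULL
    }
    vol <- synthesize_subject(templates, truth$maps, tcs,
                              noise_sd = truth$noise_sd,
                              confounds = conf, confound_weights = cw,
                              tr_seconds = tr_seconds,
                              seed = derive_seed(sseed, "noise"))
    write_volume4d(vol, paths$bold[i])
    # only the motion-like series go to the confound file: the WM/CSF
    # signals are planted in their tissue masks and must be *estimated*
    # by the pipeline (extract_tissue_signal), as in a real study
    if (with_confounds) {
      utils::write.table(format(conf[, 1:6], digits = 17), paths$confounds[i],
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    dm <- truth$depression_model[[g]]
    design$depression_score[i] <- max(0, round(stats::rnorm(1, dm["mean"],
                                                            dm["sd"]), 1))
    b <- truth$behavior
    design$executive_score[i] <- b$intercept[[g]] + b$slope[[g]] * edge_r[i] +
      stats::rnorm(1, 0, b$noise_sd[[g]])
  }
  write_design(design, file.path(out_dir, "design.tsv"))
  write_nifti(templates$brain_mask * 1, file.path(out_dir, "brain_mask.nii"))
  if (with_confounds) {
    write_nifti(templates$wm_mask * 1, file.path(out_dir, "wm_mask.nii"))
    write_nifti(templates$csf_mask * 1, file.path(out_dir, "csf_mask.nii"))
  }
  for (j in seq_len(k)) {
    write_nifti(templates$masks[[j]] * 1,
                file.path(out_dir, paste0("template_", truth$networks[j], ".nii")))
  }
  truth_json <- file.path(out_dir, "truth.json")
  jsonlite::write_json(list(
    networks = truth$networks,
    seed = seed, t_points = t_points, tr_seconds = tr_seconds,
    noise_sd = truth$noise_sd, subject_r_sd = truth$subject_r_sd,
    corr_by_group = lapply(truth$corr_by_group, unname),
    behavior = truth$behavior,
    subject_corr = lapply(subject_corr, unname),
    behavior_edge = c(edge_i, edge_j)
  ), truth_json, auto_unbox = TRUE, digits = NA)
  list(design = design, paths = paths, subject_corr = subject_corr,
       edge_r = edge_r, truth_json = truth_json)
}

# draw a per-subject correlation matrix around a group matrix and project it
# back onto the correlation-matrix set (eigenvalue clipping + unit diagonal)
perturb_correlation <- function(corr, sd) {
  k <- nrow(corr)
  if (sd <= 0) return(corr)
  noise <- matrix(0, k, k)
  noise[upper.tri(noise)] <- stats::rnorm(k * (k - 1) / 2, 0, sd)
  noise <- noise + t(noise)
  raw <- corr + noise
  raw[raw > 0.99] <- 0.99
  raw[raw < -0.99] <- -0.99
  diag(raw) <- 1
  ev <- eigen(raw, symmetric = TRUE)
  vals <- pmax(ev$values, 1e-4)
  m <- ev$vectors %*% diag(vals, k) %*% t(ev$vectors)
  d <- 1 / sqrt(diag(m))
  m <- m * tcrossprod(d)
  diag(m) <- 1
  dimnames(m) <- dimnames(corr)
  m
}

#' Motion-like and tissue confound series
#'
#' Six smooth "motion" series (integrated white noise, standardized) plus
#' one white-matter and one CSF latent series (low-frequency noise).
#'
#' @param t_points Number of time points.
#' @param tr_seconds Repetition time.
#' @param seed Integer seed.
#' @return T x 8 matrix with named columns.
#' @export
make_confounds <- function(t_points, tr_seconds = 2, seed = 1L) {
  local_rng(seed)
  motion <- vapply(1:6, function(i) {
    s <- cumsum(stats::rnorm(t_points, sd = 0.1))
    (s - mean(s)) / stats::sd(s)
  }, numeric(t_points))
  tissue <- vapply(1:2, function(i) {
    s <- lowpass_filter(matrix(stats::rnorm(t_points)), tr_seconds, 0.1)[, 1]
    (s - mean(s)) / stats::sd(s)
  }, numeric(t_points))
  out <- cbind(motion, tissue)
  colnames(out) <- c(paste0("motion", 1:6), "wm", "csf")
  out
}

# spatial weights for the confound series: motion leaks weakly everywhere in
# the brain; wm/csf series live in their tissue masks
confound_weights <- function(templates, motion_amp = 0.2, tissue_amp = 1) {
  b <- templates$brain_mask * motion_amp
  c(rep(list(b), 6L),
    list(templates$wm_mask * tissue_amp, templates$csf_mask * tissue_amp))
}
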