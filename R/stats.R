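# Inferential statistics: per-subject inter-network correlation matrices,
# edge-level two-sample tests (optionally age-residualized), Monte-Carlo
# cluster-size correction on the network-pair graph (a network-based
# statistic), voxelwise permutation cluster tests, behavior correlations,
# and the summary-statistic tests that reproduce printed demographic and
# edge tables.

#' Inter-network Pearson correlation matrix
#'
#' @param tcs A `subject_timecourses` (or T x K matrix), T >= 3, no
#'   constant column.
#' @param fisher_z Also store the Fisher z transform (`atanh(r)`).
#' @return List with `r` (K x K, unit diagonal) and, when requested, `z`.
#' @export
inter_network_correlation <- function(tcs, fisher_z = FALSE) {
  m <- if (inherits(tcs, "subject_timecourses")) tcs$values else as.matrix(tcs)
  if (nrow(m) < 3L) stop("need at least 3 time points")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0)) stop("constant column: correlation undefined for column ",
                          which(sds == 0)[1])
  r <- stats::cor(m)
  out <- list(r = r)
  if (fisher_z) {
    z <- suppressWarnings(atanh(r))
    diag(z) <- Inf
    out$z <- z
  }
  out
}

# all unordered network pairs (i < j) for K networks
edge_pairs <- function(k, names = NULL) {
  idx <- which(upper.tri(diag(k)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  out <- data.frame(i = idx[, 1], j = idx[, 2])
  if (!is.null(names)) {
    out$edge <- paste(names[out$i], names[out$j], sep = "-")
  } else {
    out$edge <- paste(out$i, out$j, sep = "-")
  }
  out
}

#' Pooled-variance two-sample t-test from summary statistics
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @return List with `t`, `df` (`n1 + n2 - 2`) and two-sided `p`.
#' @export
summary_ttest <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group")
  if (sd1 < 0 || sd2 < 0 || (sd1 == 0 && sd2 == 0)) stop("invalid SDs")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t_stat <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t_stat, df = df, p = 2 * stats::pt(-abs(t_stat), df))
}

#' Pearson chi-square test on a 2x2 table
#'
#' No continuity correction, df = 1.
#'
#' @param a,b,c,d Cell counts, rows = groups, columns = categories
#'   (`a`,`b` row 1; `c`,`d` row 2).
#' @return List with `chi2` and `p`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("negative counts")
  n <- sum(counts)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (any(c(r1, r2, c1, c2) == 0)) stop("zero margin")
  chi2 <- n * (a * d - b * c)^2 / (r1 * r2 * c1 * c2)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

# residualize values on age with a common slope; group intercepts preserved
# (slope estimated from the model value ~ group + age)
age_residualize <- function(values, groups, ages) {
  x <- cbind(stats::model.matrix(~ groups), age = ages)
  beta <- qr.coef(qr(x), values)
  values - beta["age"] * (ages - mean(ages))
}

#' Edge-level two-sample test
#'
#' Pooled-variance two-sample t-test on per-subject edge correlation
#' values. When ages are supplied the values are first residualized on age
#' with a common slope (group intercepts preserved), then tested.
#'
#' @param values_a,values_b Per-subject edge values per group (>= 2 each).
#' @param age_a,age_b Optional ages (both or neither).
#' @param fisher_z Test `atanh` transformed values (group means/SDs are
#'   still reported on the raw scale).
#' @return List (`edge_stat`): `mean_a`, `sd_a`, `mean_b`, `sd_b`, `t`,
#'   `df`, `p`, `covariate_adjusted`.
#' @export
edge_group_test <- function(values_a, values_b, age_a = NULL, age_b = NULL,
                            fisher_z = FALSE) {
  n1 <- length(values_a); n2 <- length(values_b)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 subjects per group")
  mean_a <- mean(values_a); sd_a <- stats::sd(values_a)
  mean_b <- mean(values_b); sd_b <- stats::sd(values_b)
  ya <- values_a; yb <- values_b
  if (fisher_z) {
    ya <- atanh(pmin(pmax(ya, -0.999999), 0.999999))
    yb <- atanh(pmin(pmax(yb, -0.999999), 0.999999))
  }
  adjusted <- !is.null(age_a)
  if (adjusted) {
    if (is.null(age_b)) stop("supply ages for both groups or neither")
    y <- age_residualize(c(ya, yb),
                         factor(rep(c("a", "b"), c(n1, n2))),
                         c(age_a, age_b))
    ya <- y[seq_len(n1)]
    yb <- y[n1 + seq_len(n2)]
  }
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(ya) + (n2 - 1) * stats::var(yb)) / df
  if (sp2 == 0) stop("zero pooled variance")
  t_stat <- (mean(ya) - mean(yb)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(mean_a = mean_a, sd_a = sd_a, mean_b = mean_b, sd_b = sd_b,
       t = t_stat, df = df, p = 2 * stats::pt(-abs(t_stat), df),
       covariate_adjusted = adjusted)
}

# vectorized pooled two-sample t for many permutations at once:
# x: n x E matrix, gmat: P x n 0/1 membership of group A per permutation.
# Returns P x E matrix of t statistics.
perm_ttest_matrix <- function(x, gmat) {
  n <- nrow(x)
  n1 <- rowSums(gmat)
  n2 <- n - n1
  tot <- colSums(x)
  tot2 <- colSums(x^2)
  s1 <- gmat %*% x
  ss1 <- gmat %*% (x^2)
  m1 <- s1 / n1
  m2 <- sweep(-s1, 2L, tot, "+") / n2
  v1 <- (ss1 - s1^2 / n1)
  v2 <- sweep(-ss1, 2L, tot2, "+") - (sweep(-s1, 2L, tot, "+"))^2 / n2
  sp2 <- (v1 + v2) / (n - 2)
  sp2[sp2 <= 0] <- NA
  tmat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  tmat[is.na(tmat)] <- 0
  tmat
}

# connected components of a set of edges on K network nodes (shared-node
# adjacency); returns an integer component id per edge
edge_components <- function(edges_i, edges_j, k) {
  parent <- seq_len(k)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  for (e in seq_along(edges_i)) {
    ra <- find(edges_i[e]); rb <- find(edges_j[e])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(edges_i, find, 0L)
  match(roots, unique(roots))
}

#' Monte-Carlo cluster-size correction on the network-pair graph
#'
#' Step 1 thresholds the edge-level two-sample tests at `edge_alpha`;
#' step 2 groups supra-threshold edges into connected clusters (edges
#' sharing a network node) and sizes each cluster by its edge count;
#' step 3 compares observed sizes with the null distribution of the
#' maximum cluster size over `n_sims` random group-label permutations,
#' with the full edge-test and clustering recomputed each draw. Corrected
#' p uses +1 smoothing: `(1 + #\{null >= obs\}) / (1 + n_sims)`.
#'
#' @param subject_edge_values n x E matrix of per-subject edge values
#'   (columns in [edge_pairs()] order).
#' @param group_labels Factor/vector with two levels, length n.
#' @param k Number of networks (edges are pairs of `1..k`).
#' @param n_sims Number of Monte-Carlo permutations (>= 100).
#' @param edge_alpha Edge-forming threshold (default 0.05).
#' @param seed Integer seed.
#' @param ages Optional ages (length n); values are age-residualized once
#'   before testing and permutation.
#' @param network_names Optional K labels for reporting.
#' @return List with `edge_table` (per-edge stats and cluster membership),
#'   `clusters` (one row per observed cluster: `cluster`, `size`,
#'   `p_corrected`, `edges`), and `null_max_sizes`.
#' @export
mc_cluster_correction <- function(subject_edge_values, group_labels, k,
                                  n_sims = 10000L, edge_alpha = 0.05,
                                  seed = 1L, ages = NULL,
                                  network_names = NULL) {
  x <- as.matrix(subject_edge_values)
  n <- nrow(x)
  groups <- factor(group_labels)
  if (nlevels(groups) != 2L) stop("need exactly two groups")
  if (n_sims < 100L) warning("n_sims < 100: corrected p resolution is coarse")
  pairs <- edge_pairs(k, network_names)
  if (ncol(x) != nrow(pairs)) stop("edge value columns do not match k choose 2")
  if (!is.null(ages)) {
    for (e in seq_len(ncol(x))) x[, e] <- age_residualize(x[, e], groups, ages)
  }
  df <- n - 2

  obs_g <- matrix(as.numeric(groups == levels(groups)[1]), 1L, n)
  t_obs <- perm_ttest_matrix(x, obs_g)[1, ]
  p_obs <- 2 * stats::pt(-abs(t_obs), df)

  supra <- which(p_obs < edge_alpha)
  cluster_id <- rep(NA_integer_, ncol(x))
  sizes <- integer(0)
  if (length(supra)) {
    comp <- edge_components(pairs$i[supra], pairs$j[supra], k)
    cluster_id[supra] <- comp
    sizes <- as.integer(table(comp))
  }

  t_thr <- stats::qt(1 - edge_alpha / 2, df)
  local_rng(derive_seed(seed, "mc_cluster"))
  gmat <- t(vapply(seq_len(n_sims), function(s) {
    as.numeric(seq_len(n) %in% sample.int(n, sum(obs_g)))
  }, numeric(n)))
  t_null <- abs(perm_ttest_matrix(x, gmat))
  null_max <- apply(t_null, 1L, function(tv) {
    hit <- which(tv > t_thr)
    if (!length(hit)) return(0L)
    comp <- edge_components(pairs$i[hit], pairs$j[hit], k)
    max(table(comp))
  })

  clusters <- data.frame(cluster = seq_along(sizes), size = sizes,
                         p_corrected = vapply(sizes, function(s) {
                           (1 + sum(null_max >= s)) / (1 + n_sims)
                         }, 0))
  clusters$edges <- vapply(clusters$cluster, function(cid) {
    paste(pairs$edge[which(cluster_id == cid)], collapse = ";")
  }, "")

  edge_table <- cbind(pairs,
                      data.frame(t = t_obs, df = df, p = p_obs,
                                 cluster = cluster_id,
                                 p_corrected = clusters$p_corrected[cluster_id]))
  list(edge_table = edge_table, clusters = clusters, null_max_sizes = null_max)
}

#' Voxelwise permutation cluster test
#'
#' Two-sample t at every in-mask voxel, converted to z; clusters formed at
#' `z > cluster_z` with 26-connectivity; the cluster-extent null comes from
#' `n_perm` group-label permutations (maximum extent per permutation).
#'
#' @param maps_a,maps_b Lists of `subject_maps` (one entry per subject) or
#'   matrices (subjects x voxels); all on a common grid.
#' @param mask 3D analysis mask (required when matrices are supplied).
#' @param component Which component map to test when `subject_maps` are
#'   supplied (default 1).
#' @param n_perm Number of permutations (default 5000).
#' @param cluster_z Cluster-forming z threshold (default 2.3).
#' @param alpha Corrected cluster alpha (default 0.05).
#' @param seed Integer seed.
#' @param ages Optional ages (group a then group b); maps are
#'   age-residualized once before testing and permutation.
#' @return List: `t_map`, `z_map` (3D arrays), `clusters` data.frame
#'   (`cluster`, `extent`, `p_corrected`, `significant`), `labels` (3D
#'   cluster label array), `null_max_extent`.
#' @export
voxelwise_group_test <- function(maps_a, maps_b, mask = NULL, component = 1L,
                                 n_perm = 5000L, cluster_z = 2.3,
                                 alpha = 0.05, seed = 1L, ages = NULL) {
  as_mat <- function(maps) {
    if (is.matrix(maps)) return(maps)
    t(vapply(maps, function(sm) sm$map_matrix[component, ],
             numeric(ncol(maps[[1]]$map_matrix))))
  }
  if (is.null(mask)) {
    if (is.matrix(maps_a)) stop("supply a mask when passing matrices")
    mask <- array(TRUE, dim = dim(maps_a[[1]]$maps[[1]]))
  }
  xa <- as_mat(maps_a)
  xb <- as_mat(maps_b)
  n1 <- nrow(xa); n2 <- nrow(xb)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 subjects per group")
  x <- rbind(xa, xb)
  n <- n1 + n2
  groups <- factor(rep(c("a", "b"), c(n1, n2)))
  if (!is.null(ages)) {
    beta_fit <- qr(cbind(stats::model.matrix(~ groups), age = ages))
    coefs <- qr.coef(beta_fit, x)
    x <- x - outer(ages - mean(ages), coefs["age", ])
  }
  df <- n - 2
  degenerate <- apply(x, 2L, stats::var) == 0
  if (mean(degenerate) > 0.10) {
    warning(sprintf("degenerate variance at %.0f%% of voxels",
                    100 * mean(degenerate)))
  }

  obs_g <- matrix(as.numeric(groups == "a"), 1L, n)
  t_obs <- perm_ttest_matrix(x, obs_g)[1, ]
  z_obs <- t_to_z(t_obs, df)
  t_thr <- stats::qt(stats::pnorm(cluster_z), df)

  grid <- dim(mask)
  if (sum(mask != 0) != ncol(x)) {
    stop("mask voxel count does not match map columns")
  }
  expand <- function(v) {
    full <- rep(-Inf, prod(grid))
    full[as.vector(mask != 0)] <- v
    full
  }
  lab <- label_clusters_3d(expand(t_obs), as.integer(grid), t_thr)

  local_rng(derive_seed(seed, "voxelwise"))
  gmat <- t(vapply(seq_len(n_perm), function(s) {
    as.numeric(seq_len(n) %in% sample.int(n, n1))
  }, numeric(n)))
  # null of the max cluster extent of the *same* signed statistic (the
  # permutation distribution is symmetric, so one signed pass suffices;
  # clustering |t| here would inflate null extents and make the test
  # conservative)
  t_null <- perm_ttest_matrix(x, gmat)                  # P x V (signed)
  statmat <- matrix(-Inf, prod(grid), n_perm)
  statmat[as.vector(mask != 0), ] <- t(t_null)
  null_max <- max_cluster_extent(statmat, as.integer(grid), t_thr)

  sizes <- lab$sizes
  clusters <- data.frame(cluster = seq_along(sizes), extent = sizes,
                         p_corrected = vapply(sizes, function(s) {
                           (1 + sum(null_max >= s)) / (1 + n_perm)
                         }, 0))
  clusters$significant <- clusters$p_corrected < alpha

  t_map <- array(0, dim = grid)
  t_map[mask != 0] <- t_obs
  z_map <- array(0, dim = grid)
  z_map[mask != 0] <- z_obs
  list(t_map = t_map, z_map = z_map, clusters = clusters,
       labels = lab$labels, null_max_extent = null_max, df = df)
}

# monotone t -> z conversion via matching tail probabilities (stable in both
# tails through log probabilities)
t_to_z <- function(t_stat, df) {
  lp <- stats::pt(t_stat, df, lower.tail = FALSE, log.p = TRUE)
  stats::qnorm(lp, lower.tail = FALSE, log.p = TRUE)
}

#' Brain-behavior correlation for one edge
#'
#' Pearson correlation between per-subject edge values and behavior scores,
#' with the two-sided t-based p-value.
#'
#' @param edge_values Per-subject edge correlations (>= 3, not constant).
#' @param scores Per-subject behavior scores (same length, not constant).
#' @return List with `r`, `df` (`n - 2`) and `p`.
#' @export
behavior_edge_correlation <- function(edge_values, scores) {
  n <- length(edge_values)
  if (n < 3L || length(scores) != n) stop("need >= 3 paired observations")
  if (stats::sd(edge_values) == 0 || stats::sd(scores) == 0) {
    stop("constant input: correlation undefined")
  }
  r <- stats::cor(edge_values, scores)
  df <- n - 2
  if (abs(r) >= 1) return(list(r = r, df = df, p = 0))
  t_stat <- r * sqrt(df / (1 - r^2))
  list(r = r, df = df, p = 2 * stats::pt(-abs(t_stat), df))
}
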