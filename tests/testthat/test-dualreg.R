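test_that("stage 1 recovers planted time courses exactly at zero noise", {
  fx <- noiseless_subject(k = 3)
  mask <- fx$vol$mask
  maps <- t(vapply(fx$maps, function(m) m[mask], numeric(sum(mask))))
  tcs <- spatial_regression(fx$vol, maps, variance_normalize = FALSE)
  for (j in 1:3) expect_gt(cor(tcs$values[, j], fx$tcs[, j]), 1 - 1e-10)

  # K = 1 indicator map on a single-network subject: time course
  # proportional to that voxel's series
  fx1 <- noiseless_subject(k = 1, seed = 86)
  mask1 <- fx1$vol$mask
  vox <- which(fx1$templates$masks[[1]][mask1])[1]   # a signal voxel
  ind <- matrix(0, 1, sum(mask1))
  ind[1, vox] <- 1
  tc1 <- spatial_regression(fx1$vol, ind, variance_normalize = FALSE)
  voxel_series <- netsync:::vol_matrix(fx1$vol)[, vox]
  expect_gt(abs(cor(tc1$values[, 1], voxel_series)), 1 - 1e-6)
})

test_that("joint multiple regression beats per-map simple regression for
           correlated maps", {
  set.seed(81)
  mask <- array(TRUE, c(6, 6, 6))
  nv <- 216
  m1 <- rnorm(nv)
  m2 <- 0.7 * m1 + 0.3 * rnorm(nv)            # strongly correlated maps
  planted <- matrix(rnorm(100 * 2), 100, 2)
  y <- cbind(m1, m2) %*% t(planted)           # V x T, zero noise
  vol <- volume4d(array(y, c(6, 6, 6, 100)), 2, mask = mask)
  joint <- spatial_regression(vol, rbind(m1, m2), variance_normalize = FALSE)
  expect_gt(cor(joint$values[, 1], planted[, 1]), 0.999)
  expect_gt(cor(joint$values[, 2], planted[, 2]), 0.999)
  # per-map simple regression is biased by the shared variance
  simple1 <- as.vector(t(y) %*% cbind(m1)) / sum(m1^2)
  expect_lt(cor(simple1, planted[, 1]), 0.999)
})

test_that("stage 2 recovers planted maps and absorbs intercept shifts", {
  fx <- noiseless_subject(k = 3)
  mask <- fx$vol$mask
  maps2 <- temporal_regression(fx$vol, fx$tcs)
  for (j in 1:3) {
    planted <- fx$maps[[j]][mask]
    expect_gt(cor(maps2$map_matrix[j, ], planted), 0.999)
  }
  shifted <- volume4d(fx$vol$data + 100, fx$vol$tr_seconds, mask)
  maps_sh <- temporal_regression(shifted, fx$tcs)
  expect_lt(max(abs(maps_sh$map_matrix - maps2$map_matrix)), 1e-6)

  # one column: coefficient proportional to voxelwise covariance oracle
  one <- temporal_regression(fx$vol, fx$tcs[, 1, drop = FALSE])
  y <- netsync:::vol_matrix(fx$vol)
  covs <- as.vector(crossprod(y, fx$tcs[, 1] - mean(fx$tcs[, 1])))
  expect_gt(cor(one$map_matrix[1, ], covs), 0.999)
})

test_that("both stages match an independent least-squares oracle", {
  set.seed(82)
  for (rep in 1:10) {
    nv <- 40; t_pts <- 25; k <- 3
    mask <- array(TRUE, c(nv, 1, 1))
    dat <- matrix(rnorm(t_pts * nv), t_pts, nv)
    vol <- volume4d(array(t(dat), c(nv, 1, 1, t_pts)), 2, mask = mask)
    gmaps <- matrix(rnorm(k * nv), k, nv)
    tcs <- spatial_regression(vol, gmaps, variance_normalize = FALSE)
    x1 <- cbind(1, t(gmaps))
    oracle1 <- t(solve(t(x1) %*% x1, t(x1) %*% t(dat))[-1, , drop = FALSE])
    expect_lt(max(abs(tcs$values - oracle1)) / max(abs(oracle1)), 1e-8)

    maps <- temporal_regression(vol, tcs)
    x2 <- cbind(1, tcs$values)
    beta2 <- solve(t(x2) %*% x2, t(x2) %*% dat)[-1, , drop = FALSE]
    # maps are z-scored; compare after z-scoring the oracle coefficients
    for (j in seq_len(k)) {
      b <- beta2[j, ]
      bz <- (b - mean(b)) / sqrt(mean((b - mean(b))^2))
      expect_lt(max(abs(maps$map_matrix[j, ] - bz)), 1e-8)
    }
  }
})

test_that("dual_regress is deterministic and scale choices do not move r", {
  fx <- noiseless_subject(k = 3, seed = 83)
  tpl <- small_templates()
  truth <- default_truth(tpl)
  tcs <- sample_network_timecourses(150, 2, truth$corr_by_group$control[1:3, 1:3],
                                    seed = 84)
  vol <- synthesize_subject(tpl, truth$maps, tcs, noise_sd = 0.5,
                            tr_seconds = 2, seed = 85)
  maps <- t(vapply(truth$maps, function(m) m[vol$mask], numeric(sum(vol$mask))))
  a <- dual_regress(vol, maps, variance_normalize = TRUE)
  b <- dual_regress(vol, maps, variance_normalize = TRUE)
  expect_identical(a$timecourses$values, b$timecourses$values)
  raw <- dual_regress(vol, maps, variance_normalize = FALSE)
  r_norm <- inter_network_correlation(a$timecourses)$r
  r_raw <- inter_network_correlation(raw$timecourses)$r
  expect_lt(max(abs(r_norm - r_raw)), 1e-10)
})
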