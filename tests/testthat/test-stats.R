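test_that("inter_network_correlation computes Pearson r with guardrails", {
  set.seed(91)
  m <- matrix(rnorm(10000 * 2), 10000, 2)
  r <- inter_network_correlation(m)$r
  expect_equal(diag(r), c(1, 1))
  expect_lt(abs(r[1, 2]), 0.05)
  dup <- cbind(m[, 1], m[, 1], -m[, 1])
  r2 <- inter_network_correlation(dup)$r
  expect_equal(r2[1, 2], 1)
  expect_equal(r2[1, 3], -1)
  expect_error(inter_network_correlation(cbind(m[, 1], rep(2, 10000))),
               "constant")
  z <- inter_network_correlation(m, fisher_z = TRUE)$z
  expect_equal(z[1, 2], atanh(r[1, 2]))
})

test_that("edge_group_test matches the textbook pooled-t oracle", {
  set.seed(92)
  a <- rnorm(10); b <- rnorm(10, 0.5)
  res <- edge_group_test(a, b)
  # independent oracle: explicit pooled-variance formula
  sp2 <- (9 * var(a) + 9 * var(b)) / 18
  t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (2 / 10))
  expect_lt(abs(res$t - t_oracle), 1e-10)
  expect_lt(abs(res$p - 2 * pt(-abs(t_oracle), 18)), 1e-10)
  # and agrees exactly with base R
  expect_equal(res$p, t.test(a, b, var.equal = TRUE)$p.value, tolerance = 1e-12)

  same <- edge_group_test(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(edge_group_test(rep(1, 5), rep(1, 5)), "zero pooled variance")

  # summary_ttest agrees exactly when fed the sample's own summaries
  s <- summary_ttest(mean(a), sd(a), 10, mean(b), sd(b), 10)
  expect_lt(abs(s$t - res$t), 1e-12)
  expect_lt(abs(s$p - res$p), 1e-12)
})

test_that("age residualization removes a common age slope", {
  set.seed(93)
  age_a <- rnorm(20, 65, 5); age_b <- rnorm(20, 72, 5)
  noise_a <- rnorm(20, sd = 0.05); noise_b <- rnorm(20, sd = 0.05)
  slope <- 0.04
  a <- 0.3 + slope * (age_a - 70) + noise_a
  b <- 0.3 + slope * (age_b - 70) + noise_b
  raw <- edge_group_test(a, b)
  adj <- edge_group_test(a, b, age_a, age_b)
  expect_true(adj$covariate_adjusted)
  # groups differ only through age; adjustment should push p toward 1
  expect_gt(adj$p, raw$p)
  expect_gt(adj$p, 0.2)
})

test_that("chi_square_2x2 matches hand computation", {
  prop <- chi_square_2x2(10, 10, 10, 10)
  expect_equal(prop$chi2, 0)
  expect_equal(prop$p, 1)
  res <- chi_square_2x2(20, 10, 10, 20)
  expect_equal(res$chi2, 20 / 3, tolerance = 1e-10)   # sum (O-E)^2/E by hand
  expect_equal(res$p, 0.0098, tolerance = 1e-2)
  # base-R oracle without continuity correction
  oracle <- chisq.test(matrix(c(13, 7, 5, 16), 2), correct = FALSE)
  ours <- chi_square_2x2(13, 5, 7, 16)
  expect_equal(ours$chi2, unname(oracle$statistic), tolerance = 1e-10)
  expect_error(chi_square_2x2(0, 0, 3, 4), "zero margin")
})

test_that("mc_cluster_correction finds planted clusters and orders p by size", {
  k <- 5
  pairs <- netsync:::edge_pairs(k, c("DMN", "CEN", "CAN", "SN", "AN"))
  an_edges <- which(pairs$i == 5 | pairs$j == 5)[1:3]   # 3 edges sharing AN
  set.seed(94)
  n <- 32
  x <- matrix(rnorm(2 * n * nrow(pairs), 0, 0.27), 2 * n, nrow(pairs))
  x[1:n, an_edges] <- x[1:n, an_edges] + 0.35           # strong group shift
  groups <- rep(c("control", "depression"), each = n)
  res <- mc_cluster_correction(x, groups, k, n_sims = 1000, seed = 95,
                               network_names = c("DMN", "CEN", "CAN", "SN", "AN"))
  expect_gte(nrow(res$clusters), 1)
  main <- res$clusters[which.max(res$clusters$size), ]
  expect_gte(main$size, 3)
  expect_lt(main$p_corrected, 0.05)
  expect_true(all(grepl("AN", strsplit(main$edges, ";")[[1]])))
  # determinism
  res2 <- mc_cluster_correction(x, groups, k, n_sims = 1000, seed = 95,
                                network_names = c("DMN", "CEN", "CAN", "SN", "AN"))
  expect_identical(res$clusters, res2$clusters)
  # corrected p monotone non-increasing in cluster size for a fixed null
  null_max <- res$null_max_sizes
  p_of <- function(s) (1 + sum(null_max >= s)) / (1 + length(null_max))
  expect_true(all(diff(vapply(1:10, p_of, 0)) <= 0))

  # no supra-threshold edges -> empty cluster list
  x0 <- matrix(rnorm(2 * n * nrow(pairs), 0, 0.27), 2 * n, nrow(pairs))
  null_res <- mc_cluster_correction(x0, groups, k, n_sims = 200, seed = 96)
  expect_true(all(null_res$edge_table$p[is.na(null_res$edge_table$cluster)] >=
                    0 ))
  if (nrow(null_res$clusters) == 0) expect_identical(null_res$clusters$size,
                                                     integer(0))
})

test_that("voxelwise test is antisymmetric and finds a planted blob", {
  set.seed(97)
  mask <- array(TRUE, c(8, 8, 8))
  nv <- 512
  blob <- array(FALSE, c(8, 8, 8)); blob[3:5, 3:5, 3:5] <- TRUE
  xa <- matrix(rnorm(10 * nv), 10, nv)
  xb <- matrix(rnorm(10 * nv), 10, nv)
  xa[, as.vector(blob)] <- xa[, as.vector(blob)] + 3
  res <- voxelwise_group_test(xa, xb, mask = mask, n_perm = 300, seed = 98)
  sig <- res$clusters[res$clusters$significant, , drop = FALSE]
  expect_identical(nrow(sig), 1L)
  # the significant cluster is the blob (possibly a couple of adjacent
  # noise voxels above threshold get merged in)
  expect_gte(sig$extent, sum(blob))
  expect_lte(sig$extent, sum(blob) + 10)
  lab_sig <- res$labels == sig$cluster
  expect_true(all(lab_sig[blob]))

  swapped <- voxelwise_group_test(xb, xa, mask = mask, n_perm = 10, seed = 98)
  expect_lt(max(abs(swapped$t_map + res$t_map)), 1e-10)
})

test_that("behavior_edge_correlation matches cor.test", {
  set.seed(99)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  res <- behavior_edge_correlation(x, y)
  oracle <- cor.test(x, y)
  expect_equal(res$r, unname(oracle$estimate), tolerance = 1e-12)
  expect_equal(res$p, oracle$p.value, tolerance = 1e-10)
  expect_equal(behavior_edge_correlation(x, x)$r, 1)
  expect_error(behavior_edge_correlation(x, rep(1, 30)), "constant")
})

test_that("Fisher-z flag barely moves p at moderate r and n = 32", {
  # atanh is within 6% of linear on [-0.4, 0.4], so the transform shifts
  # two-sample p-values only slightly; simulation puts the worst case near
  # 0.04 and the typical case well below 0.01 (see the methods vignette)
  set.seed(100)
  deltas <- replicate(200, {
    a <- pmin(pmax(rnorm(32, 0.2, 0.15), -0.4), 0.4)
    b <- pmin(pmax(rnorm(32, 0.1, 0.15), -0.4), 0.4)
    abs(edge_group_test(a, b)$p - edge_group_test(a, b, fisher_z = TRUE)$p)
  })
  expect_lt(max(deltas), 0.05)
  expect_lt(median(deltas), 0.01)
})
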