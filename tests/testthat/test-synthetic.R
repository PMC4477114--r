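test_that("make_templates places disjoint blobs inside the brain mask", {
  one <- make_templates(c(12, 12, 12), 1, seed = 11)
  expect_length(one$masks, 1)
  expect_gt(sum(one$masks[[1]]), 0)
  expect_true(all(one$brain_mask[one$masks[[1]]]))

  again <- make_templates(c(12, 12, 12), 1, seed = 11)
  expect_identical(one$masks, again$masks)

  five <- make_templates(c(20, 20, 20), 5, seed = 12)
  expect_identical(five$names, c("DMN", "CEN", "CAN", "SN", "AN"))
  combos <- utils::combn(5, 2)
  for (c_i in seq_len(ncol(combos))) {
    expect_identical(sum(five$masks[[combos[1, c_i]]] &
                           five$masks[[combos[2, c_i]]]), 0L)
  }
  for (m in five$masks) {
    expect_identical(sum(m & five$wm_mask), 0L)
    expect_identical(sum(m & five$csf_mask), 0L)
  }
  expect_error(make_templates(c(8, 8, 8), 50, seed = 1), "cannot place")
})

test_that("latent time courses realize the requested correlation", {
  id <- sample_network_timecourses(10000, 2, diag(4), seed = 21)
  expect_lt(max(abs(cor(id)[upper.tri(diag(4))])), 0.05)
  expect_lt(max(abs(colMeans(id))), 1e-10)
  expect_lt(max(abs(apply(id, 2, sd) - 1)), 0.01)

  corr <- diag(3)
  corr[1, 2] <- corr[2, 1] <- 0.30
  y <- sample_network_timecourses(10000, 2, corr, seed = 22)
  expect_lt(abs(cor(y)[1, 2] - 0.30), 0.05)
  # the construction targets the empirical correlation, even at T = 150
  y150 <- sample_network_timecourses(150, 2, corr, seed = 23)
  expect_lt(max(abs(cor(y150) - corr)), 1e-8)

  bad <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3)
  expect_error(sample_network_timecourses(150, 2, bad, seed = 1),
               "smallest eigenvalue")
})

test_that("latent spectra concentrate below the cutoff", {
  y <- sample_network_timecourses(600, 2, diag(2), lowfreq_cutoff_hz = 0.08,
                                  seed = 24)
  spec <- Mod(stats::mvfft(y))^2
  freqs <- (seq_len(600) - 1)
  freqs <- pmin(freqs, 600 - freqs) / (600 * 2)
  high <- colSums(spec[freqs >= 0.08, ])
  expect_lt(max(high / colSums(spec)), 0.01)
})

test_that("synthesize_subject composes maps, confounds and noise", {
  fx <- noiseless_subject(k = 1)
  v_idx <- which(fx$templates$masks[[1]], arr.ind = TRUE)[1, ]
  series <- fx$vol$data[v_idx[1], v_idx[2], v_idx[3], ]
  expect_gt(abs(cor(series, fx$tcs[, 1])), 1 - 1e-10)

  # SNR monotone in noise_sd
  tpl <- small_templates()
  truth <- default_truth(tpl)
  tcs <- sample_network_timecourses(150, 2, diag(3), seed = 25)
  cors <- vapply(c(0.1, 1, 10), function(ns) {
    vol <- synthesize_subject(tpl, truth$maps, tcs, noise_sd = ns,
                              tr_seconds = 2, seed = 26)
    idx <- which(tpl$masks[[2]], arr.ind = TRUE)
    mean(vapply(seq_len(nrow(idx)), function(r) {
      cor(vol$data[idx[r, 1], idx[r, 2], idx[r, 3], ], tcs[, 2])
    }, 0))
  }, 0)
  expect_true(all(diff(cors) < 0))
  expect_error(synthesize_subject(tpl, truth$maps[1:2], tcs), "mismatch")
})

test_that("synthesize_study is reproducible and plants the behavior model", {
  st <- small_study()
  expect_true(all(file.exists(st$paths$bold)))
  expect_true(all(file.exists(st$paths$confounds)))
  expect_true(file.exists(st$truth_json))

  # same seed regenerates byte-identical volumes
  dir2 <- file.path(tempdir(), "netsync_regen")
  tpl <- st$templates
  st2 <- synthesize_study(make_design(6, seed = 302), st$truth, tpl, dir2,
                          t_points = 150, seed = 303)
  expect_identical(unname(tools::md5sum(st$paths$bold[1])),
                   unname(tools::md5sum(st2$paths$bold[1])))
  unlink(dir2, recursive = TRUE)

  # subject matrices stay valid correlation matrices
  for (m in st$subject_corr) {
    expect_lt(max(abs(m - t(m))), 1e-12)
    expect_lt(max(abs(diag(m) - 1)), 1e-12)
    expect_gte(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values), 0)
  }

  # behavior: executive score tracks the planted SN-AN edge with the
  # configured negative slope in the depression group
  tpl20 <- make_templates(c(12, 12, 12), 3, seed = 31,
                          names = c("CEN", "SN", "AN"))
  truth <- default_truth(tpl20, behavior = list(
    edge = c("SN", "AN"),
    intercept = c(control = 0, depression = 0),
    slope = c(control = 0, depression = -3),
    noise_sd = c(control = 0.7, depression = 0.05)))
  dir3 <- file.path(tempdir(), "netsync_behav")
  st3 <- synthesize_study(make_design(16, seed = 32), truth, tpl20, dir3,
                          t_points = 60, seed = 33)
  dep <- st3$design$group == "depression"
  expect_lt(cor(st3$edge_r[dep], st3$design$executive_score[dep]), -0.9)
  unlink(dir3, recursive = TRUE)

  expect_error(synthesize_study(make_design(4, groups = c("x", "y"), seed = 1),
                                st$truth, tpl, tempfile()),
               "missing from truth")
})
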