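make_vol <- function(arr, tr = 2) volume4d(arr, tr)

test_that("extract_tissue_signal averages over the tissue mask", {
  set.seed(41)
  a <- array(rnorm(3 * 3 * 3 * 20), c(3, 3, 3, 20))
  vol <- make_vol(a)
  one <- array(FALSE, c(3, 3, 3)); one[2, 1, 3] <- TRUE
  expect_identical(extract_tissue_signal(vol, one), a[2, 1, 3, ])
  two <- one; two[1, 1, 1] <- TRUE
  expect_equal(extract_tissue_signal(vol, two),
               (a[2, 1, 3, ] + a[1, 1, 1, ]) / 2)
  # constant-5 volume: masked mean is 5 at every t (mask validity is not
  # tied to data variance here)
  u <- volume4d(array(5, c(3, 3, 3, 20)), 2, mask = array(TRUE, c(3, 3, 3)))
  expect_equal(extract_tissue_signal(u, two), rep(5, 20), tolerance = 1e-12)
  expect_error(extract_tissue_signal(vol, array(FALSE, c(3, 3, 3))), "empty")
})

test_that("regress_out matches a normal-equations oracle and is a projection", {
  set.seed(42)
  y <- matrix(rnorm(150 * 10), 150, 10)
  x <- matrix(rnorm(150 * 8), 150, 8)
  colnames(x) <- paste0("c", 1:8)
  res <- regress_out(y, x)
  # independent oracle: explicit normal-equations solve
  xd <- cbind(1, x)
  beta <- solve(t(xd) %*% xd, t(xd) %*% y)
  expect_lt(max(abs(res - (y - xd %*% beta))), 1e-8)
  # residuals orthogonal to demeaned confounds, mean zero
  xc <- sweep(x, 2, colMeans(x))
  rel <- max(abs(t(xc) %*% res)) / max(abs(t(xc) %*% y))
  expect_lt(rel, 1e-8)
  expect_lt(max(abs(colMeans(res))), 1e-10)
  # projection: idempotent
  expect_lt(max(abs(regress_out(res, x) - res)), 1e-8)
  # variance never increases
  expect_true(all(apply(res, 2, var) <= apply(y, 2, var) + 1e-12))

  # intercept-only: demeaning
  expect_equal(regress_out(y, matrix(0.5, 150, 0)),
               sweep(y, 2, colMeans(y)), tolerance = 1e-12)
  # a voxel equal to a confound column is annihilated
  res2 <- regress_out(cbind(x[, 3]), x)
  expect_lt(max(abs(res2)), 1e-10)
  # rank deficiency reported by column name
  expect_error(regress_out(y, cbind(x, c8dup = x[, 8])), "c8dup|c8")
})

test_that("lowpass_filter honors the analytic attenuation contract", {
  t_idx <- 0:149
  hi <- sin(2 * pi * 0.2 * t_idx * 2)           # 0.2 Hz at TR = 2 s
  lo <- sin(2 * pi * 0.02 * t_idx * 2)          # 0.02 Hz
  fhi <- lowpass_filter(cbind(hi), 2, 0.08)
  flo <- lowpass_filter(cbind(lo), 2, 0.08)
  expect_lt(var(fhi[, 1]) / var(hi), 0.01)
  expect_gt(var(flo[, 1]) / var(lo), 0.95)
  # DC retained exactly; idempotent; linear
  const <- matrix(3, 150, 1)
  expect_equal(lowpass_filter(const, 2, 0.08), const, tolerance = 1e-12)
  once <- lowpass_filter(cbind(hi + lo), 2, 0.08)
  expect_equal(lowpass_filter(once, 2, 0.08), once, tolerance = 1e-10)
  expect_equal(once, fhi + flo, tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(lowpass_filter(cbind(hi), 2, 0.25), "Nyquist")
})

test_that("butterworth option attenuates above cutoff with unit DC gain", {
  t_idx <- 0:299
  hi <- sin(2 * pi * 0.2 * t_idx * 2)
  out <- lowpass_filter(cbind(hi), 2, 0.08, type = "butterworth")
  expect_lt(var(out[150:250, 1]) / var(hi), 0.01)
  const <- matrix(4, 300, 1)
  expect_equal(lowpass_filter(const, 2, 0.08, type = "butterworth"), const,
               tolerance = 1e-6)
})

test_that("preprocess_subject recovers a planted low-frequency signal", {
  tpl <- small_templates()
  t_idx <- 0:149
  latent <- sin(2 * pi * 0.05 * t_idx * 2)       # 0.05 Hz network signal
  wm_sig <- sin(2 * pi * 0.01 * t_idx * 2 + 1)
  maps <- default_truth(tpl, noise_sd = 0)$maps
  vol <- synthesize_subject(tpl, maps[1], cbind(latent), noise_sd = 0,
                            confounds = cbind(wm = wm_sig),
                            confound_weights = list(tpl$wm_mask * 1),
                            tr_seconds = 2)
  # no csf confound here: this phantom has no CSF signal, and a constant
  # tissue mean is correctly rejected as rank-deficient
  pp <- preprocess_subject(vol, wm_mask = tpl$wm_mask)
  idx <- which(tpl$masks[[1]], arr.ind = TRUE)
  cors <- vapply(seq_len(nrow(idx)), function(r) {
    cor(pp$data[idx[r, 1], idx[r, 2], idx[r, 3], ], latent)
  }, 0)
  expect_true(all(cors > 0.99))

  # with band-limited confounds, preprocessing is idempotent
  set.seed(43)
  conf <- lowpass_filter(matrix(rnorm(150 * 3), 150, 3), 2, 0.08)
  noisy <- synthesize_subject(tpl, maps, sample_network_timecourses(150, 2,
                                                                    diag(3),
                                                                    seed = 44),
                              noise_sd = 1, confounds = conf,
                              confound_weights = rep(list(tpl$brain_mask * 0.3), 3),
                              tr_seconds = 2, seed = 45)
  once <- preprocess_subject(noisy, conf)
  twice <- preprocess_subject(once, conf)
  expect_lt(max(abs(twice$data - once$data)), 1e-6)

  # per-stage variance never increases
  y0 <- apply(vol$data, 1:3, var)
  y1 <- apply(once$data, 1:3, var)
  expect_true(all(y1 <= apply(noisy$data, 1:3, var) + 1e-10))
})
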