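# Shared fixtures, all generated in code. The small study is expensive
# enough to build once and reuse across test files (testthat sources
# helpers once per run), so it is memoized here.

.phantom_cache <- new.env(parent = emptyenv())

# 3-network template set on a 14^3 grid
small_templates <- function() {
  if (is.null(.phantom_cache$tpl)) {
    .phantom_cache$tpl <- make_templates(c(14, 14, 14), 3, seed = 301,
                                         names = c("CEN", "SN", "AN"))
  }
  .phantom_cache$tpl
}

# 6 + 6 subject study on disk (tempdir), default truth
small_study <- function() {
  if (is.null(.phantom_cache$study)) {
    tpl <- small_templates()
    truth <- default_truth(tpl)
    design <- make_design(6, seed = 302)
    dir <- file.path(tempdir(), "netsync_small_study")
    .phantom_cache$study <- synthesize_study(design, truth, tpl, dir,
                                             t_points = 150, seed = 303)
    .phantom_cache$study$truth <- truth
    .phantom_cache$study$templates <- tpl
    .phantom_cache$study$dir <- dir
  }
  .phantom_cache$study
}

# full pipeline run on the small study (voxelwise at reduced permutations)
small_pipeline <- function() {
  if (is.null(.phantom_cache$pipe)) {
    st <- small_study()
    cfg <- pipeline_config(n_components = 3, n_mc_sims = 500,
                           n_perm_voxelwise = 200, rng_seed = 304)
    out_dir <- file.path(tempdir(), "netsync_small_out")
    .phantom_cache$pipe <- run_pipeline(cfg, st$dir, st$design, out_dir)
    .phantom_cache$pipe$out_dir <- out_dir
    .phantom_cache$pipe$config <- cfg
  }
  .phantom_cache$pipe
}

# zero-noise single-subject volume with orthogonally supported maps
noiseless_subject <- function(k = 3, t_points = 150, seed = 305) {
  tpl <- small_templates()
  truth <- default_truth(tpl, noise_sd = 0)
  tcs <- sample_network_timecourses(t_points, 2, diag(k), seed = seed)
  vol <- synthesize_subject(tpl, truth$maps[seq_len(k)], tcs, noise_sd = 0,
                            tr_seconds = 2, seed = seed)
  list(vol = vol, tcs = tcs, maps = truth$maps[seq_len(k)], templates = tpl)
}

expect_rel_equal <- function(actual, expected, tol = 1e-8) {
  scale <- max(abs(expected), 1e-12)
  expect_lt(max(abs(actual - expected)) / scale, tol)
}
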