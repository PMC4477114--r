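# Run configuration. Defaults mirror the published analysis: 20 ICA
# components, 0.08 Hz low-pass, cluster forming threshold z = 2.3 at
# alpha = 0.05, edge threshold p < 0.05, 10,000 Monte-Carlo simulations.

#' Pipeline configuration
#'
#' @param n_components Number of ICA components (default 20).
#' @param lowpass_hz Low-pass cutoff in Hz; frequencies below it are
#'   retained (default 0.08). Must be below Nyquist for the data's TR.
#' @param cluster_z Voxel cluster-forming z threshold (default 2.3).
#' @param cluster_alpha Corrected cluster alpha (default 0.05).
#' @param edge_alpha Uncorrected edge p threshold forming network clusters
#'   (default 0.05).
#' @param n_mc_sims Monte-Carlo label permutations for network cluster
#'   correction (default 10000).
#' @param n_perm_voxelwise Permutations for the voxelwise cluster test
#'   (default 5000).
#' @param gof_close_ratio Keep a second-best component when its
#'   goodness-of-fit is at least this fraction of the best (default 0.9).
#' @param fisher_z Apply the Fisher z transform to inter-network
#'   correlations before group tests (default FALSE; group tests on raw r
#'   reproduce the published table p-values).
#' @param variance_normalize_stage1 Unit-variance scale the stage-1 dual
#'   regression time courses (default TRUE; Pearson correlations are
#'   scale-invariant so headline statistics do not depend on this).
#' @param filter_type `"ideal"` FFT brick-wall (default) or `"butterworth"`
#'   (order 4, forward-backward).
#' @param rng_seed Global RNG seed; each stochastic stage derives a child
#'   seed from it via [derive_seed()].
#' @return A `netsync_config` list.
#' @export
pipeline_config <- function(n_components = 20L,
                            lowpass_hz = 0.08,
                            cluster_z = 2.3,
                            cluster_alpha = 0.05,
                            edge_alpha = 0.05,
                            n_mc_sims = 10000L,
                            n_perm_voxelwise = 5000L,
                            gof_close_ratio = 0.9,
                            fisher_z = FALSE,
                            variance_normalize_stage1 = TRUE,
                            filter_type = c("ideal", "butterworth"),
                            rng_seed = 1L) {
  cfg <- list(
    n_components = as.integer(n_components),
    lowpass_hz = as.numeric(lowpass_hz),
    cluster_z = as.numeric(cluster_z),
    cluster_alpha = as.numeric(cluster_alpha),
    edge_alpha = as.numeric(edge_alpha),
    n_mc_sims = as.integer(n_mc_sims),
    n_perm_voxelwise = as.integer(n_perm_voxelwise),
    gof_close_ratio = as.numeric(gof_close_ratio),
    fisher_z = isTRUE(fisher_z),
    variance_normalize_stage1 = isTRUE(variance_normalize_stage1),
    filter_type = match.arg(filter_type),
    rng_seed = as.integer(rng_seed)
  )
  validate_config(cfg)
  structure(cfg, class = "netsync_config")
}

validate_config <- function(cfg) {
  counts <- c("n_components", "n_mc_sims", "n_perm_voxelwise")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] <= 0L) stop(f, " must be a positive count")
  }
  for (f in c("cluster_alpha", "edge_alpha")) {
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1) stop(f, " must lie in (0, 1)")
  }
  if (cfg$lowpass_hz <= 0) stop("lowpass_hz must be positive")
  if (cfg$gof_close_ratio <= 0 || cfg$gof_close_ratio > 1) {
    stop("gof_close_ratio must lie in (0, 1]")
  }
  invisible(cfg)
}

#' Read a JSON configuration file
#'
#' Fields present in the file override [pipeline_config()] defaults; any
#' entries supplied in `...` override the file in turn (the CLI uses this
#' for flag overrides).
#'
#' @param path Path to a JSON file, or `NULL` for pure defaults.
#' @param ... Named overrides applied after the file.
#' @return A `netsync_config`.
#' @export
read_config <- function(path = NULL, ...) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Write the effective configuration as JSON
#'
#' @param cfg A `netsync_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Derive a stage-specific child seed
#'
#' Each stochastic stage draws its seed deterministically from the global
#' seed and its own name, so any stage is independently reproducible.
#' The result is a stable 31-bit integer hash.
#'
#' @param seed Global integer seed.
#' @param stage Stage name (character).
#' @return A positive integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(stage)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h %% 2147483563) + 1L
}
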