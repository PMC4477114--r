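# End-to-end orchestration: preprocess -> concatenate -> group ICA ->
# template matching -> dual regression -> inter-network statistics ->
# behavior correlations, with every stage's intermediate output persisted
# beside the results so stages can be re-run and audited.

#' Run the full between-network synchronization pipeline
#'
#' Expects a flat `data_dir` as produced by [synthesize_study()] (or
#' equivalent): one 4D NIfTI per subject named `<subject_id>.nii[.gz]`,
#' optional `<subject_id>_confounds.tsv`, `brain_mask.nii`, `wm_mask.nii`,
#' `csf_mask.nii`, and `template_<NAME>.nii` network templates. All
#' subjects referenced by the design must be present; this is verified
#' before any computation starts.
#'
#' @param config A `netsync_config` ([pipeline_config()]).
#' @param data_dir Input directory.
#' @param design Design `data.frame` ([read_design()]).
#' @param out_dir Output directory (created).
#' @param run_voxelwise Also run the voxelwise permutation cluster test on
#'   each matched component (the slowest stage; default TRUE).
#' @return Invisibly, a results bundle: `ics`, `assignments`,
#'   `timecourses`, `subject_corr`, `edge_values`, `edge_table`,
#'   `clusters`, `behavior`, `voxelwise`, `paths`.
#' @export
run_pipeline <- function(config, data_dir, design, out_dir,
                         run_voxelwise = TRUE) {
  validate_config(config)
  validate_design(design)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_config(config, file.path(out_dir, "config.json"))

  bold <- file.path(data_dir, paste0(design$subject_id, ".nii"))
  alt <- paste0(bold, ".gz")
  bold[!file.exists(bold) & file.exists(alt)] <- alt[!file.exists(bold) &
                                                       file.exists(alt)]
  missing <- !file.exists(bold)
  if (any(missing)) {
    stop("missing 4D file(s) for subject(s): ",
         paste(design$subject_id[missing], collapse = ", "))
  }
  tpl_files <- list.files(data_dir, "^template_.*\\.nii(\\.gz)?$",
                          full.names = TRUE)
  if (!length(tpl_files)) stop("no template_<NAME>.nii files in ", data_dir)

  mask_path <- file.path(data_dir, "brain_mask.nii")
  brain_mask <- if (file.exists(mask_path)) read_nifti(mask_path)$data != 0 else NULL
  wm_path <- file.path(data_dir, "wm_mask.nii")
  csf_path <- file.path(data_dir, "csf_mask.nii")
  wm_mask <- if (file.exists(wm_path)) read_nifti(wm_path)$data else NULL
  csf_mask <- if (file.exists(csf_path)) read_nifti(csf_path)$data else NULL

  stage <- function(name, sid = NULL, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "'",
           if (!is.null(sid)) paste0(" (subject ", sid, ")"), " failed: ",
           conditionMessage(e), call. = FALSE)
    })
  }

  # --- preprocessing ---------------------------------------------------
  vols <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    sid <- design$subject_id[i]
    vols[[i]] <- stage("preprocess", sid, {
      vol <- read_volume4d(bold[i],
                           mask_path = if (!is.null(brain_mask)) mask_path)
      cpath <- file.path(data_dir, paste0(sid, "_confounds.tsv"))
      conf <- if (file.exists(cpath)) {
        as.matrix(utils::read.delim(cpath, sep = "\t"))
      } else NULL
      preprocess_subject(vol, conf, wm_mask, csf_mask,
                         cutoff_hz = config$lowpass_hz,
                         filter_type = config$filter_type)
    })
  }
  names(vols) <- design$subject_id

  # --- group ICA -------------------------------------------------------
  ics <- stage("group_ica", NULL, {
    concat <- concatenate_subjects(vols)
    fit_spatial_ica(concat, config$n_components,
                    seed = derive_seed(config$rng_seed, "group_ica"),
                    mask = vols[[1]]$mask)
  })
  write_group_ics(ics, file.path(out_dir, "group_ica"))
  write_nifti(ics$mask * 1, file.path(out_dir, "group_ica", "mask.nii"))

  # --- template matching ----------------------------------------------
  templates <- stage("match", NULL, {
    nm <- sub("^template_(.*)\\.nii(\\.gz)?$", "\\1", basename(tpl_files))
    list(names = nm,
         masks = stats::setNames(lapply(tpl_files, function(f) {
           read_nifti(f)$data != 0
         }), nm))
  })
  assignments <- match_components(ics, templates,
                                  close_ratio = config$gof_close_ratio)
  write_assignments(assignments, file.path(out_dir, "assignments.csv"))

  # --- dual regression -------------------------------------------------
  k_nets <- nrow(assignments)
  comp_idx <- assignments$component
  tcs_dir <- file.path(out_dir, "timecourses")
  dir.create(tcs_dir, showWarnings = FALSE)
  maps_dir <- file.path(out_dir, "subject_maps")
  dir.create(maps_dir, showWarnings = FALSE)
  all_tcs <- vector("list", nrow(design))
  all_maps <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    sid <- design$subject_id[i]
    dr <- stage("dual_regression", sid, {
      dual_regress(vols[[i]], ics,
                   variance_normalize = config$variance_normalize_stage1)
    })
    all_tcs[[i]] <- dr$timecourses
    all_maps[[i]] <- dr$maps
    write_timecourses(dr$timecourses,
                      file.path(tcs_dir, paste0(sid, "_timecourses.tsv")))
    stack <- array(0, dim = c(dim(vols[[i]]$mask), ics$n_components))
    for (j in seq_len(ics$n_components)) stack[, , , j] <- dr$maps$maps[[j]]
    write_nifti(stack, file.path(maps_dir, paste0(sid, "_maps.nii")),
                tr_seconds = 1)
  }

  # --- inter-network statistics ---------------------------------------
  pairs <- edge_pairs(k_nets, assignments$network)
  n <- nrow(design)
  edge_values <- matrix(NA_real_, n, nrow(pairs),
                        dimnames = list(design$subject_id, pairs$edge))
  subject_corr <- vector("list", n)
  for (i in seq_len(n)) {
    net_tcs <- all_tcs[[i]]$values[, comp_idx, drop = FALSE]
    colnames(net_tcs) <- assignments$network
    r <- stage("netstats", design$subject_id[i],
               inter_network_correlation(net_tcs, fisher_z = config$fisher_z)$r)
    subject_corr[[i]] <- r
    edge_values[i, ] <- r[cbind(pairs$i, pairs$j)]
  }

  groups <- design$group
  lv <- levels(groups)
  if (nlevels(droplevels(groups)) == 2L) {
    mc <- stage("netstats", NULL, {
      mc_cluster_correction(edge_values, groups, k_nets,
                            n_sims = config$n_mc_sims,
                            edge_alpha = config$edge_alpha,
                            seed = derive_seed(config$rng_seed, "mc_cluster"),
                            ages = design$age,
                            network_names = assignments$network)
    })
    # unadjusted group summaries alongside the (age-adjusted) cluster stats
    unadj <- lapply(seq_len(nrow(pairs)), function(e) {
      edge_group_test(edge_values[groups == lv[1], e],
                      edge_values[groups == lv[2], e],
                      fisher_z = config$fisher_z)
    })
    edge_table <- cbind(mc$edge_table,
                        data.frame(
                          mean_1 = vapply(unadj, `[[`, 0, "mean_a"),
                          sd_1 = vapply(unadj, `[[`, 0, "sd_a"),
                          mean_2 = vapply(unadj, `[[`, 0, "mean_b"),
                          sd_2 = vapply(unadj, `[[`, 0, "sd_b"),
                          t_unadjusted = vapply(unadj, `[[`, 0, "t"),
                          p_unadjusted = vapply(unadj, `[[`, 0, "p")))
    utils::write.csv(edge_table, file.path(out_dir, "edge_stats.csv"),
                     row.names = FALSE)
    utils::write.csv(mc$clusters, file.path(out_dir, "clusters.csv"),
                     row.names = FALSE)
  } else {
    mc <- NULL
    edge_table <- NULL
  }

  # --- behavior correlations ------------------------------------------
  behavior <- NULL
  if (!all(is.na(design$executive_score))) {
    rows <- list()
    for (g in lv) {
      sel <- groups == g
      for (e in seq_len(nrow(pairs))) {
        for (score in c("executive_score", "depression_score")) {
          y <- design[[score]][sel]
          if (all(is.na(y)) || stats::sd(y, na.rm = TRUE) == 0) next
          bc <- behavior_edge_correlation(edge_values[sel, e], y)
          rows[[length(rows) + 1L]] <-
            data.frame(group = g, edge = pairs$edge[e], score = score,
                       r = bc$r, df = bc$df, p = bc$p)
        }
      }
    }
    behavior <- do.call(rbind, rows)
    utils::write.csv(behavior, file.path(out_dir, "behavior.csv"),
                     row.names = FALSE)
  }

  # --- voxelwise tests -------------------------------------------------
  voxelwise <- NULL
  if (run_voxelwise && nlevels(droplevels(groups)) == 2L) {
    voxelwise <- vector("list", k_nets)
    names(voxelwise) <- assignments$network
    for (j in seq_len(k_nets)) {
      comp <- comp_idx[j]
      vw <- stage("voxelwise", NULL, {
        voxelwise_group_test(all_maps[groups == lv[1]],
                             all_maps[groups == lv[2]],
                             mask = vols[[1]]$mask, component = comp,
                             n_perm = config$n_perm_voxelwise,
                             cluster_z = config$cluster_z,
                             alpha = config$cluster_alpha,
                             seed = derive_seed(config$rng_seed,
                                                paste0("voxelwise:", comp)),
                             ages = c(design$age[groups == lv[1]],
                                      design$age[groups == lv[2]]))
      })
      write_nifti(vw$z_map, file.path(out_dir, sprintf(
        "voxelwise_z_%s.nii", assignments$network[j])))
      utils::write.csv(vw$clusters, file.path(out_dir, sprintf(
        "voxelwise_clusters_%s.csv", assignments$network[j])),
        row.names = FALSE)
      voxelwise[[j]] <- vw
    }
  }

  invisible(list(ics = ics, assignments = assignments, timecourses = all_tcs,
                 subject_corr = subject_corr, edge_values = edge_values,
                 edge_table = edge_table,
                 clusters = if (!is.null(mc)) mc$clusters else NULL,
                 behavior = behavior, voxelwise = voxelwise,
                 paths = list(out_dir = out_dir)))
}
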