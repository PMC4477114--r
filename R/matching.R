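# Goodness-of-fit assignment of ICA components to named network templates.
# GOF of a z-scored map against a binary template is the mean z inside the
# template minus the mean z outside it (within the brain mask) — the
# Greicius-style test. The best-scoring component is assigned; a close
# second (>= close_ratio of the best) is retained as a secondary match, so
# one component may serve several templates and vice versa.

#' Goodness of fit of a spatial map to a template
#'
#' @param map 3D (z-scored) map.
#' @param template 3D binary template mask; nonempty and a strict subset of
#'   `brain_mask`.
#' @param brain_mask 3D binary analysis mask (defaults to all voxels).
#' @return Scalar score: mean(map inside template) - mean(map outside
#'   template), both within the brain mask.
#' @export
goodness_of_fit <- function(map, template, brain_mask = NULL) {
  template <- template != 0
  if (is.null(brain_mask)) brain_mask <- array(TRUE, dim = dim(map))
  brain_mask <- brain_mask != 0
  inside <- template & brain_mask
  outside <- !template & brain_mask
  if (!any(inside)) stop("template empty (within brain mask)")
  if (!any(outside)) stop("template covers the whole brain mask")
  mean(map[inside]) - mean(map[outside])
}

#' Assign components to network templates
#'
#' For each template the primary component is the GOF argmax (ties broken
#' by lowest component index). A secondary component is retained when the
#' second-largest GOF is at least `close_ratio` times the largest and the
#' largest is positive. A template whose best GOF is non-positive is
#' flagged `no credible match` with a warning.
#'
#' @param ics A `group_ics` from [fit_spatial_ica()].
#' @param templates A `template_set` (or list with `names` and `masks`).
#' @param close_ratio Secondary retention threshold in (0, 1] (default 0.9).
#' @param brain_mask Optional analysis mask (defaults to the ICA mask).
#' @return A `data.frame` with one row per template: `network`,
#'   `component`, `gof`, `secondary_component`, `secondary_gof`,
#'   `credible`; the full GOF matrix (templates x components) is attached
#'   as attribute `gof_matrix`.
#' @export
match_components <- function(ics, templates, close_ratio = 0.9,
                             brain_mask = NULL) {
  if (is.null(brain_mask)) brain_mask <- ics$mask
  k <- ics$n_components
  n_tpl <- length(templates$masks)
  if (k < 1L || n_tpl < 1L) stop("need at least one component and one template")
  gof <- matrix(NA_real_, n_tpl, k,
                dimnames = list(templates$names, sprintf("ic%02d", seq_len(k))))
  for (i in seq_len(n_tpl)) {
    for (j in seq_len(k)) {
      gof[i, j] <- goodness_of_fit(ics$maps[[j]], templates$masks[[i]],
                                   brain_mask)
    }
  }
  rows <- lapply(seq_len(n_tpl), function(i) {
    scores <- gof[i, ]
    best <- which.max(scores)                     # lowest index wins ties
    credible <- scores[best] > 0
    if (!credible) {
      warning("no credible match for template '", templates$names[i],
              "' (all GOF <= 0)")
    }
    second <- NA_integer_
    second_gof <- NA_real_
    if (k >= 2L && credible) {
      rest <- scores
      rest[best] <- -Inf
      cand <- which.max(rest)
      if (rest[cand] >= close_ratio * scores[best]) {
        second <- cand
        second_gof <- scores[cand]
      }
    }
    data.frame(network = templates$names[i], component = unname(best),
               gof = unname(scores[best]), secondary_component = second,
               secondary_gof = second_gof, credible = credible,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "gof_matrix") <- gof
  out
}

#' Write component assignments and the GOF audit matrix
#'
#' @param assignments Result of [match_components()].
#' @param path Output CSV path; the GOF matrix goes beside it as
#'   `<path>_gof_matrix.csv`.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  utils::write.csv(assignments, path, row.names = FALSE)
  gof <- attr(assignments, "gof_matrix")
  utils::write.csv(gof, sub("(\\.csv)?$", "_gof_matrix.csv", path, perl = TRUE))
  invisible(path)
}
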