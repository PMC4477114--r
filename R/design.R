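# Study design table: subject IDs, group labels, age, depression and
# executive scores. Read from TSV; group levels keep file order so contrasts
# are stated the way the study file states them.

design_required_cols <- c("subject_id", "group", "age",
                          "depression_score", "executive_score")

#' Read a study design TSV
#'
#' The file must be tab-separated with a header row containing at least
#' `subject_id`, `group`, `age`, `depression_score`, `executive_score`.
#' Optional sub-labels (e.g. remitted / active) go in a `subgroup` column.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with `group` as a factor whose levels preserve
#'   first-appearance order in the file.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  missing_cols <- setdiff(design_required_cols, names(df))
  if (length(missing_cols)) {
    stop("design is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$subject_id <- as.character(df$subject_id)
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup)) stop("duplicate subject ID(s) in design: ",
                        paste(unique(dup), collapse = ", "))
  df$group <- factor(df$group, levels = unique(df$group))
  for (col in c("age", "depression_score", "executive_score")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  validate_design(df)
  df
}

validate_design <- function(design) {
  counts <- table(design$group)
  if (any(counts < 2L)) {
    stop("every group needs >= 2 subjects; offending group(s): ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  }
  invisible(design)
}

#' Write a study design TSV
#'
#' @param design A design `data.frame` (see [read_design()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
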