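#' Canonical site and time labels
#'
#' The pipeline stratifies by anatomical site (oral, nasal, vaginal cavity
#' and foremilk) plus a `control` pseudo-site for extraction/sequencing
#' negative controls, and by sampling time (1 week pre-partum, then 1, 3 and
#' 7 months post-partum).
#' @name enums
#' @export
SITE_LEVELS <- c("oral", "nasal", "vaginal", "milk", "control")

#' @rdname enums
#' @export
TIME_LEVELS <- c("-1W", "1M", "3M", "7M")

#' @rdname enums
#' @export
GROUP_LEVELS <- c("G1", "G2", "G3")

#' Validate a sample metadata frame
#'
#' Checks the per-sample metadata contract: unique sample IDs; site and time
#' tokens from the known vocabularies; `is_control` consistent with
#' `site == "control"`; every non-control sample carries animal, site, time
#' and group. The genomic susceptibility-to-mastitis (`sm_score`) and
#' body-condition (`bc_score`) breeding values may be missing.
#'
#' @param meta data.frame with columns `sample_id`, `animal_id`, `site`,
#'   `time`, `group`, `sm_score`, `bc_score`, `quarter`, `is_control`
#'   (missing optional columns are added as NA).
#' @param sites,times,groups allowed tokens.
#' @return The validated data.frame, classed `sample_metadata`.
#' @export
sample_metadata <- function(meta, sites = SITE_LEVELS, times = TIME_LEVELS,
                            groups = GROUP_LEVELS) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  required <- c("sample_id", "site", "is_control")
  miss <- setdiff(required, names(meta))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  for (col in c("animal_id", "time", "group", "quarter")) {
    if (!col %in% names(meta)) meta[[col]] <- NA_character_
  }
  for (col in c("sm_score", "bc_score")) {
    if (!col %in% names(meta)) meta[[col]] <- NA_real_
    meta[[col]] <- as.numeric(meta[[col]])
  }
  for (col in c("sample_id", "animal_id", "site", "time", "group", "quarter")) {
    meta[[col]] <- trimws(as.character(meta[[col]]))
    meta[[col]][!nzchar(meta[[col]]) | meta[[col]] == "NA"] <- NA_character_
  }
  meta$is_control <- as.logical(meta$is_control)
  if (anyNA(meta$sample_id)) stop("missing sample_id")
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample IDs: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  }
  bad_site <- setdiff(stats::na.omit(meta$site), sites)
  if (length(bad_site)) stop("unknown site token(s): ", paste(bad_site, collapse = ", "))
  bad_time <- setdiff(stats::na.omit(meta$time), times)
  if (length(bad_time)) stop("unknown time token(s): ", paste(bad_time, collapse = ", "))
  if (anyNA(meta$is_control)) stop("is_control must be TRUE/FALSE")
  if (any(meta$is_control != (meta$site == "control"), na.rm = TRUE) ||
      any(is.na(meta$site))) {
    stop("is_control must hold exactly for site == \"control\"")
  }
  nc <- !meta$is_control
  for (col in c("animal_id", "time", "group")) {
    if (anyNA(meta[[col]][nc])) {
      stop("non-control sample(s) missing ", col, ": ",
           paste(meta$sample_id[nc & is.na(meta[[col]])], collapse = ", "))
    }
  }
  bad_grp <- setdiff(stats::na.omit(meta$group), groups)
  if (length(bad_grp)) stop("unknown group token(s): ", paste(bad_grp, collapse = ", "))
  rownames(meta) <- meta$sample_id
  class(meta) <- c("sample_metadata", "data.frame")
  meta
}

#' Read a sample metadata sheet
#'
#' Tab-separated text with a header row; see [sample_metadata()] for the
#' required columns and validation rules.
#'
#' @param path file path.
#' @inheritParams sample_metadata
#' @return A validated `sample_metadata` data.frame.
#' @export
read_metadata <- function(path, sites = SITE_LEVELS, times = TIME_LEVELS,
                          groups = GROUP_LEVELS) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  sample_metadata(df, sites = sites, times = times, groups = groups)
}

#' Write a sample metadata sheet
#'
#' @param meta a `sample_metadata` data.frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(as.data.frame(meta), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Align metadata rows to a table's samples; error on dangling samples.
align_metadata <- function(table, meta) {
  ids <- rownames(table)
  miss <- setdiff(ids, meta$sample_id)
  if (length(miss)) {
    stop("samples absent from metadata: ", paste(miss, collapse = ", "))
  }
  meta[match(ids, meta$sample_id), , drop = FALSE]
}
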