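#' Filtering thresholds
#'
#' Defaults follow the printed filtering rules: an ASV is low-abundance if
#' its pooled relative abundance is < 1e-5 in every site-by-time stratum or
#' < 5e-5 overall; low-prevalence if seen in < 5% of samples within every
#' site or in fewer than 3 samples overall; samples with fewer than 1000
#' reads after filtering are discarded; contaminant ("kitome") ASVs must
#' exceed 50% prevalence in the negative controls.
#'
#' @param abn_stratum per-stratum pooled relative abundance floor.
#' @param abn_overall overall pooled relative abundance floor.
#' @param prev_site per-site prevalence floor (fraction of samples).
#' @param prev_min_samples minimum number of positive samples overall.
#' @param min_reads minimum per-sample read total.
#' @param kit_prev control-prevalence threshold for kitome flagging (strict >).
#' @param mean_per_sample if `TRUE`, stratum relative abundance is the mean
#'   of per-sample fractions instead of pooled (stratum-summed) reads; a
#'   sensitivity-analysis mode.
#' @return list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(abn_stratum = 1e-5, abn_overall = 5e-5,
                              prev_site = 0.05, prev_min_samples = 3L,
                              min_reads = 1000L, kit_prev = 0.5,
                              mean_per_sample = FALSE) {
  stopifnot(abn_stratum > 0, abn_stratum < 1, abn_overall > 0, abn_overall < 1,
            prev_site > 0, prev_site < 1, prev_min_samples >= 1,
            min_reads >= 1, kit_prev > 0, kit_prev < 1)
  structure(list(abn_stratum = abn_stratum, abn_overall = abn_overall,
                 prev_site = prev_site,
                 prev_min_samples = as.integer(prev_min_samples),
                 min_reads = as.integer(min_reads), kit_prev = kit_prev,
                 mean_per_sample = isTRUE(mean_per_sample)),
            class = "filter_thresholds")
}

# Pooled (or mean per-sample) relative abundance of every ASV in a stratum.
stratum_relabund <- function(table, idx, mean_per_sample = FALSE) {
  m <- unclass(table)[idx, , drop = FALSE]
  storage.mode(m) <- "double"
  if (mean_per_sample) {
    tot <- rowSums(m)
    keep <- tot > 0
    if (!any(keep)) return(rep(NA_real_, ncol(m)))
    colMeans(m[keep, , drop = FALSE] / tot[keep])
  } else {
    tot <- sum(m)
    if (tot == 0) return(rep(NA_real_, ncol(m)))
    colSums(m) / tot
  }
}

#' Low-abundance / low-prevalence ASV filter
#'
#' Removes an ASV iff it is low-abundance (pooled relative abundance below
#' `abn_stratum` in EVERY site-by-time stratum, OR below `abn_overall`
#' overall) or low-prevalence (positive in less than `prev_site` of the
#' samples within EVERY site, OR positive in fewer than `prev_min_samples`
#' samples overall). Strata and prevalences are computed over non-control
#' samples; inequalities are strict, as printed. Empty strata are skipped
#' with a warning.
#'
#' @param table an [asv_table()].
#' @param meta matching [sample_metadata()].
#' @param th a [filter_thresholds()].
#' @return list with `table` (filtered) and `log` ([removal_log()]; the
#'   `detail` field records which clause fired with the measured values).
#' @export
filter_low_abundance_prevalence <- function(table, meta, th = filter_thresholds()) {
  meta <- align_metadata(table, meta)
  body <- !meta$is_control
  if (!any(body)) stop("no non-control samples")
  bt <- unclass(table)[body, , drop = FALSE]
  storage.mode(bt) <- "double"
  site <- meta$site[body]
  stratum <- interaction(site, meta$time[body], drop = TRUE)

  # abundance clauses
  strat_ab <- vapply(levels(stratum), function(s) {
    idx <- which(stratum == s)
    if (sum(bt[idx, , drop = FALSE]) == 0) {
      warning("empty stratum skipped: ", s)
      return(rep(NA_real_, ncol(bt)))
    }
    stratum_relabund(table, rownames(bt)[idx], th$mean_per_sample)
  }, numeric(ncol(bt)))
  low_every_stratum <- apply(strat_ab, 1, function(v) all(v < th$abn_stratum, na.rm = TRUE) &&
                               !all(is.na(v)))
  overall_ab <- stratum_relabund(table, rownames(bt), th$mean_per_sample)
  low_overall <- overall_ab < th$abn_overall
  low_abundance <- low_every_stratum | low_overall

  # prevalence clauses
  pos <- bt > 0
  prev_by_site <- vapply(unique(site), function(s) {
    colMeans(pos[site == s, , drop = FALSE])
  }, numeric(ncol(bt)))
  low_every_site <- apply(prev_by_site, 1, function(v) all(v < th$prev_site))
  n_pos <- colSums(pos)
  too_few <- n_pos < th$prev_min_samples
  low_prevalence <- low_every_site | too_few

  remove <- low_abundance | low_prevalence
  asvs <- colnames(table)[remove]
  detail <- vapply(which(remove), function(j) {
    clauses <- c(
      if (low_every_stratum[j]) sprintf("abn<%.1e in every stratum (max %.2e)",
                                        th$abn_stratum, suppressWarnings(max(strat_ab[j, ], na.rm = TRUE))),
      if (low_overall[j]) sprintf("overall abn %.2e < %.1e", overall_ab[j], th$abn_overall),
      if (low_every_site[j]) sprintf("prev<%.2g in every site (max %.3g)",
                                     th$prev_site, max(prev_by_site[j, ])),
      if (too_few[j]) sprintf("in %d < %d samples", n_pos[j], th$prev_min_samples))
    paste(clauses, collapse = "; ")
  }, character(1))
  log <- removal_log(asvs, rep("asv", length(asvs)),
                     rep("low_abundance_prevalence", length(asvs)), detail)
  list(table = subset_asv_table(table, asvs = setdiff(colnames(table), asvs)),
       log = log)
}

#' Detect kitome (negative-control contaminant) ASVs
#'
#' Splits samples by site with the negative controls as an extra stratum and
#' flags an ASV as a kit contaminant iff (1) its prevalence among control
#' samples is strictly greater than `kit_prev` and (2) its pooled relative
#' abundance in the controls exceeds its pooled relative abundance over all
#' non-control samples combined.
#'
#' @inheritParams filter_low_abundance_prevalence
#' @return list with `kitome` (character ASV IDs) and `evidence`
#'   (data.frame of the two measured quantities per ASV, all ASVs).
#' @export
detect_kitome <- function(table, meta, th = filter_thresholds()) {
  meta <- align_metadata(table, meta)
  ctl <- meta$is_control
  if (!any(ctl)) stop("no control samples; cannot assess the kitome")
  cm <- unclass(table)[ctl, , drop = FALSE]
  prev_ctl <- colMeans(cm > 0)
  ab_ctl <- stratum_relabund(table, rownames(table)[ctl], th$mean_per_sample)
  ab_body <- stratum_relabund(table, rownames(table)[!ctl], th$mean_per_sample)
  flagged <- (prev_ctl > th$kit_prev) & (ab_ctl > ab_body)
  flagged[is.na(flagged)] <- FALSE
  evidence <- data.frame(asv_id = colnames(table),
                         control_prevalence = prev_ctl,
                         control_abundance = ab_ctl,
                         body_abundance = ab_body,
                         flagged = flagged,
                         row.names = NULL, stringsAsFactors = FALSE)
  list(kitome = colnames(table)[flagged], evidence = evidence)
}

#' Remove a set of ASVs from a table
#'
#' @param table an [asv_table()].
#' @param asvs character, ASV IDs to drop (must exist in the table).
#' @param rule_id label recorded in the removal log.
#' @return list with `table`, `log`, and `reads_removed` (per-sample
#'   fraction of reads removed).
#' @export
remove_asvs <- function(table, asvs, rule_id = "kitome") {
  unknown <- setdiff(asvs, colnames(table))
  if (length(unknown)) stop("unknown ASV(s): ", paste(unknown, collapse = ", "))
  before <- rowSums(unclass(table))
  out <- subset_asv_table(table, asvs = setdiff(colnames(table), asvs))
  after <- rowSums(unclass(out))
  frac <- ifelse(before > 0, (before - after) / before, 0)
  tot <- colSums(unclass(table))[asvs]
  log <- removal_log(asvs, rep("asv", length(asvs)),
                     rep(rule_id, length(asvs)),
                     sprintf("total reads %d", as.integer(tot)))
  list(table = out, log = log, reads_removed = frac)
}

#' Discard samples with too few reads
#'
#' Removes every sample whose read total is strictly below `min_reads`
#' ("less than 1000 reads after filtering"), the last filter in the chain.
#'
#' @inheritParams filter_low_abundance_prevalence
#' @return list with `table` and `log`.
#' @export
filter_samples_min_reads <- function(table, th = filter_thresholds()) {
  totals <- rowSums(unclass(table))
  drop <- totals < th$min_reads
  log <- removal_log(rownames(table)[drop], rep("sample", sum(drop)),
                     rep("min_reads", sum(drop)),
                     sprintf("%d reads < %d", as.integer(totals[drop]), th$min_reads))
  if (all(drop)) warning("all samples below the read threshold; empty table")
  list(table = subset_asv_table(table, samples = rownames(table)[!drop]),
       log = log)
}

#' Rarefy a count table to a common depth
#'
#' Subsamples each sample's reads uniformly without replacement to exactly
#' `depth` reads (hypergeometric subsampling).  Samples with fewer than
#' `depth` reads are dropped and reported in the `dropped` attribute.
#' Deterministic given `seed`.
#'
#' @param table an [asv_table()].
#' @param depth target depth (reads); default the minimum sample total.
#' @param seed integer seed.
#' @return A rarefied `asv_table`; attribute `dropped` lists removed samples.
#' @export
rarefy <- function(table, depth = NULL, seed = 1L) {
  totals <- rowSums(unclass(table))
  if (is.null(depth)) depth <- min(totals)
  depth <- as.integer(depth)
  if (depth <= 0) stop("depth must be >= 1")
  keep <- totals >= depth
  dropped <- rownames(table)[!keep]
  m <- unclass(table)[keep, , drop = FALSE]
  out <- withr::with_seed(seed, {
    t(apply(m, 1, function(counts) {
      if (sum(counts) == depth) return(counts)
      reads <- rep.int(seq_along(counts), counts)
      tabulate(sample(reads, depth), nbins = length(counts))
    }))
  })
  dimnames(out) <- dimnames(m)
  res <- asv_table(out)
  attr(res, "dropped") <- dropped
  attr(res, "depth") <- depth
  res
}
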