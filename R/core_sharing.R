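#' Animal-level community at one site and time
#'
#' The unit on which core membership and cross-site sharing are defined.
#' Milk quarter samples of the same animal/time are aggregated by summing
#' counts before computing presence (count > 0) and relative abundance
#' (union semantics); other sites have a single sample.
#'
#' @param table an [asv_table()] (filtered, unrarefied by default policy).
#' @param meta matching [sample_metadata()].
#' @param animal,site,time stratum selectors.
#' @return Named numeric vector of relative abundances over the ASVs
#'   present in the community, or `NULL` if the animal has no sample (the
#'   community is missing and must be excluded from denominators).
#' @export
animal_site_community <- function(table, meta, animal, site, time) {
  meta <- align_metadata(table, meta)
  sel <- !meta$is_control & meta$animal_id == animal &
    meta$site == site & meta$time == time
  if (!any(sel)) return(NULL)
  counts <- colSums(unclass(table)[sel, , drop = FALSE])
  total <- sum(counts)
  if (total == 0) return(stats::setNames(numeric(0), character(0)))
  pos <- counts > 0
  counts[pos] / total
}

#' All animal-level communities for one time point
#'
#' @inheritParams animal_site_community
#' @param sites sites to build (default: all non-control sites present).
#' @param animals animals to build (default: all).
#' @return Nested list: `communities[[animal]][[site]]` is a named relative
#'   abundance vector, or absent when the animal has no sample there.
#' @export
build_communities <- function(table, meta, time, sites = NULL, animals = NULL) {
  meta <- align_metadata(table, meta)
  body <- meta[!meta$is_control & meta$time == time, , drop = FALSE]
  if (is.null(sites)) sites <- setdiff(unique(body$site), "control")
  if (is.null(animals)) animals <- sort(unique(body$animal_id))
  m <- unclass(table)
  out <- list()
  for (animal in animals) {
    per_site <- list()
    for (site in sites) {
      sel <- body$sample_id[body$animal_id == animal & body$site == site]
      if (!length(sel)) next
      counts <- colSums(m[sel, , drop = FALSE])
      total <- sum(counts)
      per_site[[site]] <- if (total == 0) {
        stats::setNames(numeric(0), character(0))
      } else {
        pos <- counts > 0
        counts[pos] / total
      }
    }
    if (length(per_site)) out[[animal]] <- per_site
  }
  out
}

#' Core microbiota of a site at a time point
#'
#' An ASV is core iff its animal-level relative abundance exceeds
#' `abn_core` (strictly; "higher than 0.01%") in at least `prev_core` of
#' the animals that have a community in the stratum (`strict_prevalence`
#' switches the prevalence comparison to strictly greater).
#'
#' @inheritParams animal_site_community
#' @param abn_core relative abundance threshold (default 1e-4, i.e. 0.01%).
#' @param prev_core prevalence threshold over animals (default 0.5).
#' @param strict_prevalence if `TRUE`, require prevalence strictly above
#'   `prev_core`.
#' @return list of class `core_set`: `site`, `time`, `core_asvs`,
#'   `evidence` (per-ASV prevalence and mean relative abundance among
#'   positive animals), `n_core`, `n_total` (ASVs present in >= 1 animal
#'   community), `core_fraction`, `per_animal` (fraction of each animal's
#'   own ASVs that are core), `n_animals`.
#' @export
core_microbiota <- function(table, meta, site, time, abn_core = 1e-4,
                            prev_core = 0.5, strict_prevalence = FALSE) {
  comm <- build_communities(table, meta, time = time, sites = site)
  mats <- lapply(comm, function(a) a[[site]])
  mats <- mats[!vapply(mats, is.null, logical(1))]
  if (length(mats) < 2) stop("fewer than 2 animals with a community in ",
                             site, " at ", time)
  n_animals <- length(mats)
  all_asvs <- sort(unique(unlist(lapply(mats, names))))
  above <- vapply(mats, function(v) {
    x <- stats::setNames(logical(length(all_asvs)), all_asvs)
    x[names(v)[v > abn_core]] <- TRUE
    x
  }, logical(length(all_asvs)))
  if (is.null(dim(above))) above <- matrix(above, nrow = length(all_asvs))
  prev <- rowMeans(above)
  is_core <- if (strict_prevalence) prev > prev_core else prev >= prev_core
  core_asvs <- all_asvs[is_core]
  mean_ab <- vapply(all_asvs, function(a) {
    vals <- vapply(mats, function(v) if (a %in% names(v)) v[[a]] else 0, numeric(1))
    mean(vals)
  }, numeric(1))
  per_animal <- vapply(mats, function(v) {
    if (!length(v)) return(NA_real_)
    mean(names(v) %in% core_asvs)
  }, numeric(1))
  structure(list(site = site, time = time, core_asvs = core_asvs,
                 evidence = data.frame(asv_id = all_asvs, prevalence = prev,
                                       mean_abundance = mean_ab,
                                       core = is_core, row.names = NULL,
                                       stringsAsFactors = FALSE),
                 n_core = length(core_asvs), n_total = length(all_asvs),
                 core_fraction = length(core_asvs) / max(length(all_asvs), 1),
                 per_animal = per_animal, n_animals = n_animals),
            class = "core_set")
}

#' Pairwise within-animal cross-site ASV sharing
#'
#' For every animal and unordered site pair with both communities present:
#' the number of shared ASVs, the fraction of each site's community that is
#' shared (n_shared / community size), and the summed relative abundance of
#' the shared ASVs in each site.
#'
#' @inheritParams animal_site_community
#' @param sites sites considered (default: all present at `time`).
#' @return list of class `sharing_report`: `pairwise` (one row per animal
#'   and pair), `summary` (per-pair mean/median of the four statistics),
#'   `n_two_way_occurrences` (total count of (ASV, animal, pair) sharing
#'   tuples), `skipped` (animal/pair combinations lacking a community).
#' @export
pairwise_sharing <- function(table, meta, time, sites = NULL) {
  comm <- build_communities(table, meta, time = time, sites = sites)
  if (is.null(sites)) {
    sites <- sort(unique(unlist(lapply(comm, names))))
  }
  rows <- list(); skipped <- list()
  for (animal in names(comm)) {
    a <- comm[[animal]]
    for (i in seq_along(sites)) for (j in seq_along(sites)) {
      if (i >= j) next
      s1 <- sites[i]; s2 <- sites[j]
      if (is.null(a[[s1]]) || is.null(a[[s2]])) {
        skipped[[length(skipped) + 1]] <- data.frame(
          animal = animal, site1 = s1, site2 = s2, stringsAsFactors = FALSE)
        next
      }
      shared <- intersect(names(a[[s1]]), names(a[[s2]]))
      rows[[length(rows) + 1]] <- data.frame(
        animal = animal, time = time, site1 = s1, site2 = s2,
        n_shared = length(shared),
        n_site1 = length(a[[s1]]), n_site2 = length(a[[s2]]),
        fraction_in_site1 = if (length(a[[s1]])) length(shared) / length(a[[s1]]) else 0,
        fraction_in_site2 = if (length(a[[s2]])) length(shared) / length(a[[s2]]) else 0,
        relabund_in_site1 = sum(a[[s1]][shared]),
        relabund_in_site2 = sum(a[[s2]][shared]),
        stringsAsFactors = FALSE)
    }
  }
  pairwise <- if (length(rows)) do.call(rbind, rows) else
    data.frame(animal = character(), time = character(), site1 = character(),
               site2 = character(), n_shared = integer(), n_site1 = integer(),
               n_site2 = integer(), fraction_in_site1 = numeric(),
               fraction_in_site2 = numeric(), relabund_in_site1 = numeric(),
               relabund_in_site2 = numeric(), stringsAsFactors = FALSE)
  summ <- NULL
  if (nrow(pairwise)) {
    key <- paste(pairwise$site1, pairwise$site2, sep = "-")
    summ <- do.call(rbind, lapply(split(pairwise, key), function(df) {
      data.frame(site1 = df$site1[1], site2 = df$site2[1], n_animals = nrow(df),
                 mean_fraction_site1 = mean(df$fraction_in_site1),
                 median_fraction_site1 = stats::median(df$fraction_in_site1),
                 mean_fraction_site2 = mean(df$fraction_in_site2),
                 median_fraction_site2 = stats::median(df$fraction_in_site2),
                 mean_relabund_site1 = mean(df$relabund_in_site1),
                 mean_relabund_site2 = mean(df$relabund_in_site2),
                 stringsAsFactors = FALSE)
    }))
    rownames(summ) <- NULL
  }
  structure(list(pairwise = pairwise, summary = summ,
                 n_two_way_occurrences = sum(pairwise$n_shared),
                 skipped = if (length(skipped)) do.call(rbind, skipped) else NULL),
            class = "sharing_report")
}

#' Multi-way within-animal ASV sharing
#'
#' An occurrence is a tuple (ASV, animal, time, site combination of size 3
#' or 4) in which the ASV is present in every site of the combination for
#' that animal.  Only animals with communities at all sites of a
#' combination contribute to it.
#'
#' @inheritParams pairwise_sharing
#' @return list of class `multiway_report`: `records` (one row per
#'   occurrence), `tallies` (named counts of 3-way and 4-way occurrences),
#'   `distinct_asvs` (per combination size), `asv_animal_counts` (per ASV,
#'   number of animals in which it is shared by >= 3 sites).
#' @export
multiway_sharing <- function(table, meta, time, sites = NULL) {
  comm <- build_communities(table, meta, time = time, sites = sites)
  if (is.null(sites)) sites <- sort(unique(unlist(lapply(comm, names))))
  rows <- list()
  for (animal in names(comm)) {
    a <- comm[[animal]]
    for (size in 3:4) {
      if (length(sites) < size) next
      combos <- utils::combn(sites, size, simplify = FALSE)
      for (cb in combos) {
        if (any(vapply(cb, function(s) is.null(a[[s]]), logical(1)))) next
        shared <- Reduce(intersect, lapply(cb, function(s) names(a[[s]])))
        for (asv in shared) {
          rows[[length(rows) + 1]] <- data.frame(
            asv_id = asv, animal = animal, time = time,
            combo = paste(cb, collapse = "+"), size = size,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  records <- if (length(rows)) do.call(rbind, rows) else
    data.frame(asv_id = character(), animal = character(), time = character(),
               combo = character(), size = integer(), stringsAsFactors = FALSE)
  tallies <- c(three_way = sum(records$size == 3),
               four_way = sum(records$size == 4))
  r3 <- records[records$size == 3, , drop = FALSE]
  per_asv <- if (nrow(r3)) {
    tapply(r3$animal, r3$asv_id, function(x) length(unique(x)))
  } else {
    stats::setNames(integer(0), character(0))
  }
  structure(list(records = records, tallies = tallies,
                 distinct_asvs = c(three_way = length(unique(r3$asv_id)),
                                   four_way = length(unique(records$asv_id[records$size == 4])),
                                   any_multiway = length(unique(records$asv_id))),
                 asv_animal_counts = per_asv),
            class = "multiway_report")
}

#' Cross-site overlap and temporal persistence of core ASVs
#'
#' Venn-style membership counts of core ASVs across sites at a fixed time,
#' and persistence of core ASVs across consecutive times within a site.
#'
#' @param cores list of `core_set` objects (from [core_microbiota()]).
#' @return list: `membership` (per core ASV, which site/time cores contain
#'   it), `site_overlap` (at each time, counts of core ASVs by the number
#'   of sites sharing them), `persistence` (within each site, the fraction
#'   of time-t core ASVs still core at the next time).
#' @export
herd_core_overlap <- function(cores) {
  if (length(cores) < 2) stop("need >= 2 core sets")
  info <- data.frame(site = vapply(cores, `[[`, "", "site"),
                     time = vapply(cores, `[[`, "", "time"),
                     stringsAsFactors = FALSE)
  membership <- do.call(rbind, lapply(seq_along(cores), function(i) {
    cs <- cores[[i]]
    if (!length(cs$core_asvs)) return(NULL)
    data.frame(asv_id = cs$core_asvs, site = cs$site, time = cs$time,
               stringsAsFactors = FALSE)
  }))
  site_overlap <- NULL
  if (!is.null(membership)) {
    site_overlap <- do.call(rbind, lapply(split(membership, membership$time), function(df) {
      k <- tapply(df$site, df$asv_id, function(x) length(unique(x)))
      data.frame(time = df$time[1],
                 n_sites = as.integer(names(table(k))),
                 n_asvs = as.integer(table(k)), stringsAsFactors = FALSE)
    }))
    rownames(site_overlap) <- NULL
  }
  persistence <- list()
  for (site in unique(info$site)) {
    idx <- which(info$site == site)
    idx <- idx[order(match(info$time[idx], TIME_LEVELS))]
    if (length(idx) < 2) next
    for (i in seq_len(length(idx) - 1)) {
      a <- cores[[idx[i]]]; b <- cores[[idx[i + 1]]]
      persistence[[length(persistence) + 1]] <- data.frame(
        site = site, time1 = a$time, time2 = b$time,
        n_core_t1 = length(a$core_asvs),
        n_persisting = length(intersect(a$core_asvs, b$core_asvs)),
        fraction = if (length(a$core_asvs))
          length(intersect(a$core_asvs, b$core_asvs)) / length(a$core_asvs)
        else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  list(membership = membership, site_overlap = site_overlap,
       persistence = if (length(persistence)) do.call(rbind, persistence) else NULL)
}
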