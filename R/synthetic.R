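#' Synthetic herd configuration
#'
#' Parameters of the generative model for a herd-structured multi-site ASV
#' dataset with planted contaminants, core taxa and within-animal
#' cross-site transfer. Defaults emulate the longitudinal dairy-herd design
#' the pipeline targets: 45 animals in three groups sampled at four sites
#' and four time points, 66 extraction negative controls, a contaminant
#' load that carries over inversely with site biomass (milk lowest, so milk
#' shows the largest kitome read fraction), and sequencing depths around
#' 10^4 reads.
#'
#' @param n_animals number of animals.
#' @param sites body sites.
#' @param timepoints time levels, chronological.
#' @param pool_size P, size of the global template ASV pool.
#' @param site_pool_size S, template ASVs per site (P >= S).
#' @param f_core fraction of each site template forced present in every
#'   animal (the planted core).
#' @param occupancy probability a non-core template ASV occurs in a given
#'   animal.
#' @param f_share per-ASV probability of cross-site transfer within an
#'   animal, per ordered site pair.
#' @param transfer_scale multiplicative abundance factor applied on transfer.
#' @param n_private animal-private ASVs per animal-site community.
#' @param time_turnover fraction of each community replaced (lowest
#'   abundance first) between consecutive time points.
#' @param lognormal_mu,lognormal_sigma log-normal parameters of template
#'   abundances.
#' @param jitter_sigma sdlog of the animal-specific abundance jitter.
#' @param n_controls number of negative-control samples.
#' @param n_kitome K, number of planted kit-contaminant ASVs.
#' @param kit_load lambda, expected contaminant read fraction in the lowest
#'   biomass site; carry-over into a site is kit_load * min(biomass) /
#'   biomass[site].
#' @param biomass named per-site relative biomass.
#' @param depth_mu,depth_sigma log-normal sequencing depth parameters
#'   (depths rounded, floored at 200 reads).
#' @param milk_quarters milk samples per animal/time (quarters); other
#'   sites always have one sample.
#' @param disjoint_templates if `TRUE`, site templates partition the pool
#'   (requires pool_size >= site_pool_size * n sites).
#' @param overdispersion optional Dirichlet precision; when set, sample
#'   compositions are Dirichlet-resampled before the multinomial draw.
#' @param seed integer seed; identical seed + config give bit-identical
#'   output.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_animals = 45L,
                             sites = c("oral", "nasal", "vaginal", "milk"),
                             timepoints = c("-1W", "1M", "3M", "7M"),
                             pool_size = 600L, site_pool_size = 150L,
                             f_core = 0.05, occupancy = 0.3,
                             f_share = 0.1, transfer_scale = 0.5,
                             n_private = 20L, time_turnover = 0.3,
                             lognormal_mu = 0, lognormal_sigma = 1,
                             jitter_sigma = 0.5,
                             n_controls = 66L, n_kitome = 60L,
                             kit_load = 0.15,
                             biomass = c(oral = 10, nasal = 10, vaginal = 3, milk = 1),
                             depth_mu = log(10000), depth_sigma = 0.6,
                             milk_quarters = 1L,
                             disjoint_templates = FALSE,
                             overdispersion = NULL,
                             seed = 1L) {
  cfg <- list(n_animals = as.integer(n_animals), sites = sites,
              timepoints = timepoints, pool_size = as.integer(pool_size),
              site_pool_size = as.integer(site_pool_size), f_core = f_core,
              occupancy = occupancy, f_share = f_share,
              transfer_scale = transfer_scale, n_private = as.integer(n_private),
              time_turnover = time_turnover, lognormal_mu = lognormal_mu,
              lognormal_sigma = lognormal_sigma, jitter_sigma = jitter_sigma,
              n_controls = as.integer(n_controls), n_kitome = as.integer(n_kitome),
              kit_load = kit_load, biomass = biomass, depth_mu = depth_mu,
              depth_sigma = depth_sigma, milk_quarters = as.integer(milk_quarters),
              disjoint_templates = isTRUE(disjoint_templates),
              overdispersion = overdispersion, seed = as.integer(seed))
  probs <- c("f_core", "occupancy", "f_share", "time_turnover")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]")
  }
  if (cfg$kit_load < 0 || cfg$kit_load > 1) stop("kit_load must be in [0, 1]")
  if (cfg$pool_size < cfg$site_pool_size || cfg$site_pool_size < 1) {
    stop("need pool_size >= site_pool_size >= 1")
  }
  if (cfg$disjoint_templates &&
      cfg$pool_size < cfg$site_pool_size * length(cfg$sites)) {
    stop("disjoint templates need pool_size >= site_pool_size * n sites")
  }
  if (cfg$n_animals < 1 || cfg$n_controls < 0 || cfg$n_kitome < 0 ||
      cfg$n_private < 0 || cfg$milk_quarters < 1) {
    stop("counts must be non-negative (n_animals, milk_quarters >= 1)")
  }
  if (cfg$n_controls > 0 && cfg$n_kitome > 0 && cfg$kit_load == 0) {
    stop("no contaminant mass: controls requested with kit_load = 0")
  }
  if (cfg$n_controls > 0 && cfg$n_kitome == 0) {
    stop("no contaminant mass: controls requested with n_kitome = 0")
  }
  miss <- setdiff(cfg$sites, names(cfg$biomass))
  if (length(miss)) stop("biomass missing for site(s): ", paste(miss, collapse = ", "))
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic herd
#'
#' Executes the generative model with a seeded pseudo-random stream:
#' site templates with log-normal abundances and a planted core; per
#' animal-site communities (core + occupancy-thinned non-core + private
#' ASVs, abundances jittered per animal); per-time-point turnover replacing
#' the lowest-abundance fraction with fresh private ASVs; within-animal
#' cross-site transfers at rate `f_share`; kit contaminants mixed into real
#' samples inversely to site biomass and making up all of the negative
#' controls; multinomial read sampling at log-normal depths; and a random
#' bifurcating tree with exponential branch lengths over all ASVs.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_herd`: `table` ([asv_table()]),
#'   `metadata` ([sample_metadata()]), `tree` (ape `phylo`), `truth`
#'   (class `herd_truth`: `kitome_asvs`, `core_asvs` per site, `transfers`
#'   data.frame, `communities[[time]][[animal]][[site]]` pre-noise
#'   abundance vectors, and the `config`).
#' @export
generate_herd <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  withr::with_seed(cfg$seed, {
    animals <- sprintf("A%02d", seq_len(cfg$n_animals))
    group_sizes <- c(G1 = 0.4, G2 = 0.33, G3 = 0.27)  # 18/15/12 of 45
    groups <- rep(names(group_sizes),
                  times = diff(round(cumsum(c(0, group_sizes)) * cfg$n_animals)))
    groups <- groups[seq_len(cfg$n_animals)]
    sm <- stats::rnorm(cfg$n_animals)
    bc <- stats::rnorm(cfg$n_animals)

    # (1) pool, site templates, planted core
    pool <- sprintf("ASV%04d", seq_len(cfg$pool_size))
    templates <- list()
    core_asvs <- list()
    for (si in seq_along(cfg$sites)) {
      site <- cfg$sites[si]
      ids <- if (cfg$disjoint_templates) {
        pool[((si - 1) * cfg$site_pool_size + 1):(si * cfg$site_pool_size)]
      } else {
        sample(pool, cfg$site_pool_size)
      }
      ab <- stats::rlnorm(cfg$site_pool_size, cfg$lognormal_mu, cfg$lognormal_sigma)
      names(ab) <- ids
      n_core <- ceiling(cfg$f_core * cfg$site_pool_size)
      core <- if (n_core > 0) sample(ids, n_core) else character(0)
      templates[[site]] <- ab
      core_asvs[[site]] <- sort(core)
    }

    # (2) base communities at the first time point
    private_counter <- 0L
    fresh_private <- function(n) {
      if (n == 0) return(character(0))
      ids <- sprintf("PRV%05d", private_counter + seq_len(n))
      private_counter <<- private_counter + n
      ids
    }
    base <- list()   # base[[animal]][[site]] named abundances (pre-transfer)
    for (animal in animals) {
      per_site <- list()
      for (site in cfg$sites) {
        tmpl <- templates[[site]]
        core <- core_asvs[[site]]
        noncore <- setdiff(names(tmpl), core)
        kept <- noncore[stats::runif(length(noncore)) < cfg$occupancy]
        ids <- c(core, kept)
        ab <- tmpl[ids] * stats::rlnorm(length(ids), 0, cfg$jitter_sigma)
        priv <- fresh_private(cfg$n_private)
        if (length(priv)) {
          ab <- c(ab, stats::setNames(
            stats::rlnorm(length(priv), cfg$lognormal_mu, cfg$lognormal_sigma),
            priv))
        }
        per_site[[site]] <- ab
      }
      base[[animal]] <- per_site
    }

    # (3)+(4) turnover chain on pre-transfer communities; transfers applied
    # fresh per time point so sharing does not compound over time
    communities <- list()   # communities[[time]][[animal]][[site]] (post-transfer)
    transfers <- list()
    for (ti in seq_along(cfg$timepoints)) {
      tp <- cfg$timepoints[ti]
      if (ti > 1) {
        for (animal in animals) {
          for (site in cfg$sites) {
            ab <- base[[animal]][[site]]
            n_replace <- floor(cfg$time_turnover * length(ab))
            if (n_replace > 0) {
              keep <- names(sort(ab, decreasing = TRUE))[seq_len(length(ab) - n_replace)]
              ab <- ab[keep]
              priv <- fresh_private(n_replace)
              ab <- c(ab, stats::setNames(
                stats::rlnorm(n_replace, cfg$lognormal_mu, cfg$lognormal_sigma),
                priv))
            }
            ab <- ab * stats::rlnorm(length(ab), 0, cfg$jitter_sigma)
            base[[animal]][[site]] <- ab
          }
        }
      }
      snap <- list()
      for (animal in animals) {
        comm <- base[[animal]]
        if (cfg$f_share > 0 && length(cfg$sites) > 1) {
          for (src in cfg$sites) for (dst in cfg$sites) {
            if (src == dst) next
            src_ab <- base[[animal]][[src]]  # transfers read pre-transfer state
            moved <- names(src_ab)[stats::runif(length(src_ab)) < cfg$f_share]
            if (!length(moved)) next
            add <- src_ab[moved] * cfg$transfer_scale
            old <- intersect(moved, names(comm[[dst]]))
            comm[[dst]][old] <- comm[[dst]][old] + add[old]
            new <- setdiff(moved, old)
            if (length(new)) comm[[dst]] <- c(comm[[dst]], add[new])
            transfers[[length(transfers) + 1]] <- data.frame(
              animal = animal, time = tp, source = src, target = dst,
              asv_id = moved, stringsAsFactors = FALSE)
          }
        }
        snap[[animal]] <- comm
      }
      communities[[tp]] <- snap
    }

    # (5) contamination profile
    kit_ids <- if (cfg$n_kitome > 0) sprintf("KIT%03d", seq_len(cfg$n_kitome)) else character(0)
    kit_profile <- if (cfg$n_kitome > 0) {
      w <- stats::rlnorm(cfg$n_kitome, cfg$lognormal_mu, cfg$lognormal_sigma)
      stats::setNames(w / sum(w), kit_ids)
    } else {
      stats::setNames(numeric(0), character(0))
    }
    min_bio <- min(cfg$biomass[cfg$sites])

    all_ids <- c(pool,
                 sprintf("PRV%05d", seq_len(private_counter)),
                 kit_ids)
    id_index <- stats::setNames(seq_along(all_ids), all_ids)

    # (6) sample compositions and multinomial reads
    sample_rows <- list()
    meta_rows <- list()
    add_sample <- function(sid, comp_named, animal, site, tp, quarter) {
      depth <- max(200L, as.integer(round(stats::rlnorm(1, cfg$depth_mu, cfg$depth_sigma))))
      p <- comp_named / sum(comp_named)
      if (!is.null(cfg$overdispersion)) {
        gam <- stats::rgamma(length(p), shape = p * cfg$overdispersion)
        if (sum(gam) > 0) p <- gam / sum(gam)
      }
      counts <- stats::rmultinom(1, depth, p)[, 1]
      sample_rows[[length(sample_rows) + 1]] <<- list(
        sid = sid, idx = id_index[names(comp_named)], counts = counts)
      meta_rows[[length(meta_rows) + 1]] <<- data.frame(
        sample_id = sid,
        animal_id = if (is.na(animal)) NA_character_ else animal,
        site = site, time = tp,
        group = if (is.na(animal)) NA_character_ else groups[match(animal, animals)],
        sm_score = if (is.na(animal)) NA_real_ else sm[match(animal, animals)],
        bc_score = if (is.na(animal)) NA_real_ else bc[match(animal, animals)],
        quarter = quarter, is_control = site == "control",
        stringsAsFactors = FALSE)
    }
    for (tp in cfg$timepoints) {
      for (animal in animals) {
        for (site in cfg$sites) {
          ab <- communities[[tp]][[animal]][[site]]
          comp <- ab / sum(ab)
          carry <- cfg$kit_load * min_bio / cfg$biomass[[site]]
          if (cfg$n_kitome > 0 && carry > 0) {
            comp <- c(comp * (1 - carry), kit_profile * carry)
          }
          nq <- if (site == "milk") cfg$milk_quarters else 1L
          for (q in seq_len(nq)) {
            sid <- if (nq > 1) sprintf("%s_%s_%s_Q%d", animal, site, tp, q)
            else sprintf("%s_%s_%s", animal, site, tp)
            add_sample(sid, comp, animal, site, tp,
                       if (nq > 1) sprintf("Q%d", q) else NA_character_)
          }
        }
      }
    }
    if (cfg$n_controls > 0) {
      for (k in seq_len(cfg$n_controls)) {
        add_sample(sprintf("NC%02d", k), kit_profile, NA_character_,
                   "control", NA_character_, NA_character_)
      }
    }

    counts <- matrix(0L, nrow = length(sample_rows), ncol = length(all_ids),
                     dimnames = list(vapply(sample_rows, `[[`, "", "sid"), all_ids))
    for (r in seq_along(sample_rows)) {
      counts[r, sample_rows[[r]]$idx] <- sample_rows[[r]]$counts
    }
    observed <- colSums(counts) > 0
    table <- asv_table(counts[, observed, drop = FALSE])
    meta <- sample_metadata(do.call(rbind, meta_rows),
                            times = cfg$timepoints,
                            groups = unique(groups))

    # (7) random bifurcating tree over every ASV, exponential branch lengths
    tree <- ape::rtree(length(all_ids), tip.label = all_ids,
                       br = function(n) stats::rexp(n, rate = 10))

    truth <- structure(list(
      kitome_asvs = kit_ids,
      core_asvs = core_asvs,
      templates = templates,
      transfers = if (length(transfers)) do.call(rbind, transfers) else
        data.frame(animal = character(), time = character(), source = character(),
                   target = character(), asv_id = character(), stringsAsFactors = FALSE),
      communities = communities,
      config = cfg), class = "herd_truth")
    structure(list(table = table, metadata = meta, tree = tree, truth = truth),
              class = "synthetic_herd")
  })
}

#' Expected cross-site shared fractions from the generator truth
#'
#' Oracle for parameter recovery: computes, from the realized pre-noise
#' communities, the exact fraction of each site's ASVs also present in the
#' other site of the pair, per animal and time.
#'
#' @param truth the `herd_truth` of a [generate_herd()] call.
#' @param pair character vector of two sites.
#' @return data.frame: animal, time, `fraction_in_site1` (fraction of the
#'   first site's ASVs shared), `fraction_in_site2`.
#' @export
truth_sharing_fraction <- function(truth, pair) {
  stopifnot(inherits(truth, "herd_truth"), length(pair) == 2)
  miss <- setdiff(pair, truth$config$sites)
  if (length(miss)) stop("unknown site(s): ", paste(miss, collapse = ", "))
  rows <- list()
  for (tp in names(truth$communities)) {
    for (animal in names(truth$communities[[tp]])) {
      a <- truth$communities[[tp]][[animal]]
      s1 <- names(a[[pair[1]]]); s2 <- names(a[[pair[2]]])
      shared <- length(intersect(s1, s2))
      rows[[length(rows) + 1]] <- data.frame(
        animal = animal, time = tp,
        fraction_in_site1 = if (length(s1)) shared / length(s1) else 0,
        fraction_in_site2 = if (length(s2)) shared / length(s2) else 0,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write the synthetic inputs to a directory
#'
#' Writes the three pipeline input files (counts TSV, metadata TSV, newick
#' tree) plus a JSON ground-truth summary.
#'
#' @param herd a `synthetic_herd` from [generate_herd()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_herd <- function(herd, dir) {
  stopifnot(inherits(herd, "synthetic_herd"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_asv_table(herd$table, file.path(dir, "counts.tsv"))
  write_metadata(herd$metadata, file.path(dir, "metadata.tsv"))
  write_tree(herd$tree, file.path(dir, "tree.nwk"))
  jsonlite::write_json(
    list(kitome_asvs = herd$truth$kitome_asvs,
         core_asvs = herd$truth$core_asvs,
         transfers = herd$truth$transfers),
    file.path(dir, "truth.json"))
  invisible(dir)
}
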