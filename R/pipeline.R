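#' Pipeline configuration
#'
#' Bundles everything one analysis run needs: input (paths to the three
#' input files, or a [synthetic_config()] to simulate them), filtering
#' thresholds, rarefaction policy, beta metrics, PERMANOVA model, cluster
#' count and core thresholds. A master seed derives per-stage seeds
#' deterministically, so adding stages never perturbs earlier stages'
#' randomness.
#'
#' @param input a [synthetic_config()], or a named list with `counts`,
#'   `metadata`, `tree` file paths.
#' @param thresholds a [filter_thresholds()].
#' @param rarefy_depth rarefaction depth; `NULL` uses the minimum retained
#'   sample total.
#' @param metrics beta-diversity metrics to compute.
#' @param permanova_terms metadata columns for the PERMANOVA model, in order.
#' @param n_perm permutations for PERMANOVA and the dispersion test.
#' @param k_clusters dendrogram cut for the stability analysis.
#' @param core_abn,core_prev core-microbiota thresholds.
#' @param out_dir output directory for artifacts (`NULL`: nothing written).
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = synthetic_config(),
                            thresholds = filter_thresholds(),
                            rarefy_depth = NULL,
                            metrics = c("jaccard", "bray", "unifrac", "wunifrac"),
                            permanova_terms = c("group", "site", "time",
                                                "sm_score", "bc_score", "animal_id"),
                            n_perm = 999L, k_clusters = 5L,
                            core_abn = 1e-4, core_prev = 0.5,
                            out_dir = NULL, seed = 1L) {
  structure(list(input = input, thresholds = thresholds,
                 rarefy_depth = rarefy_depth, metrics = metrics,
                 permanova_terms = permanova_terms, n_perm = as.integer(n_perm),
                 k_clusters = as.integer(k_clusters), core_abn = core_abn,
                 core_prev = core_prev, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Derive a per-stage seed from the master seed
#'
#' Deterministic hash of (master seed, stage name), kept below 2^31.
#'
#' @param master integer master seed.
#' @param stage stage name.
#' @return integer seed.
#' @export
stage_seed <- function(master, stage) {
  h <- as.double(master) %% 2147483647
  for (c in utf8ToInt(stage)) h <- (h * 69069 + c) %% 2147483647
  as.integer(h)
}

#' Run the full analysis pipeline
#'
#' Stage order: ingest/simulate, low-abundance/prevalence filter, kitome
#' removal, minimum-reads filter, then rarefied analyses (alpha diversity
#' with per-time ANOVA+Tukey across sites, beta diversity, ordination,
#' PERMANOVA, per-time dispersion test on site, per-site cluster
#' stability) and unrarefied analyses (core microbiota, pairwise and
#' multi-way sharing). Every artifact is written under `out_dir` (when
#' set) and hashed into the run manifest; re-running with the same config
#' is bit-identical.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_run` with all stage results, the
#'   removal logs, the manifest data.frame, and (for synthetic input) the
#'   ground truth.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  t0 <- Sys.time()
  note <- function(stage, seed = NA_integer_, files = character()) {
    hashes <- if (length(files)) unname(tools::md5sum(files)) else character()
    manifest[[length(manifest) + 1]] <<- data.frame(
      stage = stage, seed = seed,
      files = paste(basename(files), collapse = ";"),
      md5 = paste(hashes, collapse = ";"),
      elapsed_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3),
      stringsAsFactors = FALSE)
  }
  emit <- function(name, writer) {
    if (is.null(out_dir)) return(character())
    path <- file.path(out_dir, name)
    writer(path)
    path
  }

  # stage 1: ingest or simulate
  truth <- NULL
  if (inherits(config$input, "synthetic_config")) {
    herd <- generate_herd(config$input)
    table <- herd$table; meta <- herd$metadata; tree <- herd$tree
    truth <- herd$truth
    files <- c(emit("counts.tsv", function(p) write_asv_table(table, p)),
               emit("metadata.tsv", function(p) write_metadata(meta, p)),
               emit("tree.nwk", function(p) write_tree(tree, p)))
    note("simulate", config$input$seed, files)
  } else {
    table <- read_asv_table(config$input$counts)
    meta <- read_metadata(config$input$metadata)
    tree <- if (!is.null(config$input$tree)) read_tree(config$input$tree) else NULL
    note("ingest")
  }

  # stage 2: abundance/prevalence filter
  f1 <- filter_low_abundance_prevalence(table, meta, config$thresholds)
  # stage 3: kitome detection and removal
  kit <- detect_kitome(f1$table, meta, config$thresholds)
  f2 <- remove_asvs(f1$table, kit$kitome, rule_id = "kitome")
  # stage 4: minimum reads
  f3 <- filter_samples_min_reads(f2$table, config$thresholds)
  log <- bind_removal_logs(f1$log, f2$log, f3$log)
  files <- c(emit("removal_log.tsv", function(p)
               utils::write.table(as.data.frame(log), p, sep = "\t",
                                  quote = FALSE, row.names = FALSE)),
             emit("kitome_evidence.tsv", function(p)
               utils::write.table(kit$evidence, p, sep = "\t",
                                  quote = FALSE, row.names = FALSE)),
             emit("filtered_counts.tsv", function(p) write_asv_table(f3$table, p)))
  note("filter", files = files)
  filtered <- f3$table
  if (nrow(filtered) == 0) stop("no samples remain after the read filter")
  meta_f <- align_metadata(filtered, meta)

  # stage 5: rarefaction
  rare_seed <- stage_seed(config$seed, "rarefy")
  rare <- rarefy(filtered, depth = config$rarefy_depth, seed = rare_seed)
  files <- emit("rarefied_counts.tsv", function(p) write_asv_table(rare, p))
  note("rarefy", rare_seed, files)
  meta_r <- align_metadata(rare, meta)
  body_r <- !meta_r$is_control

  # stage 6: alpha diversity + per-time ANOVA/Tukey across sites
  alpha <- alpha_diversity(rare)
  alpha <- cbind(alpha, meta_r[match(alpha$sample_id, meta_r$sample_id),
                               c("site", "time", "animal_id"), drop = FALSE])
  rownames(alpha) <- NULL
  alpha_tests <- list()
  for (tp in unique(stats::na.omit(alpha$time))) {
    sub <- alpha[!is.na(alpha$time) & alpha$time == tp, ]
    if (length(unique(sub$site)) < 2 || any(table(sub$site) < 2)) next
    alpha_tests[[tp]] <- list(
      richness = anova_tukey(sub$richness, sub$site),
      shannon = anova_tukey(sub$shannon, sub$site))
  }
  files <- emit("alpha_diversity.tsv", function(p)
    utils::write.table(alpha, p, sep = "\t", quote = FALSE, row.names = FALSE))
  note("alpha", files = files)

  # stage 7: beta diversity, ordination, PERMANOVA, dispersion, clustering
  body_table <- subset_asv_table(rare, samples = rownames(rare)[body_r])
  meta_b <- align_metadata(body_table, meta)
  dists <- list(); ords <- list(); perms <- list(); disps <- list()
  files <- character()
  for (metric in config$metrics) {
    dm <- beta_diversity(body_table, metric, tree = tree)
    dists[[metric]] <- dm
    ords[[metric]] <- pcoa(dm)
    pterms <- intersect(config$permanova_terms, names(meta_b))
    pterms <- pterms[vapply(pterms, function(tm) {
      v <- meta_b[[tm]]
      if (is.numeric(v)) !anyNA(v) else length(unique(stats::na.omit(v))) > 1
    }, logical(1))]
    perms[[metric]] <- permanova(dm, meta_b, pterms,
                                 n_perm = config$n_perm,
                                 seed = stage_seed(config$seed, paste0("permanova_", metric)))
    disps[[metric]] <- betadisper_test(dm, stats::setNames(meta_b$site, meta_b$sample_id),
                                       n_perm = config$n_perm,
                                       seed = stage_seed(config$seed, paste0("betadisper_", metric)))
    files <- c(files,
               emit(paste0("dist_", metric, ".tsv"), function(p) write_dist(dm, p)),
               emit(paste0("permanova_", metric, ".tsv"), function(p)
                 utils::write.table(as.data.frame(perms[[metric]]), p, sep = "\t",
                                    quote = FALSE, row.names = FALSE)))
  }
  note("beta", files = files)
  stability <- cluster_stability(rare, meta_r, k = config$k_clusters,
                                 times = if (inherits(config$input, "synthetic_config"))
                                   config$input$timepoints else NULL)
  files <- emit("cluster_stability.tsv", function(p)
    utils::write.table(stability, p, sep = "\t", quote = FALSE, row.names = FALSE))
  note("cluster", files = files)

  # stage 8: core microbiota and sharing on the unrarefied filtered table
  body_f <- subset_asv_table(filtered, samples = rownames(filtered)[!meta_f$is_control])
  meta_bf <- align_metadata(body_f, meta)
  times <- unique(meta_bf$time)
  sites <- setdiff(unique(meta_bf$site), "control")
  cores <- list(); sharing <- list(); multiway <- list()
  for (tp in times) {
    for (site in sites) {
      n_an <- length(unique(meta_bf$animal_id[meta_bf$site == site & meta_bf$time == tp]))
      if (n_an < 2) next
      cores[[paste(site, tp, sep = "_")]] <-
        core_microbiota(body_f, meta_bf, site, tp,
                        abn_core = config$core_abn, prev_core = config$core_prev)
    }
    sharing[[tp]] <- pairwise_sharing(body_f, meta_bf, tp)
    multiway[[tp]] <- multiway_sharing(body_f, meta_bf, tp)
  }
  overlap <- if (length(cores) >= 2) herd_core_overlap(cores) else NULL
  files <- character()
  if (length(sharing)) {
    all_pairs <- do.call(rbind, lapply(sharing, `[[`, "pairwise"))
    files <- emit("sharing_pairwise.tsv", function(p)
      utils::write.table(all_pairs, p, sep = "\t", quote = FALSE, row.names = FALSE))
  }
  note("core_sharing", files = files)

  manifest <- do.call(rbind, manifest)
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         dataframe = "rows", auto_unbox = TRUE)
  }
  structure(list(table = table, metadata = meta, tree = tree,
                 filtered = filtered, rarefied = rare, kitome = kit,
                 removal_log = log, alpha = alpha, alpha_tests = alpha_tests,
                 distances = dists, ordinations = ords, permanova = perms,
                 dispersion = disps, stability = stability,
                 cores = cores, sharing = sharing, multiway = multiway,
                 core_overlap = overlap, truth = truth,
                 manifest = manifest, config = config),
            class = "pipeline_run")
}

#' Compare a synthetic run against its ground truth
#'
#' Reports how well the pipeline recovered the planted structure: kitome
#' sensitivity/specificity, planted-core precision/recall, measured minus
#' expected cross-site shared fraction, and the PERMANOVA site term.
#'
#' @param run a `pipeline_run` from synthetic input.
#' @param truth the matching `herd_truth` (default: the run's own).
#' @return list of class `truth_report`.
#' @export
validate_against_truth <- function(run, truth = run$truth) {
  if (is.null(truth)) stop("run has no ground truth (not synthetic input)")
  if (!inherits(truth, "herd_truth")) stop("not a herd_truth object")

  flagged <- run$kitome$kitome
  candidates <- run$kitome$evidence$asv_id
  planted <- intersect(truth$kitome_asvs, candidates)
  nonplanted <- setdiff(candidates, truth$kitome_asvs)
  kit_sens <- if (length(planted)) mean(planted %in% flagged) else NA_real_
  kit_spec <- if (length(nonplanted)) mean(!nonplanted %in% flagged) else NA_real_

  core_stats <- list()
  for (key in names(run$cores)) {
    cs <- run$cores[[key]]
    planted_core <- truth$core_asvs[[cs$site]]
    recovered <- cs$core_asvs
    core_stats[[key]] <- data.frame(
      site = cs$site, time = cs$time,
      precision = if (length(recovered)) mean(recovered %in% planted_core) else NA_real_,
      recall = if (length(planted_core)) mean(planted_core %in% recovered) else NA_real_,
      stringsAsFactors = FALSE)
  }
  core_stats <- if (length(core_stats)) do.call(rbind, core_stats) else NULL

  sharing_bias <- NULL
  sites <- truth$config$sites
  if (length(sites) >= 2 && length(run$sharing)) {
    pair <- sites[1:2]
    expected <- truth_sharing_fraction(truth, pair)
    measured <- do.call(rbind, lapply(run$sharing, `[[`, "pairwise"))
    measured <- measured[(measured$site1 == pair[1] & measured$site2 == pair[2]) |
                           (measured$site1 == pair[2] & measured$site2 == pair[1]), ]
    if (nrow(measured)) {
      mf <- ifelse(measured$site1 == pair[1],
                   measured$fraction_in_site1, measured$fraction_in_site2)
      sharing_bias <- list(pair = pair,
                           measured_mean = mean(mf),
                           expected_mean = mean(expected$fraction_in_site1),
                           bias = mean(mf) - mean(expected$fraction_in_site1))
    }
  }

  site_perm <- lapply(run$permanova, function(pr) {
    row <- pr[pr$term == "site", , drop = FALSE]
    if (nrow(row)) c(R2 = row$R2, p = row$p) else c(R2 = NA, p = NA)
  })

  structure(list(kitome_sensitivity = kit_sens, kitome_specificity = kit_spec,
                 core_recovery = core_stats, sharing_bias = sharing_bias,
                 permanova_site = site_perm),
            class = "truth_report")
}
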