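# Small deterministic fixtures built in code.

make_table <- function(counts, samples = NULL, asvs = NULL) {
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(nrow(counts)))
  if (is.null(asvs)) asvs <- sprintf("a%02d", seq_len(ncol(counts)))
  asv_table(matrix(as.integer(counts), nrow(counts), ncol(counts),
                   dimnames = list(samples, asvs)))
}

random_table <- function(n_samples, n_asvs, seed, lambda = 20) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_samples * n_asvs, lambda), n_samples, n_asvs)
    # guarantee positive totals
    m[, 1] <- m[, 1] + 1L
    make_table(m)
  })
}

random_tree <- function(n_leaves, seed, labels = sprintf("a%02d", seq_len(n_leaves))) {
  withr::with_seed(seed, ape::rtree(n_leaves, tip.label = labels,
                                    br = function(n) runif(n, 0.1, 2)))
}

star_tree <- function(labels) {
  txt <- paste0("(", paste0(labels, ":1", collapse = ","), "):0;")
  ape::read.tree(text = txt)
}

simple_meta <- function(samples, animal, site, time, group = "G1",
                        is_control = FALSE, quarter = NA) {
  sample_metadata(data.frame(
    sample_id = samples, animal_id = animal, site = site, time = time,
    group = ifelse(is_control, NA, group), sm_score = NA_real_,
    bc_score = NA_real_, quarter = quarter, is_control = is_control,
    stringsAsFactors = FALSE))
}

tiny_config <- function(...) {
  defaults <- list(n_animals = 6L, sites = c("oral", "nasal", "vaginal", "milk"),
                   timepoints = c("1M", "3M"), pool_size = 120L,
                   site_pool_size = 40L, f_core = 0.1, occupancy = 0.3,
                   f_share = 0.1, n_private = 5L, n_controls = 4L,
                   n_kitome = 15L, kit_load = 0.15, depth_mu = log(5000),
                   depth_sigma = 0.3, seed = 1L)
  args <- utils::modifyList(defaults, list(...))
  do.call(synthetic_config, args)
}
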