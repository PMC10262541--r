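# A hand-built 2-animal fixture with milk quarters.
quarter_fixture <- function() {
  ids <- c("A1_oral_1M", "A1_milk_1M_Q1", "A1_milk_1M_Q2", "A1_milk_1M_Q3",
           "A1_milk_1M_Q4", "A2_oral_1M")
  counts <- rbind(
    c(5, 0, 2, 0),    # A1 oral
    c(0, 0, 0, 0),    # A1 milk Q1
    c(0, 3, 0, 0),    # A1 milk Q2
    c(0, 0, 0, 0),    # A1 milk Q3
    c(1, 0, 0, 0),    # A1 milk Q4
    c(0, 0, 0, 7))    # A2 oral
  tab <- make_table(counts, samples = ids, asvs = c("x", "y", "z", "w"))
  meta <- simple_meta(ids, c("A1", "A1", "A1", "A1", "A1", "A2"),
                      c("oral", rep("milk", 4), "oral"), "1M",
                      quarter = c(NA, "Q1", "Q2", "Q3", "Q4", NA))
  list(tab = tab, meta = meta)
}

test_that("milk quarters are aggregated with union semantics", {
  fx <- quarter_fixture()
  milk <- animal_site_community(fx$tab, fx$meta, "A1", "milk", "1M")
  expect_setequal(names(milk), c("x", "y"))   # y present in one quarter only
  expect_equal(milk[["y"]], 3 / 4)
  expect_equal(milk[["x"]], 1 / 4)

  oral <- animal_site_community(fx$tab, fx$meta, "A1", "oral", "1M")
  expect_equal(oral, c(x = 5 / 7, z = 2 / 7))

  expect_null(animal_site_community(fx$tab, fx$meta, "A2", "milk", "1M"))
  # all-zero sample -> empty community
  zero <- make_table(rbind(c(0, 0)), samples = "A9_oral_1M")
  zmeta <- simple_meta("A9_oral_1M", "A9", "oral", "1M")
  expect_length(animal_site_community(zero, zmeta, "A9", "oral", "1M"), 0)
})

core_fixture <- function(abns) {
  # one sample per animal, asv "c1" at given relative abundances vs filler
  n <- length(abns)
  ids <- sprintf("A%d_oral_1M", seq_len(n))
  scale <- 1e5
  counts <- cbind(c1 = as.integer(round(abns * scale)),
                  filler = as.integer(round((1 - abns) * scale)))
  tab <- asv_table(counts, sample_ids = ids, asv_ids = c("c1", "filler"))
  meta <- simple_meta(ids, sprintf("A%d", seq_len(n)), "oral", "1M")
  list(tab = tab, meta = meta)
}

test_that("core membership follows the prevalence and abundance thresholds", {
  # 2e-4 in 2 of 4 animals: prevalence 0.5 >= 0.5 and 2e-4 > 1e-4 -> core
  fx <- core_fixture(c(2e-4, 2e-4, 0, 0))
  cs <- core_microbiota(fx$tab, fx$meta, "oral", "1M")
  expect_true("c1" %in% cs$core_asvs)
  expect_equal(cs$evidence$prevalence[cs$evidence$asv_id == "c1"], 0.5)

  # strict mode: 0.5 is no longer enough
  cs_strict <- core_microbiota(fx$tab, fx$meta, "oral", "1M",
                               strict_prevalence = TRUE)
  expect_false("c1" %in% cs_strict$core_asvs)

  # abundant enough nowhere: 5e-5 in all animals -> not core
  fx2 <- core_fixture(rep(5e-5, 4))
  cs2 <- core_microbiota(fx2$tab, fx2$meta, "oral", "1M")
  expect_false("c1" %in% cs2$core_asvs)
  # the abundance inequality is strict: exactly 1e-4 does not count
  fx3 <- core_fixture(rep(1e-4, 4))
  cs3 <- core_microbiota(fx3$tab, fx3$meta, "oral", "1M")
  expect_false("c1" %in% cs3$core_asvs)
})

sharing_fixture <- function() {
  ids <- c("A1_oral_1M", "A1_nasal_1M")
  counts <- rbind(c(4, 3, 2, 1, 0), c(0, 0, 5, 3, 2))
  tab <- make_table(counts, samples = ids, asvs = c("a", "b", "c", "d", "e"))
  meta <- simple_meta(ids, "A1", c("oral", "nasal"), "1M")
  list(tab = tab, meta = meta)
}

test_that("pairwise sharing does the printed set arithmetic", {
  fx <- sharing_fixture()
  rep <- pairwise_sharing(fx$tab, fx$meta, "1M")
  row <- rep$pairwise[1, ]
  expect_equal(row$n_shared, 2)                 # {c, d}
  site_o <- if (row$site1 == "oral") "1" else "2"
  expect_equal(row[[paste0("fraction_in_site", site_o)]], 0.5)      # 2/4
  expect_equal(row[[paste0("fraction_in_site", ifelse(site_o == "1", "2", "1"))]], 2 / 3)
  expect_equal(row[[paste0("relabund_in_site", site_o)]], 0.3)      # (2+1)/10
  expect_equal(row[[paste0("relabund_in_site", ifelse(site_o == "1", "2", "1"))]], 0.8)
  expect_equal(rep$n_two_way_occurrences, 2)
})

test_that("disjoint and identical communities are the boundary cases", {
  ids <- c("A1_oral_1M", "A1_nasal_1M")
  meta <- simple_meta(ids, "A1", c("oral", "nasal"), "1M")
  disj <- make_table(rbind(c(3, 0), c(0, 3)), samples = ids)
  r1 <- pairwise_sharing(disj, meta, "1M")$pairwise
  expect_equal(r1$n_shared, 0)
  expect_equal(r1$fraction_in_site1 + r1$relabund_in_site2, 0)

  same <- make_table(rbind(c(3, 4), c(6, 8)), samples = ids)
  r2 <- pairwise_sharing(same, meta, "1M")$pairwise
  expect_equal(r2$fraction_in_site1, 1)
  expect_equal(r2$fraction_in_site2, 1)
  expect_equal(r2$relabund_in_site1, 1)
})

test_that("missing communities are skipped and logged", {
  fx <- quarter_fixture()
  rep <- pairwise_sharing(fx$tab, fx$meta, "1M")
  expect_true(any(rep$skipped$animal == "A2" & rep$skipped$site2 == "oral" |
                    rep$skipped$animal == "A2"))
  # A1 contributes the milk-oral pair
  expect_equal(nrow(rep$pairwise), 1)
})

test_that("an ASV in all four sites yields four 3-way and one 4-way occurrence", {
  sites <- c("oral", "nasal", "vaginal", "milk")
  ids <- paste0("A1_", sites, "_1M")
  counts <- rbind(c(1, 1), c(1, 0), c(1, 0), c(1, 0))
  tab <- make_table(counts, samples = ids, asvs = c("u", "v"))
  meta <- simple_meta(ids, "A1", sites, "1M")
  mw <- multiway_sharing(tab, meta, "1M")
  expect_equal(unname(mw$tallies["three_way"]), 4)   # C(4,3) combos for "u"
  expect_equal(unname(mw$tallies["four_way"]), 1)
  # "v" is in one site only: no contribution
  expect_false("v" %in% mw$records$asv_id)
  # every 4-way ASV appears in all four 3-way records
  four <- mw$records[mw$records$size == 4, ]
  for (asv in four$asv_id) {
    expect_equal(sum(mw$records$size == 3 & mw$records$asv_id == asv), 4)
  }
})

test_that("multiway tallies equal the exhaustive tuple enumeration oracle", {
  herd <- generate_herd(tiny_config(seed = 61, n_animals = 5L,
                                    timepoints = "1M", n_controls = 0,
                                    n_kitome = 0, kit_load = 0,
                                    pool_size = 60L, site_pool_size = 20L,
                                    n_private = 2L))
  mw <- multiway_sharing(herd$table, herd$metadata, "1M")
  expect_equal(mw$tallies,
               oracle_multiway_tallies(herd$table, herd$metadata, "1M"))
})

test_that("sharing fractions match an independent set oracle on a herd", {
  herd <- generate_herd(tiny_config(seed = 71, n_animals = 5L,
                                    timepoints = "1M", n_controls = 0,
                                    n_kitome = 0, kit_load = 0))
  rep <- pairwise_sharing(herd$table, herd$metadata, "1M")
  m <- unclass(herd$table)
  meta <- herd$metadata
  rows <- withr::with_seed(1, sample(nrow(rep$pairwise), 10))
  for (r in rows) {
    row <- rep$pairwise[r, ]
    ids1 <- meta$sample_id[!meta$is_control & meta$animal_id == row$animal &
                             meta$site == row$site1 & meta$time == "1M"]
    ids2 <- meta$sample_id[!meta$is_control & meta$animal_id == row$animal &
                             meta$site == row$site2 & meta$time == "1M"]
    s1 <- colnames(m)[colSums(m[ids1, , drop = FALSE]) > 0]
    s2 <- colnames(m)[colSums(m[ids2, , drop = FALSE]) > 0]
    expect_equal(row$n_shared, length(intersect(s1, s2)))
    expect_equal(row$fraction_in_site1, length(intersect(s1, s2)) / length(s1))
  }
})

test_that("core overlap and persistence behave on planted structure", {
  fx1 <- core_fixture(rep(2e-4, 4))
  csA <- core_microbiota(fx1$tab, fx1$meta, "oral", "1M")
  csB <- csA; csB$site <- "nasal"
  ov <- herd_core_overlap(list(csA, csB))
  expect_equal(ov$site_overlap$n_asvs[ov$site_overlap$n_sites == 2],
               length(csA$core_asvs))

  csC <- csA; csC$time <- "3M"; csC$core_asvs <- character(0)
  ov2 <- herd_core_overlap(list(csA, csC))
  expect_equal(ov2$persistence$fraction, 0)

  csD <- csA; csD$time <- "3M"
  ov3 <- herd_core_overlap(list(csA, csD))
  expect_equal(ov3$persistence$fraction, 1)
})
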