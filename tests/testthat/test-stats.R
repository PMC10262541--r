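two_group_meta <- function(n1, n2, ids = NULL) {
  n <- n1 + n2
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(n))
  data.frame(sample_id = ids, grp = rep(c("a", "b"), c(n1, n2)),
             stringsAsFactors = FALSE)
}

test_that("permanova recovers the classical F on euclidean distances", {
  withr::with_seed(4, {
    pts <- rbind(matrix(rnorm(10 * 3), 10, 3),
                 matrix(rnorm(8 * 3, mean = 1.5), 8, 3))
  })
  rownames(pts) <- sprintf("s%02d", 1:18)
  d <- dist(pts)
  meta <- two_group_meta(10, 8)
  res <- permanova(d, meta, "grp", n_perm = 99, seed = 1)

  grp <- meta$grp
  ss_between <- sum(vapply(1:3, function(j) {
    summary(aov(pts[, j] ~ grp))[[1]]["grp", "Sum Sq"]
  }, numeric(1)))
  ss_within <- sum(vapply(1:3, function(j) {
    summary(aov(pts[, j] ~ grp))[[1]]["Residuals", "Sum Sq"]
  }, numeric(1)))
  expect_equal(res$SumOfSqs[1], ss_between, tolerance = 1e-9)
  expect_equal(res$SumOfSqs[2], ss_within, tolerance = 1e-9)
  f_classic <- (ss_between / 1) / (ss_within / 16)
  expect_equal(res$F[1], f_classic, tolerance = 1e-9)
  expect_equal(res$SumOfSqs[3], ss_between + ss_within, tolerance = 1e-9)
  expect_equal(sum(res$R2[1:2]), 1, tolerance = 1e-9)
})

test_that("permanova matches adonis2 on a multi-term model", {
  skip_if_not_installed("vegan")
  withr::with_seed(11, {
    tab <- random_table(24, 40, seed = 12)
    meta <- data.frame(sample_id = rownames(tab),
                       site = rep(c("oral", "nasal", "milk"), 8),
                       cov = rnorm(24), stringsAsFactors = FALSE)
  })
  dm <- bray_curtis(tab)
  res <- permanova(dm, meta, c("site", "cov"), n_perm = 199, seed = 3)
  ref <- vegan::adonis2(dm ~ site + cov, data = meta, permutations = 199,
                        by = "terms")
  expect_equal(res$SumOfSqs[1:3], ref$SumOfSqs[1:3], tolerance = 1e-9)
  expect_equal(res$F[1:2], ref$F[1:2], tolerance = 1e-9)
  expect_equal(res$R2[1:3], ref$R2[1:3], tolerance = 1e-9)

  resm <- permanova(dm, meta, c("site", "cov"), n_perm = 199, seed = 3,
                    by = "margin")
  refm <- vegan::adonis2(dm ~ site + cov, data = meta, permutations = 199,
                         by = "margin")
  expect_equal(resm$SumOfSqs[1:2], refm$SumOfSqs[1:2], tolerance = 1e-9)
})

test_that("exhaustive permanova p on the separated 6-point fixture is 0.1", {
  d <- matrix(10, 6, 6)
  d[1:3, 1:3] <- 1; d[4:6, 4:6] <- 1
  diag(d) <- 0
  rownames(d) <- colnames(d) <- sprintf("s%02d", 1:6)
  meta <- two_group_meta(3, 3)
  res <- permanova(as.dist(d), meta, "grp", exact = TRUE)
  expect_equal(res$p[1], 0.1)
  # independent label-enumeration oracle
  expect_equal(oracle_permanova_exact_p(as.dist(d), meta$grp), 0.1)
  expect_equal(res$F[1], oracle_permanova_f(d, meta$grp), tolerance = 1e-9)
})

test_that("degenerate single-level terms get zero df and no test", {
  d <- dist(matrix(rnorm(12), 6, 2))
  attr(d, "Labels") <- sprintf("s%02d", 1:6)
  meta <- data.frame(sample_id = sprintf("s%02d", 1:6), one = "x")
  res <- permanova(d, meta, "one", n_perm = 99)
  expect_equal(res$Df[1], 0)
  expect_true(is.na(res$F[1]))
})

test_that("permutation p-values are reproducible given the seed", {
  tab <- random_table(16, 20, seed = 41)
  meta <- two_group_meta(8, 8, ids = rownames(tab))
  dm <- bray_curtis(tab)
  p1 <- permanova(dm, meta, "grp", n_perm = 199, seed = 7)$p[1]
  p2 <- permanova(dm, meta, "grp", n_perm = 199, seed = 7)$p[1]
  p3 <- permanova(dm, meta, "grp", n_perm = 199, seed = 8)$p[1]
  expect_identical(p1, p2)
  expect_true(p1 >= 1 / 200 && p1 <= 1)
  expect_true(p3 >= 1 / 200 && p3 <= 1)
  d1 <- betadisper_test(dm, setNames(meta$grp, meta$sample_id),
                        n_perm = 199, seed = 5)
  d2 <- betadisper_test(dm, setNames(meta$grp, meta$sample_id),
                        n_perm = 199, seed = 5)
  expect_identical(d1$p, d2$p)
})

test_that("dispersion distances match the euclidean oracle", {
  withr::with_seed(6, {
    pts <- rbind(matrix(rnorm(12, sd = 0.5), 6, 2),
                 matrix(rnorm(12, sd = 2), 6, 2))
  })
  rownames(pts) <- sprintf("s%02d", 1:12)
  grp <- rep(c("tight", "wide"), each = 6)
  res <- betadisper_test(dist(pts), setNames(grp, rownames(pts)),
                         n_perm = 199, seed = 2)
  for (g in c("tight", "wide")) {
    centroid <- colMeans(pts[grp == g, ])
    d_direct <- sqrt(rowSums(sweep(pts[grp == g, ], 2, centroid)^2))
    expect_equal(unname(res$distances[grp == g]), unname(d_direct),
                 tolerance = 1e-9)
  }
})

test_that("dispersion distances match vegan::betadisper on bray distances", {
  skip_if_not_installed("vegan")
  tab <- random_table(14, 25, seed = 43)
  grp <- rep(c("a", "b"), 7)
  dm <- bray_curtis(tab)
  res <- betadisper_test(dm, setNames(grp, rownames(tab)), n_perm = 99)
  ref <- vegan::betadisper(dm, grp, type = "centroid")
  expect_equal(unname(res$distances), unname(ref$distances), tolerance = 1e-8)
})

test_that("a duplicated-point group has zero dispersion", {
  pts <- rbind(matrix(1, 4, 2), matrix(rnorm(8, sd = 2), 4, 2))
  rownames(pts) <- sprintf("s%02d", 1:8)
  grp <- rep(c("zero", "wide"), each = 4)
  res <- betadisper_test(dist(pts), setNames(grp, rownames(pts)), n_perm = 99)
  expect_true(all(res$distances[grp == "zero"] < 1e-12))
  expect_true(all(res$distances[grp == "wide"] > 0))
})

test_that("groups of size one are excluded with a warning", {
  pts <- matrix(rnorm(14), 7, 2)
  rownames(pts) <- sprintf("s%02d", 1:7)
  grp <- c("a", "a", "a", "b", "b", "b", "lonely")
  expect_warning(res <- betadisper_test(dist(pts), setNames(grp, rownames(pts)),
                                        n_perm = 99), "lonely")
  expect_equal(length(res$distances), 6)
})

test_that("anova_tukey reproduces classical identities", {
  res0 <- anova_tukey(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(res0$F, 0)
  expect_equal(res0$p, 1)

  # two groups: Tukey adjusted p equals the pooled-variance t-test p
  withr::with_seed(9, { x <- rnorm(9); y <- rnorm(7, mean = 1) })
  res <- anova_tukey(c(x, y), rep(c("a", "b"), c(9, 7)))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(res$pairwise$p_adj, tt$p.value, tolerance = 1e-9)
  expect_error(anova_tukey(1:4, c("a", "a", "a", "a")), "2 groups")
})

test_that("ward clustering separates blobs and matches the merge oracle", {
  withr::with_seed(14, {
    pts <- rbind(matrix(rnorm(10, sd = 0.2), 5, 2),
                 matrix(rnorm(10, mean = 5, sd = 0.2), 5, 2))
  })
  rownames(pts) <- sprintf("s%02d", 1:10)
  labels <- ward_clusters(dist(pts), k = 2)
  expect_equal(partition_label(labels),
               partition_label(rep(1:2, each = 5)))
  expect_equal(length(unique(ward_clusters(dist(pts), k = 10))), 10)
  expect_error(ward_clusters(dist(pts), k = 11), "exceeds")

  withr::with_seed(15, pts8 <- matrix(rnorm(16), 8, 2))
  rownames(pts8) <- sprintf("p%d", 1:8)
  oracle <- oracle_ward_merges(pts8)
  for (k in c(6, 4, 2)) {
    ours <- ward_clusters(dist(pts8), k = k)
    oracle_k <- oracle[[8 - k]]
    expect_equal(partition_label(ours[order(names(ours))]),
                 partition_label(oracle_k[order(rownames(pts8))]),
                 info = paste("k =", k))
  }
})

test_that("adjusted rand index follows the hubert-arabie formula", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y")), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  # symmetry
  withr::with_seed(19, {
    l1 <- sample(1:3, 30, replace = TRUE)
    l2 <- sample(1:4, 30, replace = TRUE)
  })
  expect_equal(adjusted_rand_index(l1, l2), adjusted_rand_index(l2, l1))
  expect_error(adjusted_rand_index(setNames(1:3, c("a", "b", "c")),
                                   setNames(1:3, c("a", "b", "z"))),
               "different sample sets")
  skip_if_not_installed("mclust")
  expect_equal(adjusted_rand_index(l1, l2), mclust::adjustedRandIndex(l1, l2),
               tolerance = 1e-12)
})

test_that("cluster stability is 1 for identical tables across times", {
  withr::with_seed(22, m <- matrix(rpois(8 * 12, 30), 8, 12))
  animals <- sprintf("A%d", 1:8)
  ids <- c(paste0(animals, "_oral_1M"), paste0(animals, "_oral_3M"))
  tab <- make_table(rbind(m, m), samples = ids)
  meta <- simple_meta(ids, rep(animals, 2), "oral",
                      rep(c("1M", "3M"), each = 8))
  st <- cluster_stability(tab, meta, k = 3)
  expect_equal(st$ari, 1)
  expect_equal(st$n_animals, 8)
})

test_that("stability is higher without turnover than with heavy turnover", {
  aris <- sapply(c(0, 0.5), function(tau) {
    vals <- sapply(1:5, function(s) {
      herd <- generate_herd(tiny_config(seed = 300 + s, time_turnover = tau,
                                        n_animals = 8L, n_controls = 0,
                                        n_kitome = 0, kit_load = 0,
                                        sites = c("oral", "nasal"),
                                        jitter_sigma = 0.2))
      st <- cluster_stability(herd$table, herd$metadata, k = 3,
                              times = c("1M", "3M"))
      mean(st$ari)
    })
    mean(vals)
  })
  expect_gt(aris[1], aris[2])
})
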