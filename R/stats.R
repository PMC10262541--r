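#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the variation of a dissimilarity matrix among an ordered list
#' of model terms. The Gower-centered inner-product matrix
#' G = -1/2 C D^2 C is computed once; the sequential sum of squares of term
#' k is tr(H_k G) - tr(H_{k-1} G), where H_k is the hat matrix of the
#' design including terms 1..k (factors dummy-coded, numeric covariates
#' centered). The pseudo-F of each term is (SS_k/df_k)/(SS_res/df_res) and
#' its p-value is obtained by permuting samples (rows and columns of D
#' jointly): p = (1 + #{F* >= F}) / (1 + n_perm). `by = "margin"` tests each
#' term against the model with all other terms instead of sequentially.
#'
#' @param dm `dist` object or symmetric distance matrix.
#' @param meta data.frame with one row per sample (matched to the distance
#'   labels through a `sample_id` column or row names).
#' @param terms character vector of metadata column names, in model order.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed for the permutation stream.
#' @param by `"terms"` (sequential, type-I) or `"margin"`.
#' @param exact if `TRUE`, enumerate all n! sample permutations (n <= 8
#'   only) instead of sampling; the p-value is then the exact fraction of
#'   permutations with F* >= F (the identity permutation included).
#' @return data.frame of class `permanova_result` with one row per term
#'   plus `Residual` and `Total`: Df, SumOfSqs, R2, F, p. Rank-deficient
#'   terms get 0 df and no test.
#' @export
permanova <- function(dm, meta, terms, n_perm = 9999L, seed = 1L,
                      by = c("terms", "margin"), exact = FALSE) {
  by <- match.arg(by)
  if (!exact && n_perm < 99) stop("n_perm must be >= 99")
  d <- as.matrix(dm)
  ids <- rownames(d)
  meta <- as.data.frame(meta)
  if (!is.null(meta$sample_id)) rownames(meta) <- meta$sample_id
  if (!all(ids %in% rownames(meta))) stop("samples missing from metadata")
  meta <- meta[ids, , drop = FALSE]
  miss <- setdiff(terms, names(meta))
  if (length(miss)) stop("unknown term(s): ", paste(miss, collapse = ", "))

  n <- nrow(d)
  g <- -0.5 * d^2
  g <- sweep(g, 1, rowMeans(g))
  g <- sweep(g, 2, colMeans(g))
  ss_total <- sum(diag(g))

  # nested hat matrices
  term_cols <- lapply(terms, function(tm) {
    v <- meta[[tm]]
    if (is.numeric(v)) {
      if (anyNA(v)) stop("missing values in covariate ", tm)
      matrix(v - mean(v), ncol = 1)
    } else {
      f <- factor(v)
      if (nlevels(f) < 2) matrix(numeric(n), ncol = 1)[, 0, drop = FALSE]
      else stats::model.matrix(~f)[, -1, drop = FALSE]
    }
  })
  hat <- function(X) {
    q <- qr(X)
    if (q$rank == 0) return(matrix(0, n, n))
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    tcrossprod(Q)
  }
  X0 <- matrix(1, n, 1)
  nt <- length(terms)
  H_list <- vector("list", nt)        # hat matrix difference per term
  df <- integer(nt)
  if (by == "terms") {
    H_prev <- hat(X0)
    X <- X0
    rank_prev <- 1L
    for (k in seq_len(nt)) {
      X <- cbind(X, term_cols[[k]])
      q <- qr(X)
      H_k <- hat(X)
      df[k] <- q$rank - rank_prev
      H_list[[k]] <- H_k - H_prev
      H_prev <- H_k
      rank_prev <- q$rank
    }
    H_full <- H_prev
    rank_full <- rank_prev
  } else {
    X_full <- do.call(cbind, c(list(X0), term_cols))
    H_full <- hat(X_full)
    rank_full <- qr(X_full)$rank
    for (k in seq_len(nt)) {
      X_red <- do.call(cbind, c(list(X0), term_cols[-k]))
      H_red <- hat(X_red)
      df[k] <- rank_full - qr(X_red)$rank
      H_list[[k]] <- H_full - H_red
    }
  }
  df_res <- n - rank_full

  trHG <- function(H, G) sum(H * G)
  ss <- vapply(H_list, trHG, numeric(1), G = g)
  ss_res <- ss_total - trHG(H_full, g)
  f_obs <- ifelse(df > 0, (ss / df) / (ss_res / df_res), NA_real_)

  perm_f <- function(idx) {
    gp <- g[idx, idx]
    ss_p <- vapply(H_list, trHG, numeric(1), G = gp)
    ss_res_p <- ss_total - trHG(H_full, gp)
    ifelse(df > 0, (ss_p / df) / (ss_res_p / df_res), NA_real_)
  }
  exceed <- integer(nt)
  if (exact) {
    if (n > 8) stop("exact enumeration limited to n <= 8 samples")
    perms <- all_permutations(n)
    for (p in seq_len(nrow(perms))) {
      f_p <- perm_f(perms[p, ])
      exceed <- exceed + as.integer(!is.na(f_p) & !is.na(f_obs) & f_p >= f_obs - 1e-12)
    }
    n_perm <- nrow(perms)
    pval <- ifelse(df > 0, exceed / n_perm, NA_real_)
  } else {
    withr::with_seed(seed, {
      for (p in seq_len(n_perm)) {
        f_p <- perm_f(sample.int(n))
        exceed <- exceed + as.integer(!is.na(f_p) & !is.na(f_obs) & f_p >= f_obs)
      }
    })
    pval <- ifelse(df > 0, (1 + exceed) / (1 + n_perm), NA_real_)
  }

  out <- data.frame(
    term = c(terms, "Residual", "Total"),
    Df = c(df, df_res, n - 1L),
    SumOfSqs = c(ss, ss_res, ss_total),
    R2 = c(ss, ss_res, ss_total) / ss_total,
    F = c(f_obs, NA, NA),
    p = c(pval, NA, NA),
    stringsAsFactors = FALSE)
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "by") <- by
  class(out) <- c("permanova_result", "data.frame")
  out
}

# All permutations of 1..n as an n! x n matrix (n small).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(sub >= k, sub + 1L, sub))
  }))
}

#' Multivariate homogeneity of group dispersions
#'
#' Embeds the samples by principal coordinates keeping the positive and
#' negative eigen-axes separately; the squared distance of a sample to its
#' group centroid is the sum of squared coordinate differences on the
#' positive axes minus that on the negative axes, floored at zero. The
#' observed F comes from a one-way ANOVA on these distances; the p-value
#' from permuting group labels over the distances; pairwise comparisons use
#' Tukey's HSD on the same distances. Groups of size one are excluded with
#' a warning.
#'
#' @param dm `dist` object or symmetric distance matrix.
#' @param grouping factor (or vector) of group labels, aligned to the
#'   distance labels (named vectors are matched by name).
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @return list of class `dispersion_result`: `distances` (named, to own
#'   group centroid), `F`, `p`, `anova_p` (parametric), `tukey` (pairwise
#'   adjusted p), `groups`.
#' @export
betadisper_test <- function(dm, grouping, n_perm = 999L, seed = 1L) {
  d <- as.matrix(dm)
  ids <- rownames(d)
  if (!is.null(names(grouping))) grouping <- grouping[ids]
  grouping <- factor(as.character(grouping))
  if (length(grouping) != nrow(d)) stop("grouping length mismatch")
  sizes <- table(grouping)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("group(s) of size 1 excluded: ", paste(small, collapse = ", "))
    keep <- !(grouping %in% small)
    d <- d[keep, keep, drop = FALSE]
    ids <- ids[keep]
    grouping <- droplevels(grouping[keep])
  }
  if (nlevels(grouping) < 2) stop("need >= 2 groups with >= 2 members")

  n <- nrow(d)
  g <- -0.5 * d^2
  g <- sweep(g, 1, rowMeans(g))
  g <- sweep(g, 2, colMeans(g))
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- e$values > tol
  neg <- e$values < -tol
  xp <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]), sum(pos))
  xn <- e$vectors[, neg, drop = FALSE] %*% diag(sqrt(-e$values[neg]), sum(neg))

  z <- numeric(n)
  for (lev in levels(grouping)) {
    i <- grouping == lev
    cp <- colMeans(xp[i, , drop = FALSE])
    cn <- colMeans(xn[i, , drop = FALSE])
    d2 <- rowSums(sweep(xp[i, , drop = FALSE], 2, cp)^2)
    if (ncol(xn)) d2 <- d2 - rowSums(sweep(xn[i, , drop = FALSE], 2, cn)^2)
    z[i] <- sqrt(pmax(d2, 0))
  }
  names(z) <- ids

  f_stat <- function(values, grp) {
    m <- tapply(values, grp, mean)
    nk <- tabulate(grp)
    ssb <- sum(nk * (m - mean(values))^2)
    ssw <- sum((values - m[as.integer(grp)])^2)
    k <- nlevels(grp)
    (ssb / (k - 1)) / (ssw / (length(values) - k))
  }
  f_obs <- f_stat(z, grouping)
  exceed <- 0L
  withr::with_seed(seed, {
    for (p in seq_len(n_perm)) {
      f_p <- f_stat(z, grouping[sample.int(n)])
      if (!is.na(f_p) && f_p >= f_obs) exceed <- exceed + 1L
    }
  })
  aovfit <- stats::aov(z ~ grouping)
  tk <- stats::TukeyHSD(aovfit)$grouping
  structure(list(distances = z, groups = grouping, F = f_obs,
                 p = (1 + exceed) / (1 + n_perm),
                 anova_p = summary(aovfit)[[1]][["Pr(>F)"]][1],
                 tukey = tk, n_perm = n_perm, seed = seed),
            class = "dispersion_result")
}

#' One-way ANOVA with Tukey's HSD
#'
#' Classical one-way analysis of variance followed by Tukey's honestly
#' significant difference post-hoc test (Tukey-Kramer for unbalanced
#' designs), as used to compare alpha diversity across sites.
#'
#' @param values numeric response, one value per sample.
#' @param grouping factor of group labels.
#' @return list: `F`, `p`, `pairwise` (data.frame of pairwise differences
#'   with Tukey-adjusted p), `zero_variance` flag.
#' @export
anova_tukey <- function(values, grouping) {
  grouping <- factor(as.character(grouping))
  if (nlevels(grouping) < 2) stop("need >= 2 groups")
  if (any(table(grouping) < 2)) stop("each group needs >= 2 values")
  fit <- stats::aov(values ~ grouping)
  tab <- summary(fit)[[1]]
  msw <- tab["Residuals", "Mean Sq"]
  zero_var <- msw <= .Machine$double.eps * stats::var(values)
  tk <- stats::TukeyHSD(fit)$grouping
  pairwise <- data.frame(comparison = rownames(tk), tk, row.names = NULL,
                         check.names = FALSE)
  names(pairwise) <- c("comparison", "diff", "lwr", "upr", "p_adj")
  list(F = tab["grouping", "F value"], p = tab["grouping", "Pr(>F)"],
       pairwise = pairwise, zero_variance = zero_var)
}

#' Ward clustering of a distance matrix
#'
#' Agglomerative hierarchical clustering with Ward linkage in the ward.D2
#' convention (Lance-Williams update on squared dissimilarities, heights in
#' the original units), cut to exactly `k` clusters.
#'
#' @param dm a `dist` object.
#' @param k number of clusters, 1 <= k <= n.
#' @return Integer cluster labels named by sample ID; the `hclust` tree is
#'   attached as attribute `tree`.
#' @export
ward_clusters <- function(dm, k) {
  n <- attr(stats::as.dist(dm), "Size")
  if (k > n) stop("k exceeds the number of samples")
  if (k < 1) stop("k must be >= 1")
  hc <- stats::hclust(stats::as.dist(dm), method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  attr(labels, "tree") <- hc
  labels
}

#' Adjusted Rand Index (Hubert-Arabie)
#'
#' Chance-corrected agreement between two partitions of the same samples:
#' 1 for identical clusterings, around 0 for independent random ones.
#' Named vectors are matched by name; otherwise positions must align.
#'
#' @param labels1,labels2 cluster label vectors.
#' @return The ARI, a real number <= 1.
#' @export
adjusted_rand_index <- function(labels1, labels2) {
  if (!is.null(names(labels1)) && !is.null(names(labels2))) {
    if (!setequal(names(labels1), names(labels2))) {
      stop("partitions cover different sample sets")
    }
    labels2 <- labels2[names(labels1)]
  }
  if (length(labels1) != length(labels2)) stop("partition size mismatch")
  tab <- table(labels1, labels2)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  expected <- a * b / choose(n, 2)
  max_index <- (a + b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}

#' Temporal stability of per-site animal clusterings
#'
#' For each site, animals are clustered at each time point by Ward linkage
#' on the Bray-Curtis distances between their (aggregated) communities, and
#' consecutive time points are compared with the Adjusted Rand Index,
#' restricted to animals present at both times.  Pairs with fewer than `k`
#' common animals are skipped with a warning.
#'
#' @param table an [asv_table()] (typically rarefied).
#' @param meta matching [sample_metadata()].
#' @param k number of clusters to cut.
#' @param times time levels in chronological order (defaults to the order
#'   of [TIME_LEVELS] restricted to those present).
#' @return data.frame: site, time1, time2, n_animals, ari.
#' @export
cluster_stability <- function(table, meta, k = 5L, times = NULL) {
  meta <- align_metadata(table, meta)
  body <- meta[!meta$is_control, , drop = FALSE]
  if (is.null(times)) times <- intersect(TIME_LEVELS, unique(body$time))
  sites <- setdiff(unique(body$site), "control")
  out <- list()
  for (site in sites) {
    labs <- list()
    for (tp in times) {
      comm <- build_communities(table, meta, time = tp, sites = site)
      mats <- lapply(comm, function(a) a[[site]])
      mats <- mats[!vapply(mats, is.null, logical(1))]
      if (length(mats) < 2) next
      all_asvs <- sort(unique(unlist(lapply(mats, names))))
      m <- t(vapply(mats, function(v) {
        x <- stats::setNames(numeric(length(all_asvs)), all_asvs)
        x[names(v)] <- v
        x
      }, numeric(length(all_asvs))))
      tab <- asv_table(round(m * 1e6))  # community proportions to pseudo-counts
      labs[[tp]] <- ward_clusters(bray_curtis(tab), k = min(k, nrow(m)))
    }
    tps <- intersect(times, names(labs))
    if (length(tps) < 2) next
    for (i in seq_len(length(tps) - 1)) {
      l1 <- labs[[tps[i]]]; l2 <- labs[[tps[i + 1]]]
      common <- intersect(names(l1), names(l2))
      if (length(common) < k) {
        warning(sprintf("site %s, %s->%s: only %d common animals (< k=%d); skipped",
                        site, tps[i], tps[i + 1], length(common), k))
        next
      }
      out[[length(out) + 1]] <- data.frame(
        site = site, time1 = tps[i], time2 = tps[i + 1],
        n_animals = length(common),
        ari = adjusted_rand_index(l1[common], l2[common]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(site = character(), time1 = character(),
                      time2 = character(), n_animals = integer(),
                      ari = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
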