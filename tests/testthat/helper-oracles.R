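# Independent brute-force oracles, deliberately written with different
# algorithms than the package implementations.

# Leaf sets under every edge, found by repeated expansion (no postorder).
oracle_edge_leafsets <- function(tree) {
  ntip <- length(tree$tip.label)
  below <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, below))
  }
  lapply(seq_len(nrow(tree$edge)), function(k) below(tree$edge[k, 2]))
}

# Exhaustive-branch-enumeration UniFrac for one sample pair.
oracle_unifrac_pair <- function(tree, x, y, weighted = FALSE, normalized = TRUE) {
  sets <- oracle_edge_leafsets(tree)
  b <- tree$edge.length
  if (!weighted) {
    num <- den <- 0
    for (k in seq_along(sets)) {
      inx <- any(x[sets[[k]]] > 0)
      iny <- any(y[sets[[k]]] > 0)
      if (xor(inx, iny)) num <- num + b[k]
      if (inx || iny) den <- den + b[k]
    }
    if (den == 0) return(0)
    return(num / den)
  }
  px <- x / sum(x); py <- y / sum(y)
  num <- den <- 0
  for (k in seq_along(sets)) {
    ax <- sum(px[sets[[k]]]); ay <- sum(py[sets[[k]]])
    num <- num + b[k] * abs(ax - ay)
    den <- den + b[k] * (ax + ay)
  }
  if (!normalized) return(num)
  if (den == 0) 0 else num / den
}

oracle_unifrac <- function(table, tree, weighted = FALSE, normalized = TRUE) {
  m <- unclass(table)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- oracle_unifrac_pair(
      tree, m[i, ], m[j, ], weighted = weighted, normalized = normalized)
  }
  as.dist(d)
}

oracle_jaccard_pair <- function(x, y) {
  a <- names(x)[x > 0]; b <- names(y)[y > 0]
  u <- union(a, b)
  if (!length(u)) return(0)
  1 - length(intersect(a, b)) / length(u)
}

# Per-ASV re-evaluation of the four abundance/prevalence clauses.
oracle_low_abn_prev <- function(table, meta, th) {
  meta <- meta[match(rownames(table), meta$sample_id), ]
  keep <- !meta$is_control
  m <- unclass(table)[keep, , drop = FALSE]
  site <- meta$site[keep]
  strata <- split(seq_len(nrow(m)), paste(site, meta$time[keep]))
  stot <- vapply(strata, function(i) sum(m[i, , drop = FALSE]), numeric(1))
  strata <- strata[stot > 0]
  stot <- stot[stot > 0]
  sites <- split(seq_len(nrow(m)), site)
  total <- sum(m)
  removed <- character()
  for (asv in colnames(m)) {
    v <- m[, asv]
    strat_ab <- vapply(seq_along(strata),
                       function(k) sum(v[strata[[k]]]) / stot[k], numeric(1))
    c1 <- length(strat_ab) > 0 && all(strat_ab < th$abn_stratum)
    c2 <- sum(v) / total < th$abn_overall
    c3 <- all(vapply(sites, function(i) mean(v[i] > 0), numeric(1)) < th$prev_site)
    c4 <- sum(v > 0) < th$prev_min_samples
    if (c1 || c2 || c3 || c4) removed <- c(removed, asv)
  }
  removed
}

# Per-ASV re-evaluation of the two kitome conditions.
oracle_kitome <- function(table, meta, th) {
  meta <- meta[match(rownames(table), meta$sample_id), ]
  ctl <- unclass(table)[meta$is_control, , drop = FALSE]
  body <- unclass(table)[!meta$is_control, , drop = FALSE]
  flagged <- character()
  for (asv in colnames(table)) {
    prev <- mean(ctl[, asv] > 0)
    ab_ctl <- sum(ctl[, asv]) / sum(ctl)
    ab_body <- sum(body[, asv]) / sum(body)
    if (prev > th$kit_prev && ab_ctl > ab_body) flagged <- c(flagged, asv)
  }
  flagged
}

# Classic PERMANOVA F for a single grouping, straight from the group
# sums of squared distances (no Gower matrix).
oracle_permanova_f <- function(d, grouping) {
  d <- as.matrix(d)
  n <- nrow(d)
  ss_total <- sum(d[upper.tri(d)]^2) / n
  ss_within <- 0
  for (g in unique(grouping)) {
    idx <- which(grouping == g)
    dg <- d[idx, idx]
    ss_within <- ss_within + sum(dg[upper.tri(dg)]^2) / length(idx)
  }
  a <- length(unique(grouping))
  ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
}

# Exact permutation p for a 2-group PERMANOVA by enumerating group
# assignments (label exchanges, not full permutations).
oracle_permanova_exact_p <- function(d, grouping) {
  n <- length(grouping)
  g1 <- sum(grouping == unique(grouping)[1])
  f_obs <- oracle_permanova_f(d, grouping)
  combos <- combn(n, g1)
  fs <- apply(combos, 2, function(idx) {
    lab <- rep("b", n); lab[idx] <- "a"
    oracle_permanova_f(d, lab)
  })
  mean(fs >= f_obs - 1e-12)
}

# Greedy Ward merge sequence on Euclidean points: at each step merge the
# cluster pair whose union minimizes the increase in total within-cluster
# sum of squares. Returns the list of partitions after each merge.
oracle_ward_merges <- function(points) {
  ess <- function(idx) {
    c <- colMeans(points[idx, , drop = FALSE])
    sum(sweep(points[idx, , drop = FALSE], 2, c)^2)
  }
  clusters <- as.list(seq_len(nrow(points)))
  partitions <- list()
  while (length(clusters) > 1) {
    best <- NULL; best_cost <- Inf
    for (i in seq_len(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      cost <- ess(c(clusters[[i]], clusters[[j]])) -
        ess(clusters[[i]]) - ess(clusters[[j]])
      if (cost < best_cost) { best_cost <- cost; best <- c(i, j) }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
    labels <- integer(nrow(points))
    for (k in seq_along(clusters)) labels[clusters[[k]]] <- k
    partitions[[length(partitions) + 1]] <- labels
  }
  partitions
}

# Exhaustive (ASV, animal, combination) tuple enumeration for multi-way
# sharing, from raw presence lookups.
oracle_multiway_tallies <- function(table, meta, time) {
  meta <- meta[match(rownames(table), meta$sample_id), ]
  body <- meta[!meta$is_control & meta$time == time, ]
  sites <- sort(unique(body$site))
  animals <- unique(body$animal_id)
  m <- unclass(table)
  present <- function(animal, site, asv) {
    ids <- body$sample_id[body$animal_id == animal & body$site == site]
    length(ids) > 0 && sum(m[ids, asv]) > 0
  }
  has_comm <- function(animal, site) {
    any(body$animal_id == animal & body$site == site)
  }
  tally3 <- tally4 <- 0L
  for (animal in animals) for (asv in colnames(m)) {
    for (size in 3:4) {
      if (length(sites) < size) next
      for (cb in combn(sites, size, simplify = FALSE)) {
        if (!all(sapply(cb, has_comm, animal = animal))) next
        if (all(sapply(cb, present, animal = animal, asv = asv))) {
          if (size == 3) tally3 <- tally3 + 1L else tally4 <- tally4 + 1L
        }
      }
    }
  }
  c(three_way = tally3, four_way = tally4)
}

partition_label <- function(labels) {
  # canonical form invariant to label names
  match(labels, unique(labels))
}
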