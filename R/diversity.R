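#' Alpha diversity
#'
#' `observed_richness()` counts ASVs with positive counts; `shannon()` is
#' the Shannon entropy H = -sum p_i log p_i with natural logarithm, over the
#' positive proportions of one sample.
#'
#' @param counts numeric vector of one sample's counts.
#' @return integer (richness) or double (Shannon index, nats).
#' @export
observed_richness <- function(counts) {
  stopifnot(all(counts >= 0))
  sum(counts > 0)
}

#' @rdname observed_richness
#' @export
shannon <- function(counts) {
  stopifnot(all(counts >= 0))
  total <- sum(counts)
  if (total <= 0) stop("zero-total sample")
  p <- counts[counts > 0] / total
  -sum(p * log(p))
}

#' Alpha diversity for every sample of a table
#'
#' @param table an [asv_table()].
#' @return data.frame with `sample_id`, `richness`, `shannon`.
#' @export
alpha_diversity <- function(table) {
  m <- unclass(table)
  data.frame(sample_id = rownames(m),
             richness = apply(m, 1, observed_richness),
             shannon = apply(m, 1, shannon),
             row.names = NULL, stringsAsFactors = FALSE)
}

as_dist_matrix <- function(d, ids) {
  dimnames(d) <- list(ids, ids)
  diag(d) <- 0
  stats::as.dist(d)
}

#' Jaccard dissimilarity (presence/absence)
#'
#' d(A, B) = 1 - |A intersect B| / |A union B| on the sets of ASVs with
#' positive counts. Two empty samples are at distance 0 (with a warning).
#'
#' @param table an [asv_table()].
#' @return A `dist` object labelled by sample IDs.
#' @export
jaccard <- function(table) {
  m <- unclass(table) > 0
  if (nrow(m) < 2) stop("need at least two samples")
  storage.mode(m) <- "double"
  shared <- tcrossprod(m)
  sizes <- rowSums(m)
  union <- outer(sizes, sizes, "+") - shared
  if (any(union[upper.tri(union)] == 0)) {
    warning("pair(s) of all-zero samples; distance set to 0")
  }
  d <- ifelse(union > 0, 1 - shared / union, 0)
  as_dist_matrix(d, rownames(m))
}

#' Bray-Curtis dissimilarity
#'
#' BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i), computed on counts
#' (equivalently on relative abundances when sample depths are equal,
#' e.g. after rarefaction).
#'
#' @param table an [asv_table()].
#' @return A `dist` object labelled by sample IDs.
#' @export
bray_curtis <- function(table) {
  m <- unclass(table)
  storage.mode(m) <- "double"
  if (nrow(m) < 2) stop("need at least two samples")
  tot <- rowSums(m)
  if (any(tot <= 0)) {
    stop("zero-total sample(s): ", paste(rownames(m)[tot <= 0], collapse = ", "))
  }
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    rest <- (i + 1):n
    num <- rowSums(abs(m[rest, , drop = FALSE] -
                         matrix(m[i, ], length(rest), ncol(m), byrow = TRUE)))
    den <- tot[rest] + tot[i]
    d[rest, i] <- d[i, rest] <- num / den
  }
  as_dist_matrix(d, rownames(m))
}

# Edge -> leaf incidence of a tree, restricted and ordered to `leaves`.
# Returns list(lengths, incidence) with incidence a sparse edges x leaves
# 0/1 matrix: entry 1 iff the leaf descends from the edge's child node.
tree_edge_incidence <- function(tree, leaves) {
  validate_tree(tree)
  miss <- setdiff(leaves, tree$tip.label)
  if (length(miss)) {
    stop("ASV(s) absent from the tree: ", paste(miss, collapse = ", "))
  }
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  nedge <- nrow(tr$edge)
  node_tips <- vector("list", ntip + tr$Nnode)
  ei <- vector("list", nedge)
  for (k in seq_len(nedge)) {
    child <- tr$edge[k, 2]
    tips <- if (child <= ntip) child else node_tips[[child]]
    ei[[k]] <- tips
    parent <- tr$edge[k, 1]
    node_tips[[parent]] <- c(node_tips[[parent]], tips)
  }
  i <- rep.int(seq_len(nedge), lengths(ei))
  j <- unlist(ei)
  inc <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(nedge, ntip),
                              dimnames = list(NULL, tr$tip.label))
  list(lengths = tr$edge.length,
       incidence = inc[, leaves, drop = FALSE])
}

#' UniFrac dissimilarities
#'
#' Phylogenetic beta diversity. Unweighted UniFrac is the fraction of total
#' branch length leading to ASVs present in exactly one of the two samples;
#' weighted UniFrac weighs each branch by the difference in relative
#' abundance it subtends, `normalized = TRUE` (the usual "wUniFrac")
#' divides by the abundance-weighted total branch length.
#'
#' @param table an [asv_table()]; its ASVs must all be tree leaves.
#' @param tree rooted ape `phylo` with branch lengths.
#' @param normalized logical, weighted variant only.
#' @return A `dist` object labelled by sample IDs.
#' @export
unifrac_unweighted <- function(table, tree) {
  m <- unclass(table)
  inc <- tree_edge_incidence(tree, colnames(m))
  pres <- (m > 0) %*% Matrix::t(inc$incidence) > 0   # samples x edges
  pres <- as.matrix(pres)
  storage.mode(pres) <- "double"
  b <- inc$lengths
  pb <- sweep(pres, 2, b, "*")                       # weighted presence
  s <- tcrossprod(pb, pres)                          # sum b * pA*pB
  r <- rowSums(pb)                                   # sum b * pA
  tot <- outer(r, r, "+")
  num <- tot - 2 * s
  den <- tot - s
  d <- ifelse(den > 0, num / den, 0)
  as_dist_matrix(d, rownames(m))
}

#' @rdname unifrac_unweighted
#' @export
unifrac_weighted <- function(table, tree, normalized = TRUE) {
  rel <- relative_abundance(table)
  inc <- tree_edge_incidence(tree, colnames(rel))
  a <- as.matrix(rel %*% Matrix::t(inc$incidence))   # samples x edges
  b <- inc$lengths
  n <- nrow(a)
  d <- matrix(0, n, n)
  asum <- a %*% b
  for (i in seq_len(n - 1)) {
    rest <- (i + 1):n
    num <- abs(a[rest, , drop = FALSE] -
                 matrix(a[i, ], length(rest), ncol(a), byrow = TRUE)) %*% b
    if (normalized) {
      den <- asum[rest] + asum[i]
      num <- ifelse(den > 0, num / den, 0)
    }
    d[rest, i] <- d[i, rest] <- num
  }
  as_dist_matrix(d, rownames(rel))
}

#' Principal coordinates analysis (classical MDS)
#'
#' Double-centers -D^2/2, eigendecomposes it symmetrically, and returns
#' coordinates eigenvector * sqrt(eigenvalue) for strictly positive
#' eigenvalues, axes ordered by decreasing eigenvalue.  Negative
#' eigenvalues (from non-Euclidean dissimilarities) are reported but
#' excluded from the coordinates; no Cailliez/Lingoes correction is
#' applied.  Sign convention: each axis is flipped so its largest-magnitude
#' loading is positive.
#'
#' @param dm a `dist` object or symmetric matrix with zero diagonal.
#' @return list of class `pcoa_result` with `ids`, `coordinates`,
#'   `eigenvalues` (all, descending) and `proportion_explained`
#'   (over positive eigenvalues).
#' @export
pcoa <- function(dm) {
  d <- as.matrix(dm)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8)) {
    stop("distance matrix must be symmetric")
  }
  ids <- rownames(d)
  n <- nrow(d)
  g <- -0.5 * d^2
  g <- sweep(g, 1, rowMeans(g))
  g <- sweep(g, 2, colMeans(g))
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  ev <- e$values
  tol <- max(abs(ev), 0) * 1e-9
  pos <- which(ev > tol)
  coords <- if (length(pos)) {
    e$vectors[, pos, drop = FALSE] %*% diag(sqrt(ev[pos]), length(pos))
  } else {
    matrix(numeric(0), n, 0)
  }
  for (j in seq_len(ncol(coords))) {
    if (coords[which.max(abs(coords[, j])), j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- ids
  if (ncol(coords)) colnames(coords) <- paste0("Axis.", seq_len(ncol(coords)))
  structure(list(ids = ids, coordinates = coords, eigenvalues = ev,
                 proportion_explained = if (length(pos)) ev[pos] / sum(ev[pos]) else numeric()),
            class = "pcoa_result")
}

#' Compute a named beta-diversity dissimilarity
#'
#' @param table an [asv_table()].
#' @param metric one of `"jaccard"`, `"bray"`, `"unifrac"`, `"wunifrac"`.
#' @param tree required for the UniFrac metrics.
#' @return A `dist` object.
#' @export
beta_diversity <- function(table, metric = c("jaccard", "bray", "unifrac", "wunifrac"),
                           tree = NULL) {
  metric <- match.arg(metric)
  if (metric %in% c("unifrac", "wunifrac") && is.null(tree)) {
    stop("metric ", metric, " requires a tree")
  }
  switch(metric,
         jaccard = jaccard(table),
         bray = bray_curtis(table),
         unifrac = unifrac_unweighted(table, tree),
         wunifrac = unifrac_weighted(table, tree))
}

#' Write / read a distance matrix as square TSV
#'
#' @param dm a `dist` object.
#' @param path file path.
#' @return `path` (write) or a `dist` (read).
#' @export
write_dist <- function(dm, path) {
  m <- as.matrix(dm)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dist
#' @export
read_dist <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (any(abs(m - t(m)) > 1e-8) || any(diag(m) != 0) || any(m < 0)) {
    stop("not a valid distance matrix")
  }
  stats::as.dist(m)
}
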