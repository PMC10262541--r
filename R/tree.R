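#' Read a rooted phylogenetic tree over ASVs
#'
#' Reads a newick tree (via ape) and enforces the contract UniFrac needs:
#' every edge has a non-negative branch length (missing lengths are a format
#' error, never silently zero-filled) and leaf labels are the ASV IDs.
#'
#' @param path newick file path.
#' @return An ape `phylo` object.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick in ", path)
  validate_tree(tree)
}

#' Validate a phylogenetic tree for UniFrac use
#'
#' @param tree an ape `phylo` object.
#' @return The tree, invisibly validated.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths; UniFrac requires them")
  }
  if (anyNA(tree$edge.length)) stop("tree has missing branch lengths")
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels")
  tree
}

#' Write a tree as newick
#'
#' @param tree an ape `phylo` object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Leaf labels in deterministic order
#'
#' @param tree an ape `phylo` object.
#' @return Character vector of leaf labels, sorted.
#' @export
tree_leaves <- function(tree) sort(tree$tip.label)
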