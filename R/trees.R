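#' Read a phylogeny from a newick file
#'
#' Wraps \code{ape::read.tree} with the validation this pipeline relies on:
#' unique tip labels, at least two tips, and finite nonnegative branch
#' lengths. Edges with missing lengths are set to 0 with a warning.
#'
#' @param path newick file (or a literal newick string via \code{text}).
#' @param text optional newick string, read instead of \code{path}.
#' @return an \code{ape::phylo} tree.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tr)) stop("newick parse failure in ",
                        if (is.null(text)) path else "input string")
  validate_tree(tr)
}

#' @rdname read_newick
#' @param tree an \code{ape::phylo}.
#' @export
validate_tree <- function(tree) {
  .check(inherits(tree, "phylo"), "not a phylo object")
  .check(length(tree$tip.label) >= 2L, "tree needs at least 2 tips")
  .check(!anyDuplicated(tree$tip.label), "duplicate tip labels")
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; all set to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning("missing branch lengths set to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  .check(all(is.finite(tree$edge.length)) && all(tree$edge.length >= 0),
         "branch lengths must be finite and >= 0")
  tree
}

#' Write a phylogeny to newick
#'
#' @param tree an \code{ape::phylo}.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Patristic distance matrix of a tree
#'
#' Sum of branch lengths along the unique path between every pair of tips.
#'
#' @param tree an \code{ape::phylo} with branch lengths.
#' @return symmetric labeled matrix with zero diagonal.
#' @export
patristic_distances <- function(tree) {
  tree <- validate_tree(tree)
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining via \code{ape::nj}. On an additive matrix the
#' generating topology and branch lengths are recovered exactly; negative
#' estimated branch lengths (possible on non-additive input) are clamped to
#' zero with a warning.
#'
#' @param D symmetric labeled distance matrix, at least 3 taxa.
#' @return an unrooted \code{ape::phylo}.
#' @export
neighbor_joining <- function(D) {
  .check(is.matrix(D) && nrow(D) == ncol(D) && nrow(D) >= 3L,
         "need a square distance matrix with >= 3 taxa")
  .check(!is.null(rownames(D)), "distance matrix must be labeled")
  tr <- ape::nj(as.dist(D))
  if (any(tr$edge.length < 0)) {
    warning(sum(tr$edge.length < 0),
            " negative NJ branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}
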