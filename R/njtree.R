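#' Neighbor-joining tree from a p-distance matrix
#'
#' A lightweight distance-based clustering check: neighbor joining exactly
#' reconstructs any additive distance matrix, so lineage-specific
#' clustering of a protein family can be assessed without model-based tree
#' inference. The agglomeration is delegated to the standard
#' implementation in \pkg{ape}; negative branch lengths (possible on
#' non-additive input) are clamped to zero with a warning.
#'
#' @param x A [`p_dist`][distance_matrix] object, a `dist`, or a square
#'   numeric matrix with taxon dimnames. All pairwise entries must be
#'   defined.
#' @return An unrooted `phylo` tree with branch lengths. Serialise with
#'   `ape::write.tree()` for Newick output.
#' @export
#' @examples
#' d <- matrix(c(0, 3, 5, 6, 3, 0, 6, 7, 5, 6, 0, 7, 6, 7, 7, 0), 4, 4,
#'             dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' nj_tree(d)
nj_tree <- function(x) {
  m <- if (inherits(x, "p_dist")) x$distance
       else if (inherits(x, "dist")) as.matrix(x)
       else as.matrix(x)
  if (nrow(m) < 3L) abort("need at least three taxa")
  if (anyNA(m)) abort("distance matrix has undefined entries; cannot build a tree")
  tree <- ape::nj(stats::as.dist(m))
  if (any(tree$edge.length < 0)) {
    warn(sprintf("%d negative branch length(s) clamped to 0",
                 sum(tree$edge.length < 0)))
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}
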