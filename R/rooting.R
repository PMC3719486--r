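#' Root a gene tree on an outgroup leaf
#'
#' Places the root on the edge subtending the given outgroup leaf, at the
#' midpoint of that edge, preserving all internal node (support) labels
#' and the total branch length.
#'
#' @param phy a `phylo` (rooted input is unrooted first).
#' @param outgroup a tip label present in `phy`.
#' @return a rooted `phylo` whose root has the outgroup as one child.
#' @export
rootWithOutgroup <- function(phy, outgroup) {
  if (!inherits(phy, "phylo")) stop("phy must be a phylo", call. = FALSE)
  if (!outgroup %in% phy$tip.label)
    stop("outgroup leaf '", outgroup, "' not found in tree",
         call. = FALSE)
  if (ape::is.rooted(phy) && length(phy$tip.label) > 2L)
    phy <- ape::unroot(phy)
  r <- ape::root(phy, outgroup = outgroup, resolve.root = TRUE,
                 edgelabel = TRUE)
  if (!is.null(r$edge.length)) {
    rootEdges <- which(r$edge[, 1L] == rootNode(r))
    tot <- sum(r$edge.length[rootEdges])
    r$edge.length[rootEdges] <- tot / 2
  }
  r
}
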