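#' Map a clade to its origin node on the species tree
#'
#' The origin is the most recent common ancestor, on the species tree, of
#' the species retaining the clade; a single-species clade originates at
#' that species' leaf.
#'
#' @param species character vector of species names (non-empty).
#' @param speciesTree a `phylo` with named internal nodes.
#' @return the origin node name (a `node.label` or tip label).
#' @export
mapCladeOrigin <- function(species, speciesTree) {
  species <- unique(species)
  if (!length(species)) stop("empty species set", call. = FALSE)
  unknown <- setdiff(species, speciesTree$tip.label)
  if (length(unknown))
    stop("unknown species: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (length(species) == 1L) return(species)
  node <- ape::getMRCA(speciesTree, species)
  nodeNames(speciesTree)[node]
}

#' Dollo reconstruction of ancestral gene counts and branch gains/losses
#'
#' Each clade of the assignment (singletons count as one-gene clades) is
#' treated as a Dollo character: gained exactly once at its origin (the
#' MRCA of the species retaining it), present as a single ancestral copy
#' at every node on the paths from the origin to each retaining species,
#' and absent elsewhere. Ancestral node counts are the number of clades
#' present; a branch's gains are the clades originating at its child plus,
#' on terminal branches, the within-species copy-number expansion; its
#' losses are the clades present at the parent but absent at the child.
#'
#' @param ca a classified [CladeAssignment-class] (the gene -> species map
#'   must be filled; see [classifyGenes()]).
#' @param speciesTree a `phylo` with uniquely named internal nodes. Species
#'   absent from the assignment are allowed (count 0 everywhere).
#' @param extantCounts optional named integer vector of observed per-species
#'   gene counts. Defaults to the counts implied by the assignment; if
#'   supplied it is validated (it must not be smaller than the number of
#'   clades containing the species) and any surplus over the assigned genes
#'   is attributed to terminal-branch gains.
#' @return a [FamilyHistory-class].
#' @export
reconstructHistory <- function(ca, speciesTree, extantCounts = NULL) {
  stopifnot(is(ca, "CladeAssignment"))
  if (!length(ca@speciesMap))
    stop("assignment carries no species map; run classifyGenes()",
         call. = FALSE)
  phy <- speciesTree
  nm <- nodeNames(phy)
  if (any(nm == "") || anyDuplicated(nm))
    stop("species tree nodes (tips and internals) must carry unique names",
         call. = FALSE)
  ntip <- length(phy$tip.label)
  root <- rootNode(phy)

  ## clade membership, with singletons (and the outgroup) as 1-gene clades
  clades <- ca@clades
  for (g in c(ca@singletons, ca@outgroup))
    clades[[paste0("s_", g)]] <- g
  if (!length(clades)) stop("no clades to reconstruct", call. = FALSE)

  spOf <- ca@speciesMap
  bad <- setdiff(unique(spOf), phy$tip.label)
  if (length(bad))
    stop("species not in tree: ", paste(bad, collapse = ", "),
         call. = FALSE)

  ## per-clade: retaining species, per-species copy numbers, origin node
  retain <- lapply(clades, function(cl) unique(spOf[cl]))
  copies <- lapply(clades, function(cl) table(spOf[cl]))
  originName <- vapply(retain, mapCladeOrigin, character(1L),
                       speciesTree = phy)
  originIdx <- match(originName, nm)

  ## extant counts: implied by the assignment unless supplied
  implied <- table(spOf)
  counts <- setNames(integer(ntip), phy$tip.label)
  counts[names(implied)] <- as.integer(implied)
  surplus <- setNames(integer(ntip), phy$tip.label)
  if (!is.null(extantCounts)) {
    for (s in names(extantCounts)) {
      ncl <- sum(vapply(retain, function(r) s %in% r, logical(1L)))
      if (extantCounts[[s]] < ncl)
        stop("extant count for ", s, " (", extantCounts[[s]],
             ") is smaller than the number of clades containing it (",
             ncl, ")", call. = FALSE)
      if (extantCounts[[s]] < counts[[s]])
        stop("extant count for ", s,
             " is smaller than the genes assigned to it", call. = FALSE)
      surplus[[s]] <- as.integer(extantCounts[[s]]) - counts[[s]]
      counts[[s]] <- as.integer(extantCounts[[s]])
    }
  }

  ## presence: for each clade, the nodes on paths origin -> retaining leaf
  nNodes <- ntip + phy$Nnode
  presence <- matrix(FALSE, nNodes, length(clades))
  for (k in seq_along(clades)) {
    o <- originIdx[k]
    for (s in retain[[k]]) {
      node <- match(s, phy$tip.label)
      while (TRUE) {
        presence[node, k] <- TRUE
        if (node == o) break
        node <- parentOf(phy, node)
        if (is.na(node))
          stop("internal error: origin not an ancestor of retainer")
      }
    }
  }

  nodeCount <- integer(nNodes)
  for (v in seq_len(nNodes))
    nodeCount[v] <- sum(presence[v, ])
  nodeCount[seq_len(ntip)] <- counts   # leaves carry observed counts

  gains <- setNames(integer(nNodes), nm)
  losses <- setNames(integer(nNodes), nm)
  for (e in seq_len(nrow(phy$edge))) {
    par <- phy$edge[e, 1L]; ch <- phy$edge[e, 2L]
    chName <- nm[ch]
    if (ch > ntip) {
      gains[chName] <- sum(originIdx == ch)
      losses[chName] <- sum(presence[par, ] & !presence[ch, ])
    } else {
      s <- phy$tip.label[ch]
      g <- 0L; l <- 0L
      for (k in seq_along(clades)) {
        if (originIdx[k] == ch) {
          g <- g + as.integer(copies[[k]][[s]])
        } else if (presence[par, k]) {
          if (s %in% retain[[k]]) g <- g + as.integer(copies[[k]][[s]]) - 1L
          else l <- l + 1L
        }
      }
      gains[chName] <- g + surplus[[s]]
      losses[chName] <- l
    }
  }

  h <- new("FamilyHistory",
           nodeCounts = setNames(nodeCount, nm),
           gains = gains, losses = losses,
           origins = originName, speciesTree = phy)
  validObject(h)
  h
}

#' Export a family history as tables / annotated Newick
#'
#' @param h a [FamilyHistory-class].
#' @return `historyTables()`: list of two data.frames (`nodes`: node,
#'   count; `branches`: branch child, gains, losses).
#'   `historyNewick()`: the species tree in Newick with
#'   `name=count` node comments.
#' @export
historyTables <- function(h) {
  stopifnot(is(h, "FamilyHistory"))
  phy <- h@speciesTree
  nm <- nodeNames(phy)
  child <- nm[phy$edge[, 2L]]
  list(nodes = data.frame(node = names(h@nodeCounts),
                          count = as.integer(h@nodeCounts)),
       branches = data.frame(branch = child,
                             gains = as.integer(h@gains[child]),
                             losses = as.integer(h@losses[child])))
}

#' @rdname historyTables
#' @export
historyNewick <- function(h) {
  phy <- h@speciesTree
  lab <- nodeNames(phy)
  cnt <- h@nodeCounts[lab]
  phy$tip.label <- sprintf("%s=%d", phy$tip.label,
                           cnt[seq_along(phy$tip.label)])
  phy$node.label <- sprintf("%s=%d", phy$node.label,
                            cnt[-seq_along(phy$tip.label)])
  ape::write.tree(phy)
}
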