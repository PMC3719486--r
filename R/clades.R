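#' Extract maximal supported clades from a rooted gene tree
#'
#' Walks the tree from the root towards the leaves; on each root-to-leaf
#' path the first internal node with bootstrap support strictly greater
#' than `minSupport` and at least two leaves defines a clade, and its
#' descendants are not split further (maximality). Leaves covered by no
#' such node become singletons. Missing or non-numeric supports count as
#' zero; the root is never clade-defining. An outgroup leaf, if given,
#' is removed before extraction and kept in the `outgroup` slot.
#'
#' @param tree a rooted `phylo` whose `node.label` carries supports 0-100.
#' @param minSupport support threshold; comparison is strict (`>`),
#'   default 40.
#' @param outgroup optional tip label excluded before extraction.
#' @return a [CladeAssignment-class] with clades and singletons filled
#'   (categories empty until [classifyGenes()]).
#' @export
extractSupportedClades <- function(tree, minSupport = 40,
                                   outgroup = NULL) {
  if (!inherits(tree, "phylo")) stop("tree must be a phylo", call. = FALSE)
  if (!ape::is.rooted(tree))
    stop("tree must be rooted (see rootWithOutgroup)", call. = FALSE)
  og <- character()
  if (!is.null(outgroup)) {
    if (!outgroup %in% tree$tip.label)
      stop("outgroup leaf '", outgroup, "' not in tree", call. = FALSE)
    og <- outgroup
    tree <- ape::drop.tip(tree, outgroup)
  }
  ntip <- length(tree$tip.label)
  sup <- suppressWarnings(as.numeric(tree$node.label))
  sup[is.na(sup)] <- 0
  if (is.null(tree$node.label)) sup <- rep(0, tree$Nnode)

  clades <- list()
  supports <- numeric()
  singles <- character()
  root <- rootNode(tree)
  visit <- function(node) {
    if (node <= ntip) {
      singles <<- c(singles, tree$tip.label[node])
      return(invisible())
    }
    s <- sup[node - ntip]
    tips <- tipsBelow(tree, node)
    if (node != root && s > minSupport && length(tips) >= 2L) {
      clades[[length(clades) + 1L]] <<- tree$tip.label[tips]
      supports <<- c(supports, s)
      return(invisible())
    }
    for (ch in childrenOf(tree, node)) visit(ch)
  }
  visit(root)
  names(clades) <- sprintf("clade%02d", seq_along(clades))
  new("CladeAssignment", clades = clades, supports = supports,
      singletons = singles, categories = character(),
      speciesMap = character(), minSupport = minSupport, outgroup = og)
}

#' Classify genes as stable, unstable or singleton
#'
#' A clade spanning two or more species makes all its members "stable";
#' a clade confined to a single species (with two or more genes) makes
#' them "unstable"; genes in no supported clade are "singleton", as is
#' the excluded outgroup gene.
#'
#' @param ca a [CladeAssignment-class] from [extractSupportedClades()].
#' @param speciesMap named character vector, gene id -> species. Must
#'   cover every gene.
#' @return the assignment with `categories` (and `speciesMap`) filled.
#' @export
classifyGenes <- function(ca, speciesMap) {
  stopifnot(is(ca, "CladeAssignment"))
  genes <- c(unlist(ca@clades, use.names = FALSE), ca@singletons,
             ca@outgroup)
  missing <- setdiff(genes, names(speciesMap))
  if (length(missing))
    stop("no species mapping for gene(s): ",
         paste(head(missing, 5L), collapse = ", "), call. = FALSE)
  cats <- character()
  for (cl in ca@clades) {
    nsp <- length(unique(speciesMap[cl]))
    cats[cl] <- if (nsp >= 2L) "stable" else "unstable"
  }
  cats[ca@singletons] <- "singleton"
  if (length(ca@outgroup)) cats[ca@outgroup] <- "singleton"
  ca@categories <- cats
  ca@speciesMap <- speciesMap[names(cats)]
  validObject(ca)
  ca
}

#' Per-species tally of unstable, stable and singleton genes
#'
#' @param ca a classified [CladeAssignment-class].
#' @return data.frame with one row per species: counts per category, the
#'   species total, and percentages rounded to the nearest integer.
#' @export
tallyBySpecies <- function(ca) {
  stopifnot(is(ca, "CladeAssignment"))
  if (!length(ca@categories))
    stop("categories not assigned yet; run classifyGenes()", call. = FALSE)
  sp <- ca@speciesMap[names(ca@categories)]
  species <- unique(sp)
  rows <- lapply(species, function(s) {
    cc <- ca@categories[sp == s]
    n <- length(cc)
    u <- sum(cc == "unstable"); st <- sum(cc == "stable")
    si <- sum(cc == "singleton")
    data.frame(species = s, unstable = u, stable = st, singleton = si,
               total = n,
               unstablePct = round(100 * u / n),
               stablePct = round(100 * st / n),
               singletonPct = round(100 * si / n))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a CladeAssignment directly from per-gene categories
#'
#' Useful to tabulate published per-species classification counts through
#' the same [tallyBySpecies()] code path, or to import a curated clade
#' override.
#'
#' @param categories named character vector, gene ->
#'   "stable"/"unstable"/"singleton".
#' @param speciesMap named character vector, gene -> species.
#' @return a [CladeAssignment-class] with categories filled (clade list
#'   empty).
#' @export
cladeAssignmentFromCategories <- function(categories, speciesMap) {
  stopifnot(all(names(categories) %in% names(speciesMap)))
  new("CladeAssignment", clades = list(), supports = numeric(),
      singletons = names(categories)[categories == "singleton"],
      categories = categories,
      speciesMap = speciesMap[names(categories)],
      minSupport = NA_real_, outgroup = character())
}

#' Apply a curated clade override
#'
#' Replaces the automatic clade membership of the listed genes with
#' user-curated clade ids (e.g. clades grouped with external gene-family
#' resources rather than by bootstrap support).
#'
#' @param ca a [CladeAssignment-class].
#' @param override named character vector or two-column data.frame
#'   (gene id, clade id).
#' @return the modified assignment (categories cleared; re-run
#'   [classifyGenes()]).
#' @export
applyCladeOverride <- function(ca, override) {
  stopifnot(is(ca, "CladeAssignment"))
  if (is.data.frame(override))
    override <- setNames(as.character(override[[2L]]),
                         as.character(override[[1L]]))
  clades <- lapply(ca@clades, function(cl) setdiff(cl, names(override)))
  singles <- setdiff(ca@singletons, names(override))
  for (cid in unique(override)) {
    genes <- names(override)[override == cid]
    clades[[cid]] <- unique(c(clades[[cid]], genes))
  }
  keep <- lengths(clades) >= 2L
  singles <- c(singles, unlist(clades[!keep], use.names = FALSE))
  clades <- clades[keep]
  new("CladeAssignment", clades = clades,
      supports = rep(NA_real_, length(clades)),
      singletons = singles, categories = character(),
      speciesMap = character(), minSupport = ca@minSupport,
      outgroup = ca@outgroup)
}
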