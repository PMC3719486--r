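## Central S4 containers. Trees are ape "phylo" objects, sequences are
## Biostrings XStringSets and gene loci are GRanges; the classes below hold
## the objects this package itself defines.

setOldClass("phylo")

#' Simulation parameters for a gene-family birth-death process
#'
#' Bundles every tunable of the family simulator: per-branch duplication and
#' loss rates, duplication "waves" (lineage-specific bursts that multiply the
#' duplication rate over a fraction of a branch), the codon substitution
#' model (transition/transversion ratio `kappa`, a background omega and
#' per-domain omega regions), the root CDS length, tandem placement
#' behaviour, and the expression model (baseline, stable-gene offset
#' `exprDelta`, noise `exprSigma`).
#'
#' @slot lambda numeric; duplication rate per gene lineage per unit branch
#'   length. Either a single value or a vector named by species-tree branch
#'   (child node name) overriding the first, unnamed element.
#' @slot mu numeric; loss rate, same conventions as `lambda`.
#' @slot waves data.frame with columns `branch`, `mult`, `from`, `to`:
#'   within the `[from, to]` fraction of `branch` the duplication rate is
#'   multiplied by `mult`.
#' @slot kappa numeric(1); transition/transversion rate ratio.
#' @slot omegaBackground numeric(1); dN/dS outside the declared regions.
#' @slot regions data.frame with columns `name`, `start`, `end`, `omega`;
#'   codon intervals (1-based, inclusive) with their own omega.
#' @slot rootLength integer(1); CDS length at the root, in codons.
#' @slot tandemProb numeric(1) in [0,1]; probability that a duplicate is
#'   placed in tandem (< 10 kb downstream) with its parent copy.
#' @slot tandemMaxOffset integer(1); largest intergenic gap (bp) used for a
#'   tandem placement.
#' @slot exprBaseline,exprDelta,exprSigma numeric(1); log2-scale expression
#'   baseline, additive offset for stable genes, and noise SD.
#' @slot seed integer(1) or NA; master seed. All simulator randomness
#'   derives from it (family: seed, sequences: seed+1, loci: seed+2,
#'   expression: seed+3).
#' @seealso [simParams()]
#' @export
setClass("SimParams", representation(
  lambda = "numeric", mu = "numeric", waves = "data.frame",
  kappa = "numeric", omegaBackground = "numeric", regions = "data.frame",
  rootLength = "integer", tandemProb = "numeric",
  tandemMaxOffset = "integer",
  exprBaseline = "numeric", exprDelta = "numeric", exprSigma = "numeric",
  seed = "integer"))

setValidity("SimParams", function(object) {
  msg <- character()
  if (any(object@lambda < 0) || any(object@mu < 0))
    msg <- c(msg, "duplication and loss rates must be >= 0")
  if (length(object@kappa) != 1L || object@kappa <= 0)
    msg <- c(msg, "kappa must be a single positive number")
  if (object@omegaBackground < 0)
    msg <- c(msg, "omegaBackground must be >= 0")
  if (length(object@rootLength) != 1L || object@rootLength < 1L)
    msg <- c(msg, "rootLength must be >= 1 codon")
  if (object@tandemProb < 0 || object@tandemProb > 1)
    msg <- c(msg, "tandemProb must lie in [0, 1]")
  if (object@tandemMaxOffset < 1L)
    msg <- c(msg, "tandemMaxOffset must be positive")
  if (object@exprSigma <= 0)
    msg <- c(msg, "exprSigma must be > 0")
  rg <- object@regions
  if (nrow(rg)) {
    if (!all(c("name", "start", "end", "omega") %in% names(rg)))
      msg <- c(msg, "regions needs columns name, start, end, omega")
    else {
      if (any(rg$start > rg$end) || any(rg$start < 1L))
        msg <- c(msg, "region intervals must satisfy 1 <= start <= end")
      if (any(rg$end > object@rootLength))
        msg <- c(msg, "regions must lie within the CDS")
      if (any(rg$omega < 0)) msg <- c(msg, "region omega must be >= 0")
      if (nrow(rg) > 1L) {
        o <- order(rg$start)
        if (any(rg$start[o][-1L] <= rg$end[o][-nrow(rg)]))
          msg <- c(msg, "regions must be disjoint")
      }
    }
  }
  wv <- object@waves
  if (nrow(wv) && !all(c("branch", "mult", "from", "to") %in% names(wv)))
    msg <- c(msg, "waves needs columns branch, mult, from, to")
  if (nrow(wv) && any(wv$from < 0 | wv$to > 1 | wv$from >= wv$to))
    msg <- c(msg, "wave windows must satisfy 0 <= from < to <= 1")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated gene family
#'
#' Everything the simulator knows about a run: the true gene tree, the
#' gene-to-species map, the event log, per-branch lineage bookkeeping,
#' and two gene groupings derived from the history: `founders` (the
#' ancestral lineage alive at the reference node, which defines the true
#' stable/unstable/singleton categories) and `eventClades` (the finest
#' decomposition, one group per retained duplication copy, used to compare
#' Dollo gain counts with the true event counts).
#'
#' @slot geneTree the true gene tree (`phylo`), or NULL for families with
#'   fewer than two surviving genes.
#' @slot speciesMap named character; gene id -> species.
#' @slot events data.frame with columns `branch`, `time`, `type`
#'   ("duplication"/"loss"), `lineage`.
#' @slot branchCounts data.frame with columns `branch`, `nIn`, `nOut`,
#'   `dups`, `losses`; lineages entering/leaving each species-tree branch.
#' @slot founders,eventClades named character; gene id -> group id.
#' @slot refNode character(1); species-tree node at which founder lineages
#'   were read off.
#' @slot tandem list of character vectors; true tandem clusters (filled by
#'   [placeLoci()]).
#' @slot regions data.frame; the omega regions used for sequence evolution.
#' @seealso [simulateFamily()], [trueCategories()]
#' @export
setClass("SimTruth", representation(
  geneTree = "ANY", speciesMap = "character", events = "data.frame",
  branchCounts = "data.frame", founders = "character",
  eventClades = "character", refNode = "character", tandem = "list",
  regions = "data.frame"))

setValidity("SimTruth", function(object) {
  msg <- character()
  g <- names(object@speciesMap)
  if (anyDuplicated(g))
    msg <- c(msg, "every extant gene must appear exactly once")
  bc <- object@branchCounts
  if (nrow(bc) && any(bc$nOut != bc$nIn + bc$dups - bc$losses))
    msg <- c(msg, "branch bookkeeping violated: nOut != nIn + dups - losses")
  if (length(object@founders) && !setequal(names(object@founders), g))
    msg <- c(msg, "founders must cover exactly the extant genes")
  if (length(msg)) msg else TRUE
})

#' Partition of genes into supported clades with evolutionary categories
#'
#' Produced by [extractSupportedClades()] and completed by
#' [classifyGenes()]. Clades are the maximal nodes of a rooted gene tree
#' with bootstrap support strictly above `minSupport` and at least two
#' leaves; leaves covered by no such node are singletons. Categories follow
#' the clade's species span: two or more species -> "stable", one species
#' with two or more genes -> "unstable", otherwise "singleton".
#'
#' @slot clades named list of character vectors (gene ids per clade).
#' @slot supports numeric; bootstrap support of each clade (0-100).
#' @slot singletons character; genes in no supported clade.
#' @slot categories named character; gene -> "stable"/"unstable"/"singleton"
#'   (empty until [classifyGenes()] is run).
#' @slot speciesMap named character; gene -> species (filled by
#'   [classifyGenes()]).
#' @slot minSupport numeric(1); the support threshold used (strict >).
#' @slot outgroup character; the excluded outgroup leaf, if any.
#' @export
setClass("CladeAssignment", representation(
  clades = "list", supports = "numeric", singletons = "character",
  categories = "character", speciesMap = "character",
  minSupport = "numeric", outgroup = "character"))

setValidity("CladeAssignment", function(object) {
  msg <- character()
  all_g <- unlist(object@clades, use.names = FALSE)
  if (anyDuplicated(all_g)) msg <- c(msg, "clades must be disjoint")
  if (length(intersect(all_g, object@singletons)))
    msg <- c(msg, "singletons must not occur inside clades")
  if (length(object@categories)) {
    bad <- setdiff(unique(object@categories),
                   c("stable", "unstable", "singleton"))
    if (length(bad))
      msg <- c(msg, paste("unknown category:", paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Ancestral gene counts and per-branch gains/losses on a species tree
#'
#' Result of the Dollo reconstruction in [reconstructHistory()]: each clade
#' is gained exactly once at its origin (the MRCA of the species retaining
#' it), carried as a single ancestral copy along every path from the origin
#' to a retaining species, and lost on branches leading away from them;
#' within-species copy-number expansion is attributed to the terminal
#' branch. The conservation identity
#' `count(child) = count(parent) + gains - losses` is enforced on every
#' branch by the class validity.
#'
#' @slot nodeCounts named integer; gene count per species-tree node
#'   (internal nodes: number of ancestral clades present; leaves: extant
#'   gene count).
#' @slot gains,losses named integer; per branch, keyed by child node name.
#' @slot origins named character; clade id -> origin node name.
#' @slot speciesTree the species tree (`phylo`) the history lives on.
#' @export
setClass("FamilyHistory", representation(
  nodeCounts = "integer", gains = "integer", losses = "integer",
  origins = "character", speciesTree = "ANY"))

setValidity("FamilyHistory", function(object) {
  phy <- object@speciesTree
  if (!inherits(phy, "phylo")) return("speciesTree must be a phylo object")
  nm <- c(phy$tip.label, phy$node.label)
  parent <- nm[phy$edge[, 1L]]
  child <- nm[phy$edge[, 2L]]
  lhs <- object@nodeCounts[child]
  rhs <- object@nodeCounts[parent] + object@gains[child] -
    object@losses[child]
  if (any(is.na(lhs)) || any(is.na(rhs)))
    return("nodeCounts/gains/losses must be keyed by node name")
  if (any(lhs != rhs))
    return("conservation violated: count(child) != count(parent) + gains - losses")
  if (any(object@gains < 0L) || any(object@losses < 0L))
    return("gains and losses must be >= 0")
  TRUE
})

#' Pairwise Ka/Ks estimate (NG86 counting, Jukes-Cantor correction)
#'
#' @slot nCodons integer(1); codons compared (after pairwise codon
#'   deletion).
#' @slot sSites,nSites numeric(1); synonymous / nonsynonymous site counts
#'   averaged over the two sequences.
#' @slot sDiff,nDiff numeric(1); pathway-averaged synonymous /
#'   nonsynonymous differences.
#' @slot pS,pN numeric(1); proportions of differences per site.
#' @slot ks,ka numeric(1); Jukes-Cantor corrected estimates (NA when
#'   saturated).
#' @slot ratio numeric(1); Ka/Ks, NA when undefined.
#' @slot flag character(1); "ok", "undefined" (Ka = Ks = 0), "infinite"
#'   (Ks = 0 < Ka), or "saturated" (p >= 3/4 so the correction diverges).
#' @export
setClass("KaKsResult", representation(
  nCodons = "integer", sSites = "numeric", nSites = "numeric",
  sDiff = "numeric", nDiff = "numeric", pS = "numeric", pN = "numeric",
  ks = "numeric", ka = "numeric", ratio = "numeric", flag = "character"))

setValidity("KaKsResult", function(object) {
  msg <- character()
  if (abs(object@sSites + object@nSites - 3 * object@nCodons) > 1e-6)
    msg <- c(msg, "site counts must sum to 3 x codon count")
  if (!is.na(object@ka) && object@ka < 0) msg <- c(msg, "Ka must be >= 0")
  if (!is.na(object@ks) && object@ks < 0) msg <- c(msg, "Ks must be >= 0")
  if (!object@flag %in% c("ok", "undefined", "infinite", "saturated"))
    msg <- c(msg, "unknown flag")
  if (length(msg)) msg else TRUE
})

#' Sliding-window Ka/Ks profile along a pairwise codon alignment
#'
#' @slot windows data.frame with one row per window: `start`, `midpoint`,
#'   `end` (1-based bp in alignment coordinates), the NG86 counts, `ka`,
#'   `ks`, `ratio` and `flag`.
#' @slot windowSize,stepSize integer(1); both multiples of 3 (bp).
#' @slot alignmentLength integer(1); alignment length in bp.
#' @export
setClass("KaKsProfile", representation(
  windows = "data.frame", windowSize = "integer", stepSize = "integer",
  alignmentLength = "integer"))

setValidity("KaKsProfile", function(object) {
  w <- object@windowSize; s <- object@stepSize; L <- object@alignmentLength
  msg <- character()
  if (w %% 3L != 0L || s %% 3L != 0L)
    msg <- c(msg, "window and step must be multiples of 3")
  expected <- (L - w) %/% s + 1L
  if (nrow(object@windows) != expected)
    msg <- c(msg, "window count must equal floor((L - w)/step) + 1")
  if (nrow(object@windows) &&
      (any(object@windows$start < 1L) || any(object@windows$end > L)))
    msg <- c(msg, "windows must lie within the alignment")
  if (length(msg)) msg else TRUE
})
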