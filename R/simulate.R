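#' Simulate a gene family along a species tree
#'
#' Gene lineages evolve from a single root gene by a birth-death process:
#' exponential waiting times per lineage with per-branch duplication rate
#' lambda and loss rate mu (Gillespie), with "wave" windows multiplying
#' the duplication rate over a stated fraction of a branch. At each
#' speciation every surviving lineage enters both child branches. The
#' returned truth records every event, per-branch lineage bookkeeping,
#' and two history-derived gene groupings: founder lineages (alive at
#' `refNode`; these define the true stable/unstable/singleton
#' categories) and event clades (one per retained duplication copy).
#'
#' @param speciesTree rooted `phylo` with unique tip and internal node
#'   names and branch lengths.
#' @param params a [SimParams-class].
#' @param refNode species-tree node at which founder lineages are read
#'   off. Default: the non-leaf child of the root when the root subtends
#'   a single-leaf outgroup, otherwise the root.
#' @param seed overrides `params@seed`.
#' @return list with `geneTree` (a `phylo`, or NULL when fewer than two
#'   genes survive — an empty family is a result, not an error) and
#'   `truth` (a [SimTruth-class]).
#' @examples
#' tr <- defaultSpeciesTree()
#' sim <- simulateFamily(tr, simParams(seed = 1))
#' table(speciesMap(sim$truth))
#' @export
simulateFamily <- function(speciesTree, params, refNode = NULL,
                           seed = params@seed) {
  stopifnot(is(params, "SimParams"))
  validObject(params)
  phy <- speciesTree
  if (!inherits(phy, "phylo") || is.null(phy$edge.length))
    stop("speciesTree must be a phylo with branch lengths", call. = FALSE)
  nm <- nodeNames(phy)
  if (any(nm == "") || anyDuplicated(nm))
    stop("species tree nodes must carry unique names", call. = FALSE)
  ntip <- length(phy$tip.label)
  root <- rootNode(phy)
  if (is.null(refNode)) {
    rootKids <- childrenOf(phy, root)
    tipKids <- rootKids[rootKids <= ntip]
    refNode <- if (length(tipKids) == 1L && length(rootKids) == 2L)
      nm[setdiff(rootKids, tipKids)] else nm[root]
  }
  if (!refNode %in% nm)
    stop("refNode '", refNode, "' not in the species tree", call. = FALSE)

  st <- new.env(parent = emptyenv())
  st$events <- list()
  branchNames <- nm[phy$edge[, 2L]]
  st$nIn <- setNames(integer(length(branchNames)), branchNames)
  st$nOut <- st$nIn
  st$geneNum <- setNames(integer(ntip), phy$tip.label)
  st$linNum <- 1L
  st$founderNum <- 0L
  st$speciesMap <- character()
  st$founders <- character()
  st$eventClades <- character()

  newLineage <- function(founder, eventClade) {
    st$linNum <- st$linNum + 1L
    list(id = st$linNum, founder = founder, eventClade = eventClade)
  }
  logEvent <- function(branch, time, type, lineage) {
    st$events[[length(st$events) + 1L]] <-
      list(branch = branch, time = time, type = type, lineage = lineage)
  }

  waves <- params@waves
  fmt <- function(x) sprintf("%.10g", x)

  ## simulate one lineage along the branch into node `ch`, from relative
  ## time t0; returns NULL (extinct) or list(frag = newick, len = edge
  ## length above the fragment's top node)
  descend <- function(ch, t0, lin) {
    bname <- nm[ch]
    B <- branchLengthAbove(phy, ch)
    lam0 <- .branchRate(params@lambda, bname)
    mu0 <- .branchRate(params@mu, bname)
    wv <- waves[waves$branch == bname, , drop = FALSE]
    breaks <- sort(unique(c(wv$from, wv$to))) * B
    t <- t0
    while (t < B) {
      inWave <- nrow(wv) && any(wv$from * B <= t + 1e-12 &
                                t < wv$to * B - 1e-12)
      lamNow <- if (inWave)
        lam0 * prod(wv$mult[wv$from * B <= t + 1e-12 &
                            t < wv$to * B - 1e-12])
      else lam0
      nextBreak <- c(breaks[breaks > t + 1e-12], B)[1L]
      nextBreak <- min(nextBreak, B)
      rate <- lamNow + mu0
      if (rate <= 0) { t <- nextBreak; next }
      dt <- rexp(1L, rate)
      if (t + dt >= nextBreak) { t <- nextBreak; next }
      t <- t + dt
      if (runif(1L) < lamNow / rate) {
        lin2 <- newLineage(lin$founder, eventClade = NA)
        lin2$eventClade <- paste0("E", lin2$id)
        logEvent(bname, t, "duplication", lin2$id)
        r1 <- descend(ch, t, lin)
        r2 <- descend(ch, t, lin2)
        if (is.null(r1) && is.null(r2)) return(NULL)
        if (is.null(r2)) return(list(frag = r1$frag,
                                     len = r1$len + (t - t0)))
        if (is.null(r1)) return(list(frag = r2$frag,
                                     len = r2$len + (t - t0)))
        return(list(frag = sprintf("(%s:%s,%s:%s)", r1$frag, fmt(r1$len),
                                   r2$frag, fmt(r2$len)),
                    len = t - t0))
      } else {
        logEvent(bname, t, "loss", lin$id)
        return(NULL)
      }
    }
    ## reached the end of the branch
    st$nOut[bname] <- st$nOut[bname] + 1L
    if (ch <= ntip) {
      sp <- phy$tip.label[ch]
      st$geneNum[sp] <- st$geneNum[sp] + 1L
      gid <- sprintf("%s_g%02d", sp, st$geneNum[sp])
      st$speciesMap[gid] <- sp
      st$founders[gid] <- lin$founder
      st$eventClades[gid] <- lin$eventClade
      return(list(frag = gid, len = B - t0))
    }
    atNode(ch, lin, B - t0)
  }

  ## speciation at internal node `node`; returns fragment with `extra`
  ## added to its top edge length
  atNode <- function(node, lin, extra) {
    if (nm[node] == refNode) {
      st$founderNum <- st$founderNum + 1L
      lin$founder <- sprintf("F%02d", st$founderNum)
    }
    kids <- childrenOf(phy, node)
    res <- list()
    for (k in kids) {
      st$nIn[nm[k]] <- st$nIn[nm[k]] + 1L
      kl <- newLineage(lin$founder, lin$eventClade)
      r <- descend(k, 0, kl)
      if (!is.null(r)) res[[length(res) + 1L]] <- r
    }
    if (!length(res)) return(NULL)
    if (length(res) == 1L)
      return(list(frag = res[[1L]]$frag, len = res[[1L]]$len + extra))
    inner <- paste(vapply(res, function(r)
      sprintf("%s:%s", r$frag, fmt(r$len)), character(1L)),
      collapse = ",")
    list(frag = sprintf("(%s)", inner), len = extra)
  }

  res <- withSeed(seed, {
    lin0 <- list(id = 1L, founder = "F00", eventClade = "E1")
    atNode(root, lin0, 0)
  })

  events <- if (length(st$events)) {
    do.call(rbind, lapply(st$events, function(e)
      data.frame(branch = e$branch, time = e$time, type = e$type,
                 lineage = e$lineage)))
  } else {
    data.frame(branch = character(), time = numeric(),
               type = character(), lineage = integer())
  }
  dups <- table(factor(events$branch[events$type == "duplication"],
                       levels = branchNames))
  losses <- table(factor(events$branch[events$type == "loss"],
                         levels = branchNames))
  branchCounts <- data.frame(
    branch = branchNames,
    nIn = as.integer(st$nIn[branchNames]),
    nOut = as.integer(st$nOut[branchNames]),
    dups = as.integer(dups[branchNames]),
    losses = as.integer(losses[branchNames]))

  geneTree <- NULL
  if (!is.null(res) && length(st$speciesMap) >= 2L)
    geneTree <- ape::read.tree(text = paste0(res$frag, ";"))

  truth <- new("SimTruth", geneTree = geneTree,
               speciesMap = st$speciesMap, events = events,
               branchCounts = branchCounts, founders = st$founders,
               eventClades = st$eventClades, refNode = refNode,
               tandem = list(), regions = params@regions)
  validObject(truth)
  list(geneTree = geneTree, truth = truth)
}

#' @describeIn simulateFamily true gene categories implied by the
#'   simulated history: a founder lineage retained in two or more species
#'   is "stable", one confined to a single species with two or more
#'   copies is "unstable", a lone survivor is a "singleton".
#' @export
setMethod("trueCategories", "SimTruth", function(x) {
  f <- x@founders
  sp <- x@speciesMap
  out <- setNames(character(length(f)), names(f))
  for (fid in unique(f)) {
    g <- names(f)[f == fid]
    nsp <- length(unique(sp[g]))
    out[g] <- if (nsp >= 2L) "stable"
      else if (length(g) >= 2L) "unstable" else "singleton"
  }
  out
})

#' Clade assignment implied by the simulated truth
#'
#' Groups genes by founder lineage (the grouping behind the true
#' categories) or by event clade (one group per retained duplication
#' copy — the finest Dollo-consistent decomposition, used to compare
#' reconstructed gains with true duplication counts).
#'
#' @param truth a [SimTruth-class].
#' @param level "founder" or "event".
#' @return a classified [CladeAssignment-class].
#' @export
trueCladeAssignment <- function(truth, level = c("founder", "event")) {
  level <- match.arg(level)
  grp <- if (level == "founder") truth@founders else truth@eventClades
  clades <- split(names(grp), grp)
  multi <- clades[lengths(clades) >= 2L]
  singles <- unlist(clades[lengths(clades) < 2L], use.names = FALSE)
  ca <- new("CladeAssignment", clades = multi,
            supports = rep(100, length(multi)),
            singletons = if (is.null(singles)) character() else singles,
            categories = character(), speciesMap = character(),
            minSupport = NA_real_, outgroup = character())
  classifyGenes(ca, truth@speciesMap)
}
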