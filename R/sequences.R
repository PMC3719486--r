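## MG94-style codon sequence evolution along a gene tree: HKY-type
## mutation with transition bias kappa, nonsynonymous changes scaled by
## a per-region omega, stop-codon mutations forbidden. Rates are
## normalized by (kappa + 2) so that one unit of branch length equals
## one expected neutral mutation per nucleotide site.

## 9 mutation rates of one codon (3 positions x 3 alternative bases)
.codonRates <- function(ci, w, kappa, tab) {
  tg <- tab$target[ci, , ]           # 3 x 3
  ts <- tab$isTs[ci, , ]
  r <- ifelse(ts, kappa, 1)
  syn <- tab$aa[tg] == tab$aa[ci]
  r <- r * ifelse(syn, 1, w)
  r[tab$isStop[tg]] <- 0
  r / (kappa + 2)
}

## per-codon omega vector from background + region table
.omegaVector <- function(params) {
  w <- rep(params@omegaBackground, params@rootLength)
  rg <- params@regions
  for (i in seq_len(nrow(rg)))
    w[rg$start[i]:rg$end[i]] <- rg$omega[i]
  w
}

#' Evolve codon sequences along a gene tree
#'
#' Draws a random stop-free root CDS and evolves it along every branch
#' with a Gillespie simulation of single-base mutations: transition bias
#' `kappa`, nonsynonymous acceptance scaled by the per-region omega, and
#' stop-creating mutations rejected (so no in-frame stop can ever
#' arise). There are no indels, hence the rows form a gap-free codon
#' alignment.
#'
#' @param geneTree a `phylo` with branch lengths (e.g. from
#'   [simulateFamily()]).
#' @param params a [SimParams-class]; `rootLength`, `kappa`,
#'   `omegaBackground` and `regions` are used. Regions must lie within
#'   the CDS (enforced by the class validity).
#' @param seed RNG seed; defaults to `params@seed + 1` (the documented
#'   stream split: family = seed, sequences = seed + 1).
#' @return a named `DNAStringSet`, one gap-free row per tip.
#' @seealso [translateCds()] to obtain the protein alignment.
#' @export
evolveSequences <- function(geneTree, params,
                            seed = if (is.na(params@seed)) NA_integer_
                                   else params@seed + 1L) {
  stopifnot(is(params, "SimParams"))
  validObject(params)
  if (!inherits(geneTree, "phylo") || is.null(geneTree$edge.length))
    stop("geneTree must be a phylo with branch lengths", call. = FALSE)
  tab <- .codonTables()
  L <- params@rootLength
  w <- .omegaVector(params)
  kappa <- params@kappa
  nonStop <- which(!tab$isStop)

  withSeed(seed, {
    rootSeq <- sample(nonStop, L, replace = TRUE)
    ntip <- length(geneTree$tip.label)
    seqs <- vector("list", ntip + geneTree$Nnode)
    seqs[[rootNode(geneTree)]] <- rootSeq
    edges <- ape::reorder.phylo(geneTree, "cladewise")$edge
    edgeLen <- ape::reorder.phylo(geneTree, "cladewise")$edge.length
    for (e in seq_len(nrow(edges))) {
      par <- edges[e, 1L]; ch <- edges[e, 2L]
      seqs[[ch]] <- .evolveEdge(seqs[[par]], edgeLen[e], w, kappa, tab)
    }
    out <- vapply(seq_len(ntip), function(i)
      paste(tab$codons[seqs[[i]]], collapse = ""), character(1L))
    names(out) <- geneTree$tip.label
    Biostrings::DNAStringSet(out)
  })
}

## Gillespie walk over one edge; s = codon index vector
.evolveEdge <- function(s, len, w, kappa, tab) {
  if (len <= 0) return(s)
  L <- length(s)
  R <- matrix(0, L, 9L)
  for (i in seq_len(L)) R[i, ] <- .codonRates(s[i], w[i], kappa, tab)
  tot <- sum(R)
  t <- 0
  repeat {
    t <- t + rexp(1L, tot)
    if (t >= len) break
    k <- sample.int(L * 9L, 1L, prob = as.vector(R))
    i <- (k - 1L) %% L + 1L
    j <- (k - 1L) %/% L + 1L
    p <- (j - 1L) %% 3L + 1L
    a <- (j - 1L) %/% 3L + 1L
    s[i] <- tab$target[s[i], p, a]
    tot <- tot - sum(R[i, ])
    R[i, ] <- .codonRates(s[i], w[i], kappa, tab)
    tot <- tot + sum(R[i, ])
  }
  s
}

#' Translate a codon alignment to proteins
#'
#' @param cds named `DNAStringSet` or character vector of gap-free CDS
#'   rows.
#' @return named character vector of protein sequences (terminal stop,
#'   if any, trimmed).
#' @export
translateCds <- function(cds) {
  if (is.character(cds)) cds <- Biostrings::DNAStringSet(cds)
  aa <- as.character(Biostrings::translate(cds, no.init.codon = TRUE))
  sub("\\*$", "", aa)
}
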