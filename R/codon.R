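## Codon-level machinery shared by the NG86 estimator and the sequence
## simulator: the standard genetic code (from Biostrings), single-base
## mutation targets, transition flags and stop masks, all as lookup
## tables built once per session.

.codonCache <- new.env(parent = emptyenv())

.BASES <- c("T", "C", "A", "G")
.PURINES <- c("A", "G")

.codonTables <- function() {
  if (!is.null(.codonCache$tab)) return(.codonCache$tab)
  codons <- as.vector(outer(outer(.BASES, .BASES, paste0), .BASES,
                            function(ab, c) paste0(c, ab)))
  codons <- sort(codons)  # deterministic order; index by name anyway
  aa <- Biostrings::GENETIC_CODE[codons]
  isStop <- aa == "*"
  ## mutation targets: target[c, p, a] = codon index after changing
  ## position p of codon c to its a-th alternative base
  target <- array(0L, c(64L, 3L, 3L))
  isTs <- array(FALSE, c(64L, 3L, 3L))
  for (ci in 1:64) {
    sp <- strsplit(codons[ci], "")[[1L]]
    for (p in 1:3) {
      alts <- setdiff(.BASES, sp[p])
      for (a in 1:3) {
        nc <- sp; nc[p] <- alts[a]
        target[ci, p, a] <- match(paste(nc, collapse = ""), codons)
        isTs[ci, p, a] <- (sp[p] %in% .PURINES) == (alts[a] %in% .PURINES)
      }
    }
  }
  .codonCache$tab <- list(codons = codons, aa = aa, isStop = isStop,
                          target = target, isTs = isTs)
  .codonCache$tab
}

.codonIndex <- function(codon) {
  tab <- .codonTables()
  idx <- match(codon, tab$codons)
  idx
}

#' NG86 synonymous and nonsynonymous site counts of one codon
#'
#' For each codon position the synonymous fraction is the number of
#' synonymous single-base changes divided by the number of changes that
#' do not create a stop codon; the codon's synonymous site count `s` is
#' the sum over the three positions and `n = 3 - s`.
#'
#' @param codon a 3-letter string over ACGT, not a stop codon.
#' @return named numeric c(s = , n = ).
#' @examples
#' ng86CodonSites("TTT")  # s = 1/3
#' ng86CodonSites("CTT")  # s = 1 (fourfold third position)
#' @export
ng86CodonSites <- function(codon) {
  tab <- .codonTables()
  codon <- toupper(codon)
  if (nchar(codon) != 3L || grepl("[^ACGT]", codon))
    stop("codon must be 3 unambiguous bases (ACGT)", call. = FALSE)
  ci <- .codonIndex(codon)
  if (tab$isStop[ci])
    stop("stop codon has no NG86 site decomposition", call. = FALSE)
  s <- 0
  for (p in 1:3) {
    tg <- tab$target[ci, p, ]
    ok <- !tab$isStop[tg]
    if (!any(ok)) next
    syn <- sum(tab$aa[tg[ok]] == tab$aa[ci])
    s <- s + syn / sum(ok)
  }
  c(s = s, n = 3 - s)
}

## Permutations of 1..d for the mutation-pathway enumeration.
.PERMS <- list(
  list(1L),
  list(c(1L, 2L), c(2L, 1L)),
  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

## Pathway-averaged (synonymous, nonsynonymous) differences between two
## non-stop codons. Paths traversing a stop codon are excluded; if every
## path is blocked, the average falls back to all paths (a step to or
## from a stop counts as nonsynonymous).
.ng86DiffPair <- function(ci, cj) {
  tab <- .codonTables()
  b1 <- strsplit(tab$codons[ci], "")[[1L]]
  b2 <- strsplit(tab$codons[cj], "")[[1L]]
  pos <- which(b1 != b2)
  d <- length(pos)
  if (d == 0L) return(c(sd = 0, nd = 0))
  paths <- .PERMS[[d]]
  stats <- matrix(0, length(paths), 2L)
  blocked <- logical(length(paths))
  for (k in seq_along(paths)) {
    cur <- b1
    syn <- 0; nsyn <- 0
    for (stepPos in pos[paths[[k]]]) {
      prevAA <- Biostrings::GENETIC_CODE[[paste(cur, collapse = "")]]
      cur[stepPos] <- b2[stepPos]
      curCodon <- paste(cur, collapse = "")
      curAA <- Biostrings::GENETIC_CODE[[curCodon]]
      if (curAA == "*" && curCodon != tab$codons[cj]) blocked[k] <- TRUE
      if (prevAA == curAA) syn <- syn + 1 else nsyn <- nsyn + 1
    }
    stats[k, ] <- c(syn, nsyn)
  }
  use <- if (all(blocked)) seq_along(paths) else which(!blocked)
  c(sd = mean(stats[use, 1L]), nd = mean(stats[use, 2L]))
}

## Memoized 64x64 lookup of pathway-averaged differences and per-codon
## site counts (stops = NA).
.ng86Tables <- function() {
  if (!is.null(.codonCache$ng86)) return(.codonCache$ng86)
  tab <- .codonTables()
  sSites <- rep(NA_real_, 64L)
  for (ci in which(!tab$isStop))
    sSites[ci] <- ng86CodonSites(tab$codons[ci])[["s"]]
  SD <- matrix(NA_real_, 64L, 64L)
  ND <- matrix(NA_real_, 64L, 64L)
  ok <- which(!tab$isStop)
  for (ci in ok) for (cj in ok) {
    dd <- .ng86DiffPair(ci, cj)
    SD[ci, cj] <- dd[["sd"]]
    ND[ci, cj] <- dd[["nd"]]
  }
  .codonCache$ng86 <- list(sSites = sSites, SD = SD, ND = ND)
  .codonCache$ng86
}
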