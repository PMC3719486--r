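## Independent oracles used by the test suite. These deliberately share
## no code with the package implementation.

## NG86 site counts by direct enumeration of the 9 single-base mutations
oracleCodonSites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  code <- Biostrings::GENETIC_CODE
  s <- 0
  for (p in 1:3) {
    syn <- 0
    valid <- 0
    for (b in bases) {
      if (b == substr(codon, p, p)) next
      mut <- codon
      substr(mut, p, p) <- b
      if (code[[mut]] == "*") next
      valid <- valid + 1
      if (code[[mut]] == code[[codon]]) syn <- syn + 1
    }
    if (valid > 0) s <- s + syn / valid
  }
  c(s = s, n = 3 - s)
}

## Pathway-averaged differences by depth-first enumeration of all orders
## in which the differing positions can be changed; paths visiting a stop
## are dropped, falling back to all paths when everything is blocked.
oracleDiffs <- function(c1, c2) {
  code <- Biostrings::GENETIC_CODE
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(sd = 0, nd = 0))
  paths <- list()
  walk <- function(cur, remaining, syn, nsyn, blocked) {
    if (!length(remaining)) {
      paths[[length(paths) + 1]] <<- c(syn, nsyn, blocked)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      isSyn <- code[[nxt]] == code[[cur]]
      nowBlocked <- blocked || (code[[nxt]] == "*" && nxt != c2)
      walk(nxt, setdiff(remaining, p), syn + isSyn, nsyn + !isSyn,
           nowBlocked)
    }
  }
  walk(c1, pos, 0, 0, FALSE)
  m <- do.call(rbind, paths)
  use <- if (all(m[, 3] == 1)) seq_len(nrow(m)) else which(m[, 3] == 0)
  c(sd = mean(m[use, 1]), nd = mean(m[use, 2]))
}

allSenseCodons <- function() {
  bases <- c("T", "C", "A", "G")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  codons[Biostrings::GENETIC_CODE[codons] != "*"]
}

## Random tree with strictly positive branch lengths and its additive
## (path-length) distance matrix.
randomAdditiveMatrix <- function(nLeaves) {
  tr <- ape::rtree(nLeaves, br = function(n) runif(n, 0.1, 2))
  list(tree = tr, d = cophenetic(tr))
}

## Random protein string over the 20 standard residues
randomProtein <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               n, replace = TRUE), collapse = "")
}
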