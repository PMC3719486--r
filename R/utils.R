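## Small internal helpers shared across modules.

## Evaluate `expr` under a temporary RNG state seeded with `seed`;
## NA seed means "use the current RNG stream".
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## All node names of a phylo (tips then internals, in index order).
nodeNames <- function(phy) {
  nl <- phy$node.label
  if (is.null(nl)) nl <- rep("", phy$Nnode)
  c(phy$tip.label, nl)
}

nodeIndex <- function(phy, name) {
  idx <- match(name, nodeNames(phy))
  if (is.na(idx)) stop("node '", name, "' not found in tree", call. = FALSE)
  idx
}

childrenOf <- function(phy, node) phy$edge[phy$edge[, 1L] == node, 2L]

parentOf <- function(phy, node) {
  p <- phy$edge[phy$edge[, 2L] == node, 1L]
  if (length(p)) p else NA_integer_
}

rootNode <- function(phy) phy$edge[1L, 1L]

## Tip indices below a node (node may itself be a tip).
tipsBelow <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(node)
  out <- integer()
  stack <- node
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    ch <- childrenOf(phy, nd)
    out <- c(out, ch[ch <= ntip])
    stack <- c(stack, ch[ch > ntip])
  }
  out
}

## Is `anc` an ancestor of (or equal to) `node`?
isAncestorOrSelf <- function(phy, anc, node) {
  while (!is.na(node)) {
    if (node == anc) return(TRUE)
    node <- parentOf(phy, node)
  }
  FALSE
}

## Edge length of the branch above `node` (into it from its parent).
branchLengthAbove <- function(phy, node) {
  i <- which(phy$edge[, 2L] == node)
  if (!length(i)) return(NA_real_)
  phy$edge.length[i]
}

## character vector of sequences -> character matrix (rows = sequences)
seqsToMatrix <- function(seqs) {
  if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names", call. = FALSE)
  n <- nchar(seqs)
  if (length(unique(n)) != 1L)
    stop("all rows must have equal length (is this an alignment?)",
         call. = FALSE)
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- names(seqs)
  m
}
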