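#' Bootstrap NJ majority-rule consensus tree with supports
#'
#' Resamples alignment columns with replacement, rebuilds a JTT-distance
#' neighbor-joining tree per replicate, and returns the majority-rule
#' consensus keeping every bipartition with frequency >= `threshold`;
#' internal node labels carry `round(100 * frequency)`.
#'
#' Distances inside replicates are JTT maximum-likelihood distances
#' evaluated on a fixed likelihood grid with parabolic refinement (see
#' [jttMlDistance()] for the exact single-pair estimator); pairwise
#' deletion of gap columns is applied within each replicate.
#'
#' @param aln named character vector of aligned protein sequences (or
#'   `AAStringSet`), >= 3 rows.
#' @param nReps number of bootstrap replicates (>= 1).
#' @param seed integer seed for the resampling.
#' @param threshold minimum bipartition frequency kept in the consensus
#'   (default 0.5, majority rule; comparison is >=).
#' @return a `phylo` with `node.label` giving supports 0-100 (the root
#'   label of the unrooted consensus is empty).
#' @export
bootstrapConsensus <- function(aln, nReps = 1000L, seed = NULL,
                               threshold = 0.5) {
  m <- seqsToMatrix(aln)
  if (nrow(m) < 3L)
    stop("need an alignment with at least 3 rows", call. = FALSE)
  if (nReps < 1L) stop("nReps must be >= 1", call. = FALSE)
  n <- nrow(m)
  L <- ncol(m)
  labels <- rownames(m)

  ## per-pair per-column states: (ia-1)*20 + ib, 0 when either has a gap
  idx <- match(m, .JTT_AA)
  dim(idx) <- dim(m)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairIdx <- matrix(0L, nrow(pairs), L)
  for (p in seq_len(nrow(pairs))) {
    ia <- idx[pairs[p, 1L], ]; ib <- idx[pairs[p, 2L], ]
    st <- (ia - 1L) * 20L + ib
    st[is.na(st)] <- 0L
    pairIdx[p, ] <- st
  }

  trees <- withSeed(seed, {
    lapply(seq_len(nReps), function(rep) {
      cols <- sample.int(L, L, replace = TRUE)
      dv <- .jttGridDistances(pairIdx, cols)
      D <- matrix(0, n, n, dimnames = list(labels, labels))
      D[cbind(pairs[, 1L], pairs[, 2L])] <- dv
      D <- D + t(D)
      neighborJoining(D)
    })
  })
  class(trees) <- "multiPhylo"

  ## ape::consensus keeps bipartitions with frequency strictly above p;
  ## shifting p by half a replicate turns that into >= threshold.
  pAdj <- max(threshold - 1 / (2 * nReps), 1e-9)
  cons <- ape::consensus(trees, p = pAdj)
  counts <- ape::prop.clades(cons, trees, rooted = FALSE)
  counts[is.na(counts)] <- nReps
  supports <- as.character(round(100 * counts / nReps))
  supports[1L] <- ""   # basal node of the unrooted consensus
  cons$node.label <- supports
  cons
}
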