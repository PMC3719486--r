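#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration. Deterministic: when several pairs
#' minimize the Q criterion the pair whose (lexicographically smallest)
#' member labels sort first is joined. Negative intermediate branch
#' lengths are clamped to zero with the deficit shifted to the sister
#' edge, so the two pendant edges of a join always sum to the original
#' within-pair distance.
#'
#' @param d symmetric numeric matrix with labels (or a `dist`), zero
#'   diagonal, >= 3 labels.
#' @return an unrooted `phylo`.
#' @examples
#' d <- matrix(c(0,3,5,6, 3,0,6,7, 5,6,0,7, 6,7,7,0), 4, 4,
#'             dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' nj <- neighborJoining(d)   # recovers the additive tree exactly
#' @export
neighborJoining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("d must be a square matrix", call. = FALSE)
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <-
      paste0("t", seq_len(nrow(d)))
  if (max(abs(d - t(d))) > 1e-8)
    stop("distance matrix is not symmetric", call. = FALSE)
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 labels", call. = FALSE)

  frag <- rownames(d)               # newick fragment per active cluster
  key <- rownames(d)                # representative (smallest) leaf label
  D <- d

  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    ## deterministic tie-break by (sorted) representative labels
    k1 <- pmin(key[cand[, 1L]], key[cand[, 2L]])
    k2 <- pmax(key[cand[, 1L]], key[cand[, 2L]])
    pick <- order(k1, k2)[1L]
    i <- cand[pick, 1L]; j <- cand[pick, 2L]

    dij <- D[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- dij - li
    if (li < 0) { li <- 0; lj <- dij }
    if (lj < 0) { lj <- 0; li <- dij }

    newFrag <- sprintf("(%s:%.12g,%s:%.12g)", frag[i], li, frag[j], lj)
    newKey <- min(key[i], key[j])
    dNew <- (D[i, ] + D[j, ] - dij) / 2
    dNew <- dNew[-c(i, j)]

    keep <- setdiff(seq_len(m), c(i, j))
    D <- D[keep, keep, drop = FALSE]
    D <- rbind(cbind(D, dNew), c(dNew, 0))
    frag <- c(frag[keep], newFrag)
    key <- c(key[keep], newKey)
    rownames(D) <- colnames(D) <- key
  }

  ## final three clusters: three-point formulas
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 frag[1], la, frag[2], lb, frag[3], lc)
  ape::read.tree(text = nwk)
}
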