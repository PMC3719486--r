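## Expression preprocessing, UPGMA clustering, category contrast, and
## sequence-clade vs expression-cluster concordance.

#' Log2-transform an expression matrix
#'
#' @param m numeric matrix (genes x samples) of positive intensities.
#' @return the log2 matrix, flagged via `attr(, "log2") = TRUE`; calling
#'   this twice is an error.
#' @export
preprocessLog2 <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("m must be a numeric matrix", call. = FALSE)
  if (isTRUE(attr(m, "log2")))
    stop("double transform: matrix is already log2 scaled", call. = FALSE)
  bad <- which(m <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("nonpositive value at gene '%s', sample '%s'",
                 rownames(m)[bad[1L, 1L]] %||% bad[1L, 1L],
                 colnames(m)[bad[1L, 2L]] %||% bad[1L, 2L]),
         call. = FALSE)
  }
  out <- log2(m)
  attr(out, "log2") <- TRUE
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' UPGMA (average linkage) clustering of expression profiles
#'
#' Agglomerates genes by average linkage on euclidean distances or on
#' correlation distance (1 - Pearson r). Merge heights follow the
#' ultrametric (phylogenetic) convention: two genes at distance d join
#' at height d/2. Ties are broken deterministically by gene label order
#' (rows are sorted before clustering).
#'
#' @param m numeric matrix, genes x samples, >= 2 genes.
#' @param metric "euclidean" or "correlation".
#' @return an `hclust` object (heights = average distance / 2) with
#'   attribute `metric`; usable with [stats::cutree()].
#' @export
upgmaCluster <- function(m, metric = c("euclidean", "correlation")) {
  metric <- match.arg(metric)
  if (!is.matrix(m) || nrow(m) < 2L)
    stop("need a matrix with at least 2 genes", call. = FALSE)
  if (is.null(rownames(m)))
    rownames(m) <- paste0("g", seq_len(nrow(m)))
  m <- m[order(rownames(m)), , drop = FALSE]
  if (metric == "euclidean") {
    d <- dist(m)
  } else {
    v <- apply(m, 1L, sd)
    if (any(v == 0))
      stop("zero-variance gene '", rownames(m)[which(v == 0)[1L]],
           "' cannot be clustered with the correlation metric",
           call. = FALSE)
    d <- as.dist(1 - cor(t(m)))
  }
  h <- hclust(d, method = "average")
  h$height <- h$height / 2
  attr(h, "metric") <- metric
  h
}

#' Two-sample contrast of per-gene mean expression between categories
#'
#' Averages each gene across samples and compares the two groups with a
#' two-sample t test (pooled variance by default, matching the classic
#' Student test; Welch by flag).
#'
#' @param m numeric matrix (genes x samples).
#' @param categories named character (gene -> group); exactly two groups
#'   after subsetting to the matrix rows, each with >= 2 genes.
#' @param welch use Welch's unequal-variance test instead of the pooled
#'   one.
#' @return list with `t`, `p`, `df`, `groupMeans` and `n`.
#' @export
groupMeanTest <- function(m, categories, welch = FALSE) {
  if (!is.matrix(m)) stop("m must be a matrix", call. = FALSE)
  cats <- categories[rownames(m)]
  if (any(is.na(cats)))
    stop("every gene in the matrix needs a category", call. = FALSE)
  lev <- if (is.factor(categories)) levels(droplevels(cats))
         else sort(unique(cats))
  if (length(lev) != 2L)
    stop("need exactly two categories, got ", length(lev), call. = FALSE)
  g1 <- rowMeans(m[cats == lev[1L], , drop = FALSE])
  g2 <- rowMeans(m[cats == lev[2L], , drop = FALSE])
  if (length(g1) < 2L || length(g2) < 2L)
    stop("each group needs >= 2 genes", call. = FALSE)
  if (sd(c(g1, g2)) == 0)
    return(list(t = 0, p = 1, df = length(g1) + length(g2) - 2,
                groupMeans = setNames(c(mean(g1), mean(g2)), lev),
                n = setNames(c(length(g1), length(g2)), lev)))
  tt <- t.test(g1, g2, var.equal = !welch)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter),
       groupMeans = setNames(c(mean(g1), mean(g2)), lev),
       n = setNames(c(length(g1), length(g2)), lev))
}

#' Concordance of sequence clades with expression clusters
#'
#' Cuts the expression dendrogram into `k` flat clusters and compares
#' that partition with the sequence-clade partition via the adjusted
#' Rand index; additionally reports, per clade, the fraction of its gene
#' pairs that land in the same expression cluster.
#'
#' @param cladeMap named character, gene -> clade id (covering the genes
#'   that were clustered).
#' @param dendro an `hclust` from [upgmaCluster()].
#' @param k number of flat clusters (2 <= k <= number of genes; default:
#'   number of distinct clades).
#' @return list with `ari` (NA with attribute `degenerate` when one of
#'   the partitions has a single class), `perClade` (named numeric) and
#'   `clusters` (the flat assignment).
#' @export
cladeCoherence <- function(cladeMap, dendro, k = NULL) {
  genes <- dendro$labels
  cl <- cladeMap[genes]
  if (any(is.na(cl)))
    stop("every clustered gene needs a clade", call. = FALSE)
  if (is.null(k)) k <- length(unique(cl))
  if (k < 2L || k > length(genes))
    stop("k must lie in [2, number of genes]", call. = FALSE)
  flat <- cutree(dendro, k = k)[genes]
  degenerate <- length(unique(cl)) < 2L
  ari <- if (degenerate) {
    structure(NA_real_, degenerate = TRUE)
  } else {
    mclust::adjustedRandIndex(cl, flat)
  }
  perClade <- vapply(unique(cl), function(cc) {
    idx <- which(cl == cc)
    if (length(idx) < 2L) return(NA_real_)
    prs <- combn(idx, 2L)
    mean(flat[prs[1L, ]] == flat[prs[2L, ]])
  }, numeric(1L))
  list(ari = ari, perClade = perClade, clusters = flat)
}
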