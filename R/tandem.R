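## Tandem-duplicate detection from gene coordinates (0-based half-open,
## BED convention) and the category/clade cross-tabulation.

.lociFrame <- function(loci) {
  if (is(loci, "GRanges")) {
    if (is.null(names(loci)))
      stop("GRanges loci must carry gene ids as names", call. = FALSE)
    df <- data.frame(gene = names(loci),
                     chrom = as.character(GenomicRanges::seqnames(loci)),
                     start = GenomicRanges::start(loci) - 1L,  # to 0-based
                     end = GenomicRanges::end(loci))
  } else {
    df <- as.data.frame(loci)
    need <- c("gene", "chrom", "start", "end")
    if (!all(need %in% names(df)))
      stop("loci need columns gene, chrom, start, end", call. = FALSE)
  }
  if (!nrow(df)) stop("empty locus list", call. = FALSE)
  if (anyDuplicated(df$gene)) stop("gene ids must be unique", call. = FALSE)
  if (any(df$start >= df$end))
    stop("loci must satisfy start < end", call. = FALSE)
  df
}

#' Detect tandem gene clusters
#'
#' Per chromosome, loci are sorted by start and adjacent genes linked
#' when the intergenic gap (next start - previous end) is strictly
#' smaller than `maxGap` (default 10 kb); chains of two or more linked
#' genes form a cluster (single linkage, so a chain is one cluster even
#' if its extremes are farther apart). Overlapping genes count as gap
#' zero; strand is ignored.
#'
#' @param loci a named `GRanges`, or a data.frame with columns `gene`,
#'   `chrom`, `start`, `end` (0-based half-open).
#' @param maxGap maximum intergenic distance in bp (strict `<`),
#'   default 10000.
#' @return list with `clusters` (list of character vectors, sorted by
#'   position) and `membership` (named integer; NA for unclustered
#'   genes).
#' @export
findTandemClusters <- function(loci, maxGap = 10000L) {
  df <- .lociFrame(loci)
  df <- df[order(df$chrom, df$start, df$gene), ]
  clusters <- list()
  membership <- setNames(rep(NA_integer_, nrow(df)), df$gene)
  for (chr in unique(df$chrom)) {
    sub <- df[df$chrom == chr, ]
    if (nrow(sub) < 2L) next
    gap <- pmax(sub$start[-1L] - sub$end[-nrow(sub)], 0L)
    linked <- gap < maxGap
    runId <- cumsum(c(0L, !linked))
    for (rid in unique(runId)) {
      genes <- sub$gene[runId == rid]
      if (length(genes) >= 2L) {
        clusters[[length(clusters) + 1L]] <- genes
        membership[genes] <- length(clusters)
      }
    }
  }
  list(clusters = clusters, membership = membership)
}

#' Tandem organization by category and clade
#'
#' For each gene category reports how many genes sit inside tandem
#' clusters and the percentage (nearest integer); additionally the
#' fraction of clustered genes whose cluster spans two or more
#' phylogenetic clades.
#'
#' @param tandem result of [findTandemClusters()].
#' @param categories named character, gene -> category; must cover every
#'   gene with a locus.
#' @param cladeMap optional named character, gene -> clade id, for the
#'   cross-clade fraction.
#' @return list with `byCategory` (data.frame: category, n, clustered,
#'   pct) and `crossCladeFraction` (NA without `cladeMap`).
#' @export
tandemStats <- function(tandem, categories, cladeMap = NULL) {
  genes <- names(tandem$membership)
  missing <- setdiff(genes, names(categories))
  if (length(missing))
    stop("gene(s) without category: ",
         paste(head(missing, 5L), collapse = ", "), call. = FALSE)
  cat <- categories[genes]
  inCluster <- !is.na(tandem$membership)
  byCat <- do.call(rbind, lapply(unique(cat), function(cc) {
    sel <- cat == cc
    data.frame(category = cc, n = sum(sel),
               clustered = sum(sel & inCluster),
               pct = round(100 * sum(sel & inCluster) / sum(sel)))
  }))
  rownames(byCat) <- NULL
  crossFrac <- NA_real_
  if (!is.null(cladeMap) && length(tandem$clusters)) {
    spans <- vapply(tandem$clusters, function(cl)
      length(unique(cladeMap[cl])), integer(1L))
    nClustered <- sum(lengths(tandem$clusters))
    crossFrac <- sum(lengths(tandem$clusters)[spans >= 2L]) / nClustered
  }
  list(byCategory = byCat, crossCladeFraction = crossFrac)
}
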