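#' Place simulated genes on synthetic chromosomes
#'
#' Genes of each species are laid out on a small set of long synthetic
#' chromosomes. Within each paralog group (same founder lineage, same
#' species) the first copy lands at a random dispersed
#' position; each further copy is placed, with probability
#' `params@tandemProb`, directly downstream of the previous copy at an
#' intergenic gap drawn uniformly from `[200, tandemMaxOffset]` bp
#' (tandem), and otherwise at a new dispersed position at least 25 kb
#' away from every gene placed so far. Runs of tandem-placed copies are
#' recorded as the true tandem clusters.
#'
#' @param truth a [SimTruth-class] from [simulateFamily()].
#' @param params a [SimParams-class].
#' @param nChrom chromosomes per species genome (default 5).
#' @param chromLength chromosome length in bp (default 3e7).
#' @param seed RNG seed; defaults to `params@seed + 2`.
#' @return list with `loci` (a named `GRanges`, 1-based, strand `+`,
#'   with metadata column `species`) and `clusters` (list of character
#'   vectors: the true tandem clusters). The updated truth (with the
#'   `tandem` slot filled) is returned as attribute `truth`.
#' @export
placeLoci <- function(truth, params, nChrom = 5L, chromLength = 3e7L,
                      seed = if (is.na(params@seed)) NA_integer_
                             else params@seed + 2L) {
  stopifnot(is(truth, "SimTruth"), is(params, "SimParams"))
  genes <- names(truth@speciesMap)
  if (!length(genes)) stop("empty family: no genes to place", call. = FALSE)
  geneLen <- 3L * params@rootLength
  ## dispersed placements keep far enough apart that even a long tandem
  ## chain grown downstream of one cannot creep into another's vicinity
  minDispersed <- 200000L

  withSeed(seed, {
    rows <- list()
    clusters <- list()
    for (sp in unique(truth@speciesMap)) {
      gs <- genes[truth@speciesMap == sp]
      occupied <- list()  # per chromosome: matrix of (start, end)
      drawDispersed <- function() {
        repeat {
          chr <- sample.int(nChrom, 1L)
          pos <- sample.int(chromLength - geneLen, 1L)
          occ <- occupied[[as.character(chr)]]
          if (is.null(occ) ||
              all(pos > occ[, 2L] + minDispersed |
                  pos + geneLen < occ[, 1L] - minDispersed))
            return(list(chr = chr, start = pos))
        }
      }
      place <- function(g, chr, start) {
        occupied[[as.character(chr)]] <<-
          rbind(occupied[[as.character(chr)]],
                c(start, start + geneLen))
        rows[[length(rows) + 1L]] <<- data.frame(
          gene = g, species = sp,
          chrom = sprintf("%s_chr%d", sp, chr),
          start = start, end = start + geneLen)
        list(chr = chr, start = start)
      }
      groups <- split(gs, truth@founders[gs])
      for (grp in groups) {
        prev <- NULL
        run <- character()
        for (g in grp) {
          tandem <- !is.null(prev) && runif(1L) < params@tandemProb
          if (tandem) {
            gap <- sample(200:params@tandemMaxOffset, 1L)
            prev <- place(g, prev$chr, prev$start + geneLen + gap)
            run <- c(run, g)
          } else {
            if (length(run) >= 2L)
              clusters[[length(clusters) + 1L]] <- run
            d <- drawDispersed()
            prev <- place(g, d$chr, d$start)
            run <- g
          }
        }
        if (length(run) >= 2L)
          clusters[[length(clusters) + 1L]] <- run
      }
    }
    df <- do.call(rbind, rows)
    gr <- GenomicRanges::GRanges(
      seqnames = df$chrom,
      ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
      strand = "+")
    names(gr) <- df$gene
    S4Vectors::mcols(gr)$species <- df$species
    truth@tandem <- clusters
    structure(list(loci = gr, clusters = clusters), truth = truth)
  })
}

#' Simulate a category-linked expression matrix
#'
#' Log2-scale values are `baseline + delta * [stable] + noise` with iid
#' Gaussian noise of SD `sigma`; optionally a clade-linked component
#' (per clade and sample, SD `cladeSd`) induces co-expression within
#' sequence clades.
#'
#' @param categories named character, gene -> category ("stable" gets
#'   the `exprDelta` offset).
#' @param params a [SimParams-class] (`exprBaseline`, `exprDelta`,
#'   `exprSigma`).
#' @param nSamples number of tissue samples (>= 2; default 120).
#' @param cladeMap optional named character (gene -> clade) enabling the
#'   clade-linked component.
#' @param cladeSd SD of the clade-linked component (default 0 = off).
#' @param seed RNG seed; defaults to `params@seed + 3`.
#' @return numeric matrix genes x samples with `attr(, "log2") = TRUE`.
#' @export
simulateExpression <- function(categories, params, nSamples = 120L,
                               cladeMap = NULL, cladeSd = 0,
                               seed = if (is.na(params@seed)) NA_integer_
                                      else params@seed + 3L) {
  stopifnot(is(params, "SimParams"))
  if (!length(categories)) stop("need at least one gene", call. = FALSE)
  if (nSamples < 2L) stop("need at least two samples", call. = FALSE)
  genes <- names(categories)
  withSeed(seed, {
    m <- matrix(rnorm(length(genes) * nSamples, sd = params@exprSigma),
                nrow = length(genes),
                dimnames = list(genes,
                                sprintf("sample%03d", seq_len(nSamples))))
    m <- m + params@exprBaseline +
      params@exprDelta * (categories == "stable")
    if (!is.null(cladeMap) && cladeSd > 0) {
      for (cl in unique(cladeMap[genes])) {
        sel <- which(cladeMap[genes] == cl)
        m[sel, ] <- m[sel, ] +
          rep(rnorm(nSamples, sd = cladeSd), each = length(sel))
      }
    }
    attr(m, "log2") <- TRUE
    m
  })
}
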