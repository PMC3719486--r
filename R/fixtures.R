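## Fixture-bundle writer and plain-text readers for the formats the
## pipeline consumes: FASTA (Biostrings), Newick (ape), BED 0-based
## half-open, TSV matrices/maps and a JSON ground-truth file.

#' Write a complete simulated fixture bundle
#'
#' Runs the full generator (family, sequences, loci, expression) from one
#' seed and writes `proteins.faa`, `cds.fna`, `genetree.nwk`,
#' `speciestree.nwk`, `loci.bed`, `expression.tsv`, `speciesmap.tsv` and
#' `truth.json` into `dir`.
#'
#' @param dir output directory (created if needed).
#' @param speciesTree rooted `phylo`; default [defaultSpeciesTree()].
#' @param params a [SimParams-class]; its seed drives everything.
#' @param nSamples expression samples (default 120).
#' @return invisibly, a list with the simulation objects and file paths.
#' @export
writeFixtureBundle <- function(dir, speciesTree = defaultSpeciesTree(),
                               params = simParams(seed = 1L),
                               nSamples = 120L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulateFamily(speciesTree, params)
  if (is.null(sim$geneTree))
    stop("family went extinct under these parameters; nothing to write",
         call. = FALSE)
  cds <- evolveSequences(sim$geneTree, params)
  prot <- translateCds(cds)
  pl <- placeLoci(sim$truth, params)
  truth <- attr(pl, "truth")
  cats <- trueCategories(truth)
  expr <- simulateExpression(cats, params, nSamples = nSamples)

  paths <- list(
    proteins = file.path(dir, "proteins.faa"),
    cds = file.path(dir, "cds.fna"),
    geneTree = file.path(dir, "genetree.nwk"),
    speciesTree = file.path(dir, "speciestree.nwk"),
    loci = file.path(dir, "loci.bed"),
    expression = file.path(dir, "expression.tsv"),
    speciesMap = file.path(dir, "speciesmap.tsv"),
    truth = file.path(dir, "truth.json"))

  Biostrings::writeXStringSet(Biostrings::AAStringSet(prot),
                              paths$proteins)
  Biostrings::writeXStringSet(cds, paths$cds)
  ape::write.tree(sim$geneTree, file = paths$geneTree)
  ape::write.tree(speciesTree, file = paths$speciesTree)
  writeLociBed(pl$loci, paths$loci)
  writeExpressionTsv(expr, paths$expression)
  write.table(data.frame(gene = names(truth@speciesMap),
                         species = unname(truth@speciesMap)),
              paths$speciesMap, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(
    refNode = truth@refNode,
    events = truth@events,
    branchCounts = truth@branchCounts,
    founders = as.list(truth@founders),
    eventClades = as.list(truth@eventClades),
    categories = as.list(cats),
    tandemClusters = truth@tandem,
    regions = truth@regions), paths$truth, auto_unbox = TRUE,
    digits = NA, pretty = TRUE)

  invisible(list(sim = sim, truth = truth, cds = cds, proteins = prot,
                 loci = pl$loci, expression = expr, paths = paths))
}

#' Plain-text readers and writers for the bundle formats
#'
#' BED files are 0-based half-open with columns chrom, start, end, name,
#' score, strand; expression matrices are TSV with a `gene` column
#' followed by one column per sample; species maps are two-column TSV
#' (gene, species).
#'
#' @param path file path.
#' @param gr,m objects to write (named `GRanges`; numeric matrix).
#' @name bundle-io
NULL

#' @rdname bundle-io
#' @export
writeLociBed <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = names(gr), score = 0L,
                   strand = as.character(GenomicRanges::strand(gr)))
  df$strand[df$strand == "*"] <- "+"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname bundle-io
#' @export
readLociBed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "name",
                                 "score", "strand")[1:6],
                   fill = TRUE, stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = ifelse(is.na(df$strand) | df$strand == "", "*", df$strand))
  names(gr) <- df$name
  gr
}

#' @rdname bundle-io
#' @export
writeExpressionTsv <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname bundle-io
#' @export
readExpressionTsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' @rdname bundle-io
#' @export
readSpeciesMap <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  setNames(df[[2L]], df[[1L]])
}
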