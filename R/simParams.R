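#' Construct simulation parameters
#'
#' Defaults describe a moderately expanding plant gene family: baseline
#' duplication rate 0.3 and loss rate 0.1 events per gene per unit branch
#' length, transition bias kappa = 2, a 200-codon CDS with a purifying
#' N-terminal domain (F-box-like, codons 11-60, omega 0.1) and a
#' diversifying C-terminal interaction domain (FBA-like, codons 101-190,
#' omega 1.5) over a background omega of 0.4, tandem placement of 35% of
#' duplicates within 9 kb, and log2 expression with baseline 6, a +2
#' offset for stable genes and unit noise.
#'
#' @param lambda,mu duplication / loss rates; a single unnamed value is
#'   global, additional named elements override per species-tree branch
#'   (named by child node).
#' @param waves data.frame (`branch`, `mult`, `from`, `to`); within the
#'   `[from, to]` fraction of `branch` the duplication rate is multiplied
#'   by `mult`.
#' @param kappa transition/transversion rate ratio.
#' @param omegaBackground dN/dS outside the declared regions.
#' @param regions data.frame (`name`, `start`, `end`, `omega`), codon
#'   intervals.
#' @param rootLength CDS length in codons.
#' @param tandemProb probability that a duplicate is tandem-placed.
#' @param tandemMaxOffset largest tandem intergenic gap (bp).
#' @param exprBaseline,exprDelta,exprSigma expression model (log2 scale).
#' @param seed master seed (integer or NA).
#' @return a [SimParams-class].
#' @export
simParams <- function(lambda = 0.3, mu = 0.1,
                      waves = data.frame(branch = character(),
                                         mult = numeric(),
                                         from = numeric(),
                                         to = numeric()),
                      kappa = 2,
                      omegaBackground = 0.4,
                      regions = data.frame(
                        name = c("F-box", "FBA-D"),
                        start = c(11L, 101L), end = c(60L, 190L),
                        omega = c(0.1, 1.5)),
                      rootLength = 200L,
                      tandemProb = 0.35, tandemMaxOffset = 9000L,
                      exprBaseline = 6, exprDelta = 2, exprSigma = 1,
                      seed = NA_integer_) {
  new("SimParams", lambda = lambda, mu = mu, waves = waves,
      kappa = kappa, omegaBackground = omegaBackground,
      regions = regions, rootLength = as.integer(rootLength),
      tandemProb = tandemProb,
      tandemMaxOffset = as.integer(tandemMaxOffset),
      exprBaseline = exprBaseline, exprDelta = exprDelta,
      exprSigma = exprSigma, seed = as.integer(seed))
}

## per-branch rate lookup: unnamed element = global default
.branchRate <- function(rates, branch) {
  if (!is.null(names(rates)) && branch %in% names(rates))
    return(unname(rates[[branch]]))
  unnamed <- if (is.null(names(rates))) rates else rates[names(rates) == ""]
  if (length(unnamed)) unname(unnamed[[1L]]) else 0
}
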