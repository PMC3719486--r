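#' Reciprocal-best-hit ortholog pairing by global alignment
#'
#' Scores every cross pair of two protein sets by exact global
#' (Needleman-Wunsch) alignment with BLOSUM62 and affine gap penalties
#' (open 11, extend 1) and keeps a pair exactly when each sequence is the
#' other's maximal-score hit. Score ties are broken by lexicographic gene
#' id and the resulting pairs flagged.
#'
#' @param setA,setB named character vectors or `AAStringSet`s (non-empty).
#' @return data.frame with columns `geneA`, `geneB`, `score`, `tie`.
#' @export
reciprocalBestHits <- function(setA, setB) {
  toSet <- function(x, what) {
    if (is.character(x)) x <- Biostrings::AAStringSet(x)
    if (!length(x)) stop(what, " is empty", call. = FALSE)
    if (is.null(names(x)) || anyDuplicated(names(x)))
      stop(what, " needs unique sequence names", call. = FALSE)
    x
  }
  setA <- toSet(setA, "setA")
  setB <- toSet(setB, "setB")
  data("BLOSUM62", package = "Biostrings", envir = environment())
  scores <- matrix(NA_real_, length(setA), length(setB),
                   dimnames = list(names(setA), names(setB)))
  for (i in seq_along(setA)) {
    scores[i, ] <- Biostrings::pairwiseAlignment(
      pattern = setB, subject = setA[[i]], type = "global",
      substitutionMatrix = get("BLOSUM62"),
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
  }
  ## best hit with lexicographic tie-break; remember whether it was a tie
  bestOf <- function(v) {
    mx <- max(v)
    hits <- sort(names(v)[v >= mx - 1e-9])
    list(id = hits[[1L]], tie = length(hits) > 1L)
  }
  bestB <- apply(scores, 1L, bestOf)
  bestA <- apply(scores, 2L, bestOf)
  out <- data.frame(geneA = character(), geneB = character(),
                    score = numeric(), tie = logical())
  for (a in names(setA)) {
    b <- bestB[[a]]$id
    if (bestA[[b]]$id == a) {
      out <- rbind(out, data.frame(
        geneA = a, geneB = b, score = scores[a, b],
        tie = bestB[[a]]$tie || bestA[[b]]$tie))
    }
  }
  rownames(out) <- NULL
  out
}
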