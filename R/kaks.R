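## NG86 pairwise Ka/Ks with Jukes-Cantor correction, sliding windows,
## domain restriction and the group contrast used for the stable vs
## unstable comparison.

.jc <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

## Split two CDS strings into comparable codon index pairs, applying
## pairwise codon deletion of gap/ambiguous codons and dropping an
## aligned terminal stop.
.codonPairs <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (nchar(a) != nchar(b))
    stop("sequences must have equal aligned length", call. = FALSE)
  L <- nchar(a)
  if (L %% 3L != 0L)
    stop("alignment length must be divisible by 3", call. = FALSE)
  starts <- seq(1L, L, by = 3L)
  ca <- substring(a, starts, starts + 2L)
  cb <- substring(b, starts, starts + 2L)
  clean <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  ia <- ifelse(clean, .codonIndex(ca), NA_integer_)
  ib <- ifelse(clean, .codonIndex(cb), NA_integer_)
  tab <- .codonTables()
  stopRow <- which(clean & (tab$isStop[ia] | tab$isStop[ib]))
  if (length(stopRow)) {
    if (length(stopRow) == 1L && stopRow == length(starts)) {
      clean[stopRow] <- FALSE   # aligned terminal stop: drop
    } else {
      stop("in-frame stop codon at codon ", stopRow[1L], call. = FALSE)
    }
  }
  keep <- which(clean)
  list(ia = ia[keep], ib = ib[keep], dropped = sum(!clean))
}

#' Pairwise Ka/Ks by NG86 counting with Jukes-Cantor correction
#'
#' Synonymous/nonsynonymous sites are counted per codon (stop-creating
#' changes excluded from the denominators) and averaged between the two
#' sequences; differences are counted over all orderings of the minimal
#' mutation path between each codon pair, excluding paths through stop
#' codons (averaging over all paths if every ordering is blocked).
#' Proportions are corrected with d = -(3/4) log(1 - 4p/3); p >= 3/4
#' flags saturation. Codons containing a gap or ambiguous base in either
#' row are deleted pairwise before counting.
#'
#' @param a,b aligned CDS rows (character or `DNAString`-coercible),
#'   equal length divisible by 3.
#' @return a [KaKsResult-class].
#' @examples
#' r <- kaksPair("TTT", "TTA")   # Sd=0 Nd=1, Ka ~ 0.5716, Ks = 0
#' kaksRatio(r)                  # NA, flag "infinite"
#' @export
kaksPair <- function(a, b) {
  cp <- .codonPairs(a, b)
  if (!length(cp$ia))
    stop("no comparable codons after pairwise deletion", call. = FALSE)
  ng <- .ng86Tables()
  sA <- sum(ng$sSites[cp$ia]); sB <- sum(ng$sSites[cp$ib])
  nc <- length(cp$ia)
  sSites <- (sA + sB) / 2
  nSites <- 3 * nc - sSites
  sd <- sum(ng$SD[cbind(cp$ia, cp$ib)])
  nd <- sum(ng$ND[cbind(cp$ia, cp$ib)])
  pS <- if (sSites > 0) sd / sSites else NA_real_
  pN <- if (nSites > 0) nd / nSites else NA_real_
  ks <- .jc(pS); ka <- .jc(pN)
  saturated <- (!is.na(pS) && pS >= 0.75) || (!is.na(pN) && pN >= 0.75)
  if (saturated) {
    flag <- "saturated"; ratio <- NA_real_
  } else if (is.na(ks) || ks == 0) {
    if (is.na(ka) || ka == 0) { flag <- "undefined"; ratio <- NA_real_ }
    else { flag <- "infinite"; ratio <- NA_real_ }
  } else {
    flag <- "ok"; ratio <- ka / ks
  }
  new("KaKsResult", nCodons = nc, sSites = sSites, nSites = nSites,
      sDiff = sd, nDiff = nd, pS = pS, pN = pN,
      ks = ks, ka = ka, ratio = ratio, flag = flag)
}

.resultRow <- function(r) {
  data.frame(nCodons = r@nCodons, sSites = r@sSites, nSites = r@nSites,
             sDiff = r@sDiff, nDiff = r@nDiff, pS = r@pS, pN = r@pN,
             ka = r@ka, ks = r@ks, ratio = r@ratio, flag = r@flag)
}

#' Sliding-window Ka/Ks profile
#'
#' Applies [kaksPair()] to successive windows along a pairwise codon
#' alignment; coordinates are 1-based inclusive bp in alignment
#' coordinates, midpoints `(start + end)/2`.
#'
#' @param a,b aligned CDS rows.
#' @param window,step window and step size in bp, both multiples of 3
#'   (defaults 150 and 9).
#' @return a [KaKsProfile-class] with `floor((L - window)/step) + 1` rows.
#' @export
slidingWindowKaKs <- function(a, b, window = 150L, step = 9L) {
  a <- as.character(a); b <- as.character(b)
  window <- as.integer(window); step <- as.integer(step)
  if (window %% 3L != 0L || step %% 3L != 0L)
    stop("window and step must be multiples of 3", call. = FALSE)
  L <- nchar(a)
  if (nchar(b) != L)
    stop("sequences must have equal aligned length", call. = FALSE)
  if (L < window) stop("alignment shorter than one window", call. = FALSE)
  starts <- seq(1L, L - window + 1L, by = step)
  rows <- lapply(starts, function(s) {
    r <- kaksPair(substr(a, s, s + window - 1L),
                  substr(b, s, s + window - 1L))
    cbind(data.frame(start = s, midpoint = s + (window - 1) / 2,
                     end = s + window - 1L), .resultRow(r))
  })
  new("KaKsProfile", windows = do.call(rbind, rows),
      windowSize = window, stepSize = step, alignmentLength = as.integer(L))
}

#' Ka/Ks restricted to a codon region
#'
#' @param a,b aligned CDS rows.
#' @param startCodon,endCodon 1-based inclusive codon interval.
#' @return a [KaKsResult-class].
#' @export
regionKaKs <- function(a, b, startCodon, endCodon) {
  a <- as.character(a); b <- as.character(b)
  L <- nchar(a) %/% 3L
  if (startCodon > endCodon || startCodon < 1L)
    stop("empty or invalid region", call. = FALSE)
  if (endCodon > L) stop("region exceeds the alignment", call. = FALSE)
  from <- 3L * (startCodon - 1L) + 1L
  to <- 3L * endCodon
  kaksPair(substr(a, from, to), substr(b, from, to))
}

#' Kruskal-Wallis contrast of Ka/Ks ratio groups
#'
#' Rank-based H test (with tie correction, chi-square approximation,
#' df = k - 1) across two or more groups of Ka/Ks ratios; undefined
#' ratios (NA) are excluded with a logged count. Groups that are
#' completely tied across the board yield H = 0, p = 1.
#'
#' @param groups list (>= 2) of numeric vectors of ratios.
#' @return list with `H`, `p`, `excluded` (number of NA ratios dropped),
#'   and `n` per group.
#' @examples
#' kaksGroupTest(list(stable = c(1, 2, 3), unstable = c(4, 5, 6)))$H
#' # 3.857...
#' @export
kaksGroupTest <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of >= 2 groups", call. = FALSE)
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(names(groups), lengths(groups)),
                levels = names(groups))
  keep <- !is.na(values)
  excluded <- sum(!keep)
  if (excluded)
    message(excluded, " undefined ratio(s) excluded from the test")
  values <- values[keep]; grp <- droplevels(grp[keep])
  if (length(values) < 3L || nlevels(grp) < 2L)
    stop("fewer than 3 usable values or fewer than 2 non-empty groups",
         call. = FALSE)
  if (length(unique(values)) == 1L)
    return(list(H = 0, p = 1, excluded = excluded,
                n = as.integer(table(grp))))
  kt <- kruskal.test(values, grp)
  list(H = unname(kt$statistic), p = kt$p.value, excluded = excluded,
       n = as.integer(table(grp)))
}
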