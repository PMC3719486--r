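#' @rdname CladeAssignment-class
#' @param object,x an object.
#' @export
setGeneric("categories", function(x) standardGeneric("categories"))

#' @rdname CladeAssignment-class
#' @export
setGeneric("cladeList", function(x) standardGeneric("cladeList"))

#' @rdname CladeAssignment-class
#' @export
setGeneric("cladeSupports", function(x) standardGeneric("cladeSupports"))

#' @rdname CladeAssignment-class
#' @export
setGeneric("singletonGenes", function(x) standardGeneric("singletonGenes"))

#' @rdname FamilyHistory-class
#' @export
setGeneric("nodeCounts", function(x) standardGeneric("nodeCounts"))

#' @rdname FamilyHistory-class
#' @export
setGeneric("branchGains", function(x) standardGeneric("branchGains"))

#' @rdname FamilyHistory-class
#' @export
setGeneric("branchLosses", function(x) standardGeneric("branchLosses"))

#' @rdname FamilyHistory-class
#' @export
setGeneric("cladeOrigins", function(x) standardGeneric("cladeOrigins"))

#' @rdname KaKsProfile-class
#' @export
setGeneric("profileWindows", function(x) standardGeneric("profileWindows"))

#' @rdname KaKsResult-class
#' @export
setGeneric("kaksRatio", function(x) standardGeneric("kaksRatio"))

#' @rdname SimTruth-class
#' @export
setGeneric("speciesMap", function(x) standardGeneric("speciesMap"))

#' @rdname SimTruth-class
#' @export
setGeneric("trueCategories", function(x) standardGeneric("trueCategories"))

## ---- accessors -------------------------------------------------------

#' @rdname CladeAssignment-class
#' @export
setMethod("categories", "CladeAssignment", function(x) x@categories)

#' @rdname CladeAssignment-class
#' @export
setMethod("cladeList", "CladeAssignment", function(x) x@clades)

#' @rdname CladeAssignment-class
#' @export
setMethod("cladeSupports", "CladeAssignment", function(x) x@supports)

#' @rdname CladeAssignment-class
#' @export
setMethod("singletonGenes", "CladeAssignment", function(x) x@singletons)

#' @rdname FamilyHistory-class
#' @export
setMethod("nodeCounts", "FamilyHistory", function(x) x@nodeCounts)

#' @rdname FamilyHistory-class
#' @export
setMethod("branchGains", "FamilyHistory", function(x) x@gains)

#' @rdname FamilyHistory-class
#' @export
setMethod("branchLosses", "FamilyHistory", function(x) x@losses)

#' @rdname FamilyHistory-class
#' @export
setMethod("cladeOrigins", "FamilyHistory", function(x) x@origins)

#' @rdname KaKsProfile-class
#' @export
setMethod("profileWindows", "KaKsProfile", function(x) x@windows)

#' @rdname KaKsResult-class
#' @export
setMethod("kaksRatio", "KaKsResult", function(x) x@ratio)

#' @rdname SimTruth-class
#' @export
setMethod("speciesMap", "SimTruth", function(x) x@speciesMap)

## ---- show ------------------------------------------------------------

setMethod("show", "SimParams", function(object) {
  cat("SimParams: lambda", paste(signif(object@lambda, 3), collapse = "/"),
      " mu", paste(signif(object@mu, 3), collapse = "/"),
      " kappa", object@kappa, "\n")
  cat("  CDS", object@rootLength, "codons; background omega",
      object@omegaBackground, "\n")
  if (nrow(object@regions))
    cat("  regions:", paste(sprintf("%s[%d-%d] omega=%g",
        object@regions$name, object@regions$start, object@regions$end,
        object@regions$omega), collapse = ", "), "\n")
  if (nrow(object@waves))
    cat("  waves on:", paste(unique(object@waves$branch), collapse = ", "),
        "\n")
  cat("  tandemProb", object@tandemProb, "; exprDelta", object@exprDelta,
      "sigma", object@exprSigma, "; seed",
      ifelse(is.na(object@seed), "unset", object@seed), "\n")
})

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", length(object@speciesMap), "extant genes in",
      length(unique(object@speciesMap)), "species;",
      sum(object@events$type == "duplication"), "duplications,",
      sum(object@events$type == "loss"), "losses\n")
  if (length(object@founders)) {
    tc <- table(trueCategories(object))
    cat("  true categories:",
        paste(names(tc), as.integer(tc), collapse = ", ", sep = "="), "\n")
  }
})

setMethod("show", "CladeAssignment", function(object) {
  cat("CladeAssignment:", length(object@clades), "supported clades (>",
      object@minSupport, "support),", length(object@singletons),
      "singletons\n")
  if (length(object@categories)) {
    tc <- table(object@categories)
    cat("  categories:",
        paste(names(tc), as.integer(tc), collapse = ", ", sep = "="), "\n")
  }
})

setMethod("show", "FamilyHistory", function(object) {
  cat("FamilyHistory on", length(object@nodeCounts), "species-tree nodes;",
      length(object@origins), "clades\n")
  cat("  total gains", sum(object@gains), "; total losses",
      sum(object@losses), "\n")
})

setMethod("show", "KaKsResult", function(object) {
  cat(sprintf(
    "KaKsResult: %d codons; Ka=%s Ks=%s ratio=%s [%s]\n",
    object@nCodons, format(object@ka, digits = 4),
    format(object@ks, digits = 4), format(object@ratio, digits = 4),
    object@flag))
})

setMethod("show", "KaKsProfile", function(object) {
  cat("KaKsProfile:", nrow(object@windows), "windows of",
      object@windowSize, "bp, step", object@stepSize, "bp over",
      object@alignmentLength, "bp\n")
})
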