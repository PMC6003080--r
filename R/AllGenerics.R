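#' @title Accessors for taxhfe classes
#' @name accessors
#' @rdname accessors
#'
#' @description Small accessor generics so user code never touches slots:
#' `sampleIds()` and `featureIds()` return the row/column identifiers of
#' an [AbundanceTable-class], `abundances()` its numeric matrix and
#' `isNormalized()` its normalization flag; `otuIds()`, `nOtus()` and
#' `nInternalNodes()` describe a [TaxonomyTree-class]; `selectedFeatures()`,
#' `igScores()` and `discardCounts()` unpack an [HFEResult-class];
#' `foldAssignments()` returns a [FoldPlan-class]'s sample-to-fold map.
#'
#' @param x an object of the documented class.
#' @keywords internal
NULL

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))
#' @rdname accessors
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))
#' @rdname accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))
#' @rdname accessors
#' @export
setGeneric("otuIds", function(x) standardGeneric("otuIds"))
#' @rdname accessors
#' @export
setGeneric("nOtus", function(x) standardGeneric("nOtus"))
#' @rdname accessors
#' @export
setGeneric("nInternalNodes", function(x) standardGeneric("nInternalNodes"))
#' @rdname accessors
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))
#' @rdname accessors
#' @export
setGeneric("igScores", function(x) standardGeneric("igScores"))
#' @rdname accessors
#' @export
setGeneric("discardCounts", function(x) standardGeneric("discardCounts"))
#' @rdname accessors
#' @export
setGeneric("foldAssignments", function(x) standardGeneric("foldAssignments"))

#' @rdname accessors
setMethod("sampleIds", "AbundanceTable", function(x) rownames(x@values))
#' @rdname accessors
setMethod("featureIds", "AbundanceTable", function(x) colnames(x@values))
#' @rdname accessors
setMethod("abundances", "AbundanceTable", function(x) x@values)
#' @rdname accessors
setMethod("isNormalized", "AbundanceTable", function(x) x@normalized)

#' @rdname accessors
setMethod("otuIds", "TaxonomyTree", function(x) x@otus$otu)
#' @rdname accessors
setMethod("nOtus", "TaxonomyTree", function(x) nrow(x@otus))
#' @rdname accessors
setMethod("nInternalNodes", "TaxonomyTree", function(x) nrow(x@nodes))

#' @rdname accessors
setMethod("selectedFeatures", "HFEResult", function(x) x@selected)
#' @rdname accessors
setMethod("igScores", "HFEResult", function(x) x@igScores)
#' @rdname accessors
setMethod("discardCounts", "HFEResult",
          function(x) c(s1 = x@s1, s2 = x@s2, s3 = x@s3))

#' @rdname accessors
setMethod("foldAssignments", "FoldPlan", function(x) x@assignments)

setMethod("show", "TaxonomyTree", function(object) {
  rk <- table(factor(object@nodes$rank, levels = TAX_RANKS[1:7]))
  cat("TaxonomyTree:", nrow(object@otus), "OTUs,",
      nrow(object@nodes), "internal taxa\n")
  cat("  per rank:", paste(names(rk), rk, sep = "=", collapse = " "), "\n")
  cat("  leaves in incomplete paths:", sum(!object@otus$complete), "\n")
})

setMethod("show", "AbundanceTable", function(object) {
  cat("AbundanceTable:", nrow(object@values), "samples x",
      ncol(object@values), "features",
      if (object@normalized) "(relative abundances)" else "(raw)", "\n")
})

setMethod("show", "HFEResult", function(object) {
  cat("HFEResult: ", length(object@selected), " features selected from m + m' = ",
      object@m, " + ", object@mPrime, "\n", sep = "")
  cat("  discards: s1 =", object@s1, "(correlation), s2 =", object@s2,
      "(path IG), s3 =", object@s3, "(incomplete-leaf IG)\n")
  cat("  theta =", object@theta, "; phase-3 averaging:", object@phase3Average, "\n")
  top <- utils::head(sort(object@igScores[object@selected], decreasing = TRUE), 5)
  if (length(top))
    cat("  top IG:", paste(names(top), sprintf("(%.3f)", top), collapse = " "), "\n")
})

setMethod("show", "FoldPlan", function(object) {
  cat("FoldPlan:", object@k, "folds over", length(object@assignments),
      "samples (seed", object@seed,
      if (object@stratified) "stratified)" else ")", "\n")
})

setMethod("show", "EvaluationReport", function(object) {
  m <- object@metrics
  cat("EvaluationReport:", nrow(m), "folds, classifier =", object@classifier,
      if (object@baseline) "[baseline mode]" else "", "\n")
  for (col in c("auc", "precision", "recall", "f"))
    cat(sprintf("  %-9s %.3f +/- %.3f\n", col, mean(m[[col]]),
                stats::sd(m[[col]])))
  cat(sprintf("  features  %.1f +/- %.1f (intersection %d)\n",
              mean(m$nFeatures), stats::sd(m$nFeatures),
              length(featureIntersection(object@selections))))
})
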