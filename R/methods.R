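#' @include calibrate.R io.R
NULL

#' @describeIn CometFit-class long-format results table.
#' @param object,x a fitted object.
#' @param ... unused.
#' @export
setMethod("resultsTable", "CometFit", function(object, ...) object@results)

#' @describeIn CometFit-class binary association-call matrix.
#' @export
setMethod("associationCalls", "CometFit", function(object) object@calls)

#' @describeIn CometFit-class per-trait marginal fits.
#' @export
setMethod("marginalFits", "CometFit", function(object) object@marginalFits)

#' @describeIn CometFit-class overlap-model fit.
#' @export
setMethod("overlapFit", "CometFit", function(object) object@overlapFit)

#' @describeIn CometFit-class categories excluded from the final overlap
#'   model for containing no overlap SNPs.
#' @export
setMethod("excludedCovariates", "CometFit",
          function(object) object@overlapFit@excludedCovariates)

#' @describeIn OverlapFit-class excluded categories.
#' @param object an [OverlapFit-class].
#' @export
setMethod("excludedCovariates", "OverlapFit",
          function(object) object@excludedCovariates)

#' @describeIn MarginalFit-class per-category associated-SNP counts.
#' @param object a [MarginalFit-class].
#' @export
setMethod("enrichmentCounts", "MarginalFit", function(object) object@counts)

#' @describeIn OverlapFit-class per-category overlap-SNP counts.
#' @export
setMethod("enrichmentCounts", "OverlapFit", function(object) object@counts)

#' @describeIn CalibrationResult-class rejection-rate summary, optionally
#'   filtered by method.
#' @param object a [CalibrationResult-class].
#' @param method optional method filter.
#' @export
setMethod("rejectionRates", "CalibrationResult",
  function(object, method = NULL) {
    s <- object@summary
    if (!is.null(method)) s <- s[s$method == method, , drop = FALSE]
    s
  })

#' @describeIn MarginalFit-class model coefficients.
#' @export
setMethod("coef", "MarginalFit", function(object, ...) object@coef)

#' @describeIn OverlapFit-class model coefficients.
#' @export
setMethod("coef", "OverlapFit", function(object, ...) object@coef)

#' @export
setMethod("show", "BFDecisionRule", function(object) {
  cat(sprintf(paste0("BFDecisionRule: log10(ABF) > %.3f ",
                     "(costRatio = %g, priorNull = %g, priorSd = %g)\n"),
              object@log10Threshold, object@costRatio, object@priorNull,
              object@priorSd))
})

#' @export
setMethod("show", "MarginalFit", function(object) {
  cat("MarginalFit for trait '", object@traitId, "': ",
      length(object@fitted), " SNPs, ", object@nAssoc,
      " called associated\n", sep = "")
  print(round(rbind(estimate = object@coef, se = object@se,
                    p_one_sided = object@pOneSided), 4))
})

#' @export
setMethod("show", "OverlapFit", function(object) {
  cat("OverlapFit (", object@varMethod, " SEs): ", object@nOverlap,
      " overlap SNPs\n", sep = "")
  if (length(object@excludedCovariates))
    cat("excluded (no overlap SNPs): ",
        paste(object@excludedCovariates, collapse = ", "), "\n", sep = "")
  print(round(rbind(estimate = object@coef, se = object@se,
                    p_one_sided = object@pOneSided), 4))
})

#' @export
setMethod("show", "CometFit", function(object) {
  cat("CometFit: ", object@nSNPs, " SNPs, traits ",
      paste(object@traits, collapse = ", "), "\n", sep = "")
  if (length(object@droppedCategories))
    cat("small-category guard removed: ",
        paste(object@droppedCategories, collapse = ", "), "\n", sep = "")
  print(object@results, digits = 4)
})

#' @export
setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: m = ", object@m, ", ", object@studyType,
      " studies N1 = ", object@N1, ", N2 = ", object@N2, "\n",
      "  p1 = ", object@p1, ", p2 = ", object@p2, ", p12 = ", object@p12,
      "\n", sep = "")
  if (!is.na(object@enrichedCategory))
    cat("  enriched: ", object@enrichedCategory, " at p12' = ",
        nullP12Prime(object), "\n", sep = "")
  cat("  categories: ",
      paste(sprintf("%s=%.2g%%", names(object@categoryProps),
                    100 * object@categoryProps), collapse = ", "),
      "\n", sep = "")
})

#' @export
setMethod("show", "StudyPair", function(object) {
  cat("StudyPair: ", object@config@m, " SNPs x ",
      length(object@stats), " traits; ",
      sum(object@truth$shared), " shared-causal SNPs\n", sep = "")
})

#' @export
setMethod("show", "CalibrationResult", function(object) {
  cat("CalibrationResult: ", object@nReps, " replicates, alpha = ",
      object@alpha, "\n", sep = "")
  print(object@summary, digits = 3)
})
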