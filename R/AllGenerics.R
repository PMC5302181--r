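#' @include AllClasses.R
NULL

#' Classify SNP-trait associations under a decision rule
#'
#' @param stats a summary-statistic \code{data.frame} (columns \code{snp},
#'   \code{beta}, \code{se}) or a named list of such data frames, one per
#'   trait.
#' @param rule a [BFDecisionRule-class] or [PValueDecisionRule-class].
#' @param ... passed to methods.
#' @return a long-format \code{data.frame} of association calls with columns
#'   \code{snp}, \code{trait}, \code{statistic} (log10 ABF, or the two-sided
#'   p-value for a p-value rule) and the binary verdict \code{y}.
#' @export
setGeneric("classifyAssociations",
           function(stats, rule, ...) standardGeneric("classifyAssociations"))

#' Long-format results table of a fitted analysis
#' @param object a [CometFit-class].
#' @param ... unused.
#' @return \code{data.frame} with columns \code{model}, \code{term},
#'   \code{estimate}, \code{se}, \code{z}, \code{p_one_sided},
#'   \code{p_two_sided}, \code{count}.
#' @export
setGeneric("resultsTable", function(object, ...) standardGeneric("resultsTable"))

#' Binary association-call matrix of a fitted analysis
#' @param object a [CometFit-class].
#' @return m x R binary matrix (SNPs x traits).
#' @export
setGeneric("associationCalls",
           function(object) standardGeneric("associationCalls"))

#' Per-trait marginal fits of a fitted analysis
#' @param object a [CometFit-class].
#' @return named list of [MarginalFit-class] objects.
#' @export
setGeneric("marginalFits", function(object) standardGeneric("marginalFits"))

#' Overlap-model fit of a fitted analysis
#' @param object a [CometFit-class].
#' @return an [OverlapFit-class].
#' @export
setGeneric("overlapFit", function(object) standardGeneric("overlapFit"))

#' Covariates excluded from a model
#' @param object an [OverlapFit-class] or [CometFit-class].
#' @return character vector of category labels removed because they contained
#'   no overlap-positive SNPs.
#' @export
setGeneric("excludedCovariates",
           function(object) standardGeneric("excludedCovariates"))

#' Per-category counts of positive SNPs in a fitted model
#' @param object a [MarginalFit-class], [OverlapFit-class] or
#'   [CometFit-class].
#' @return named numeric vector of counts.
#' @export
setGeneric("enrichmentCounts",
           function(object) standardGeneric("enrichmentCounts"))

#' Rejection-rate summary of a calibration run
#' @param object a [CalibrationResult-class].
#' @param method optional filter, \code{"comet"} or \code{"hypergeometric"}.
#' @return the summary \code{data.frame} (method, covariate, nReps, rate,
#'   Wilson CI bounds, inflation factors).
#' @export
setGeneric("rejectionRates",
           function(object, method = NULL) standardGeneric("rejectionRates"))
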