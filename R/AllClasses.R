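#' @import methods
NULL

#' Bayes-factor decision rule for declaring association
#'
#' Encodes the Bayesian decision criterion used to turn a per-SNP, per-trait
#' approximate Bayes factor (ABF) into a binary association verdict: a SNP is
#' declared associated when \code{log10(ABF)} strictly exceeds
#' \code{log10Threshold = log10(priorNull / ((1 - priorNull) * costRatio))}.
#' With the defaults (cost ratio 20, prior null probability 0.99) the bound is
#' 0.695, roughly equivalent to a p-value threshold of 0.004--0.01 depending on
#' study size.
#'
#' @slot costRatio positive cost ratio of false positives to false negatives.
#' @slot priorNull prior probability that a SNP is null, in (0, 1).
#' @slot log10Threshold derived decision bound on the log10 ABF scale.
#' @slot priorSd standard deviation of the normal effect-size prior used in
#'   the ABF, on the log-odds-ratio / standardized-beta scale. The default
#'   0.3 makes the 0.695 bound correspond to a per-SNP p-value threshold of
#'   roughly 0.004--0.01 across case-control studies of 3000--20,000 cases.
#'
#' @seealso [bfDecisionRule()], [decisionThreshold()], [classifyAssociations()]
#' @exportClass BFDecisionRule
setClass("BFDecisionRule",
         slots = c(costRatio = "numeric", priorNull = "numeric",
                   log10Threshold = "numeric", priorSd = "numeric"))

setValidity("BFDecisionRule", function(object) {
  msg <- character()
  if (length(object@costRatio) != 1L || !is.finite(object@costRatio) ||
      object@costRatio <= 0)
    msg <- c(msg, "'costRatio' must be a single positive number")
  if (length(object@priorNull) != 1L || !is.finite(object@priorNull) ||
      object@priorNull <= 0 || object@priorNull >= 1)
    msg <- c(msg, "'priorNull' must lie strictly between 0 and 1")
  if (length(object@priorSd) != 1L || !is.finite(object@priorSd) ||
      object@priorSd < 0)
    msg <- c(msg, "'priorSd' must be a single non-negative number")
  if (length(msg) == 0L) {
    want <- log10(object@priorNull /
                    ((1 - object@priorNull) * object@costRatio))
    if (abs(object@log10Threshold - want) > 1e-12)
      msg <- c(msg, "'log10Threshold' does not match costRatio and priorNull")
  }
  if (length(msg)) msg else TRUE
})

#' P-value decision rule (alternative classifier)
#'
#' Alternative to [BFDecisionRule-class]: declares association when the Wald
#' two-sided p-value computed from beta/se falls below \code{alpha}. Off by
#' default throughout the package; provided because BF thresholds correspond
#' to study-size-dependent p-value thresholds and some users prefer to fix the
#' latter.
#'
#' @slot alpha significance threshold in (0, 1).
#' @exportClass PValueDecisionRule
setClass("PValueDecisionRule", slots = c(alpha = "numeric"))

setValidity("PValueDecisionRule", function(object) {
  if (length(object@alpha) != 1L || !is.finite(object@alpha) ||
      object@alpha <= 0 || object@alpha >= 1)
    "'alpha' must lie strictly between 0 and 1" else TRUE
})

#' Fitted per-trait marginal enrichment model
#'
#' Maximum-likelihood logistic regression of the binary per-trait association
#' verdicts on the SNP covariate categories,
#' \code{logit(p_ir) = gamma_0r + gamma_r' x_i}. The intercept is the baseline
#' log-odds of association not attributable to any covariate; a significantly
#' positive coefficient marks a category enriched for trait-associated SNPs.
#'
#' @slot traitId trait label.
#' @slot coef named coefficient vector (intercept first).
#' @slot se standard errors.
#' @slot zValue coef / se.
#' @slot pOneSided one-sided p-values, H1: coefficient > 0.
#' @slot pTwoSided two-sided Wald p-values.
#' @slot fitted fitted association probabilities, one per SNP.
#' @slot counts per-covariate number of associated SNPs inside the category.
#' @slot nAssoc total number of SNPs called associated for this trait.
#' @slot dropped labels of all-zero covariate columns dropped before fitting.
#'
#' @exportClass MarginalFit
setClass("MarginalFit",
         slots = c(traitId = "character", coef = "numeric", se = "numeric",
                   zValue = "numeric", pOneSided = "numeric",
                   pTwoSided = "numeric", fitted = "numeric",
                   counts = "numeric", nAssoc = "numeric",
                   dropped = "character"))

setValidity("MarginalFit", function(object) {
  if (length(object@fitted) &&
      (any(object@fitted <= 0) || any(object@fitted >= 1)))
    return("fitted probabilities must lie strictly in (0, 1)")
  TRUE
})

#' Fitted overlap (concordance) enrichment model
#'
#' Second-stage logistic regression of the overlap verdicts
#' \code{Y_i = prod_r Y_ir} on the covariate categories, with the per-SNP
#' log-odds of chance overlap included as a fixed offset,
#' \code{logit(p_i) = beta_0 + beta' x_i + offset_i}. Coefficients measure
#' enrichment of shared-associated SNPs beyond what the marginal models imply
#' by chance; the intercept captures excess sharing unrelated to any covariate.
#' Standard errors treat the offset as known (the package's default variance
#' choice; see the methods vignette).
#'
#' @slot coef,se,zValue,pOneSided,pTwoSided as in [MarginalFit-class].
#' @slot offset per-SNP offset used in the fit (zeros in no-offset mode).
#' @slot excludedCovariates categories removed because they contained no
#'   overlap-positive SNPs.
#' @slot counts per-covariate number of overlap SNPs inside the category
#'   (including excluded categories, where the count is 0).
#' @slot nOverlap total number of overlap SNPs.
#' @slot varMethod \code{"known-offset"} or \code{"jackknife"}.
#'
#' @exportClass OverlapFit
setClass("OverlapFit",
         slots = c(coef = "numeric", se = "numeric", zValue = "numeric",
                   pOneSided = "numeric", pTwoSided = "numeric",
                   offset = "numeric", excludedCovariates = "character",
                   counts = "numeric", nOverlap = "numeric",
                   varMethod = "character"))

setValidity("OverlapFit", function(object) {
  bad <- object@excludedCovariates[
    object@excludedCovariates %in% names(object@counts) &
      object@counts[object@excludedCovariates] != 0]
  if (length(bad))
    return(paste0("excluded covariates must have zero overlap counts: ",
                  paste(bad, collapse = ", ")))
  TRUE
})

#' Complete two-stage enrichment analysis result
#'
#' Container returned by [comet()]: association calls per trait, per-trait
#' marginal fits, the offset-corrected overlap fit, and a long-format results
#' table (one row per model term with estimate, SE, one- and two-sided
#' p-values and category counts).
#'
#' @slot traits trait labels, in model order.
#' @slot rule the decision rule used for classification.
#' @slot calls m x R binary matrix of association verdicts.
#' @slot marginalFits named list of [MarginalFit-class] objects.
#' @slot overlapFit an [OverlapFit-class].
#' @slot results long-format results \code{data.frame}.
#' @slot droppedCategories categories removed up front by the small-category
#'   guard (fewer than \code{minCategoryProp} positive SNPs).
#' @slot nSNPs number of SNPs analysed after intersection across traits.
#'
#' @exportClass CometFit
setClass("CometFit",
         slots = c(traits = "character", rule = "ANY", calls = "matrix",
                   marginalFits = "list", overlapFit = "OverlapFit",
                   results = "data.frame", droppedCategories = "character",
                   nSNPs = "numeric"))

#' Generative parameters for paired-GWAS simulation
#'
#' Describes a panel of approximately independent SNPs annotated with binary
#' covariate categories, and two (case-control or quantitative) studies whose
#' per-SNP summary statistics are drawn from the asymptotic sampling
#' distribution. Proportions \code{p1}, \code{p2}, \code{p12} give the
#' fraction of SNPs causal for trait 1, trait 2 and both; \code{p12Prime} is
#' the fraction of SNPs that are shared-causal AND inside
#' \code{enrichedCategory} (under the null it equals \code{p12} times the
#' category proportion, i.e. uniform allocation).
#'
#' @slot m number of SNPs in the panel.
#' @slot categoryProps named per-category membership proportions, each in
#'   (0, 1).
#' @slot p1,p2,p12 causal proportions (marginal trait 1, marginal trait 2,
#'   shared), with \code{p12 <= min(p1, p2)}.
#' @slot enrichedCategory label of the enriched category, or \code{NA} for
#'   uniform (null) allocation of shared-causal SNPs.
#' @slot p12Prime shared-causal-in-category proportion; \code{NA} means the
#'   null value \code{p12 * categoryProps[enrichedCategory]}.
#' @slot studyType \code{"case-control"} or \code{"quantitative"}.
#' @slot N1,N2 per-study sizes (cases = controls = N for case-control;
#'   individuals for quantitative).
#' @slot sharedIndividuals fraction of overlapping subjects between the
#'   studies; induces that much correlation between the per-SNP noise terms.
#' @slot effectSd standard deviation of causal effect magnitudes.
#' @slot bMin lower truncation bound on causal effect magnitudes.
#' @slot mafRange minor-allele-frequency sampling range (uniform).
#' @slot seed integer seed, or \code{NA}.
#'
#' @seealso [simConfig()], [simulateStudyPair()]
#' @exportClass SimulationConfig
setClass("SimulationConfig",
         slots = c(m = "numeric", categoryProps = "numeric", p1 = "numeric",
                   p2 = "numeric", p12 = "numeric",
                   enrichedCategory = "character", p12Prime = "numeric",
                   studyType = "character", N1 = "numeric", N2 = "numeric",
                   sharedIndividuals = "numeric", effectSd = "numeric",
                   bMin = "numeric", mafRange = "numeric", seed = "numeric"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (length(object@m) != 1L || object@m < 10 || object@m != round(object@m))
    msg <- c(msg, "'m' must be a single integer >= 10")
  if (is.null(names(object@categoryProps)) ||
      any(!nzchar(names(object@categoryProps))))
    msg <- c(msg, "'categoryProps' must be a named vector")
  if (any(object@categoryProps <= 0) || any(object@categoryProps >= 1))
    msg <- c(msg, "'categoryProps' must lie strictly in (0, 1)")
  for (p in c("p1", "p2", "p12"))
    if (slot(object, p) <= 0 || slot(object, p) >= 1)
      msg <- c(msg, sprintf("'%s' must lie strictly in (0, 1)", p))
  if (object@p12 > min(object@p1, object@p2))
    msg <- c(msg, "'p12' cannot exceed min(p1, p2)")
  if (!is.na(object@enrichedCategory) &&
      !object@enrichedCategory %in% names(object@categoryProps))
    msg <- c(msg, "'enrichedCategory' is not a named category")
  if (!is.na(object@p12Prime)) {
    if (is.na(object@enrichedCategory))
      msg <- c(msg, "'p12Prime' requires 'enrichedCategory'")
    if (object@p12Prime < 0 || object@p12Prime > object@p12)
      msg <- c(msg, "'p12Prime' must lie in [0, p12]")
  }
  if (!object@studyType %in% c("case-control", "quantitative"))
    msg <- c(msg, "'studyType' must be 'case-control' or 'quantitative'")
  if (object@N1 < 2 || object@N2 < 2)
    msg <- c(msg, "study sizes must be at least 2")
  if (object@sharedIndividuals < 0 || object@sharedIndividuals > 1)
    msg <- c(msg, "'sharedIndividuals' must lie in [0, 1]")
  if (object@effectSd <= 0) msg <- c(msg, "'effectSd' must be positive")
  if (object@bMin < 0) msg <- c(msg, "'bMin' must be non-negative")
  if (length(object@mafRange) != 2L || object@mafRange[1] <= 0 ||
      object@mafRange[2] > 0.5 || object@mafRange[1] >= object@mafRange[2])
    msg <- c(msg, "'mafRange' must be an increasing pair within (0, 0.5]")
  if (length(msg)) msg else TRUE
})

#' Simulated pair of GWAS studies
#'
#' Output of [simulateStudyPair()]: per-trait summary statistics, the binary
#' annotation matrix and the ground-truth causal table, together with the
#' generating configuration.
#'
#' @slot stats named list of per-trait summary-statistic \code{data.frame}s
#'   (columns \code{snp}, \code{beta}, \code{se}).
#' @slot annotations m x K binary matrix, rownames = SNP ids.
#' @slot truth \code{data.frame} with per-SNP causal status (\code{causal1},
#'   \code{causal2}, \code{shared}) and the sampled MAF.
#' @slot config the [SimulationConfig-class] used.
#'
#' @exportClass StudyPair
setClass("StudyPair",
         slots = c(stats = "list", annotations = "matrix",
                   truth = "data.frame", config = "SimulationConfig"))

#' Replicate-level calibration results
#'
#' Output of [runReplicates()]: per-covariate rejection rates with Wilson 95%
#' confidence intervals and median-chi-square inflation factors for the
#' offset-corrected overlap test and the hypergeometric comparator, plus the
#' raw standardized statistics for QQ inspection.
#'
#' @slot summary \code{data.frame} with columns \code{method},
#'   \code{covariate}, \code{nReps}, \code{rate}, \code{ciLo}, \code{ciHi},
#'   \code{lambda}, \code{lambdaPos}.
#' @slot overlapZ nReps x K matrix of standardized overlap-model estimates
#'   (\code{NA} where the covariate was excluded from the final model).
#' @slot marginalZ named list (per trait) of nReps x K matrices of
#'   standardized marginal-model estimates.
#' @slot cometP nReps x K matrix of one-sided overlap p-values (1 where the
#'   covariate was excluded).
#' @slot hyperP nReps x K matrix of hypergeometric upper-tail p-values.
#' @slot alpha significance level used for the rejection rates.
#' @slot nReps number of replicates.
#' @slot repSeeds per-replicate seeds spawned from the master seed, recorded
#'   for exact replay.
#' @slot config the [SimulationConfig-class] simulated from.
#'
#' @exportClass CalibrationResult
setClass("CalibrationResult",
         slots = c(summary = "data.frame", overlapZ = "matrix",
                   marginalZ = "list", cometP = "matrix", hyperP = "matrix",
                   alpha = "numeric", nReps = "numeric", repSeeds = "numeric",
                   config = "SimulationConfig"))
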