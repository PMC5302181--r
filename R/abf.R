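#' @include AllGenerics.R
NULL

#' log10 approximate Bayes factor from a single-SNP summary statistic
#'
#' Computes the asymptotic (Wakefield-style) Bayes factor in favour of
#' association from an effect estimate and its standard error, under a normal
#' effect-size prior N(0, \code{priorSd}^2):
#' \deqn{ABF = \sqrt{V/(V+W)} \exp\{z^2 W / (2(V+W))\}}
#' with \eqn{V = se^2}, \eqn{W = priorSd^2}, \eqn{z = beta/se}. Larger values
#' mean more evidence for association; the function is even in \code{beta}.
#'
#' \code{priorSd = 0} is accepted as the degenerate no-alternative limit and
#' returns 0 (BF = 1) for every input; negative values are errors.
#'
#' @param beta effect size(s): log odds ratio for case-control studies,
#'   standardized beta for quantitative traits.
#' @param se standard error(s) of \code{beta}, strictly positive.
#' @param priorSd prior standard deviation of the true effect, on the same
#'   scale as \code{beta}. Default 0.3.
#' @return numeric vector of log10 ABF values.
#' @examples
#' log10ABF(0.3, 0.05, priorSd = 0.2)
#' log10ABF(0, 0.1, priorSd = 0.1)  # z = 0, V = W: log10(1/sqrt(2))
#' @export
log10ABF <- function(beta, se, priorSd = 0.3) {
  if (length(beta) != length(se))
    stop("'beta' and 'se' must have the same length")
  if (any(!is.finite(beta)))
    stop("'beta' must be finite")
  if (any(!is.finite(se)) || any(se <= 0))
    stop("'se' must be finite and strictly positive")
  if (length(priorSd) != 1L || !is.finite(priorSd) || priorSd < 0)
    stop("'priorSd' must be a single non-negative number")
  if (priorSd == 0) return(rep(0, length(beta)))
  V <- se^2
  W <- priorSd^2
  z2 <- (beta / se)^2
  0.5 * (log10(V) - log10(V + W)) + (z2 / 2) * (W / (V + W)) / log(10)
}

#' Bayesian decision threshold on the log10 ABF scale
#'
#' The posterior-odds decision bound implied by a cost ratio \code{costRatio}
#' (relative cost of a false positive to a false negative) and a prior null
#' probability \code{priorNull}: association is declared when
#' \code{log10(ABF) > log10(priorNull / ((1 - priorNull) * costRatio))}.
#' The defaults give 0.695 (to 3 decimals).
#'
#' @param costRatio positive cost ratio.
#' @param priorNull prior null probability, strictly in (0, 1).
#' @return the threshold on the log10 ABF scale.
#' @examples
#' decisionThreshold(20, 0.99)  # 0.695
#' @export
decisionThreshold <- function(costRatio, priorNull) {
  if (length(costRatio) != 1L || !is.finite(costRatio) || costRatio <= 0)
    stop("'costRatio' must be a single positive number")
  if (length(priorNull) != 1L || !is.finite(priorNull) ||
      priorNull <= 0 || priorNull >= 1)
    stop("'priorNull' must lie strictly between 0 and 1")
  log10(priorNull / ((1 - priorNull) * costRatio))
}

#' Construct a Bayes-factor decision rule
#'
#' @param costRatio cost ratio of false positives to false negatives.
#' @param priorNull prior null probability.
#' @param priorSd prior SD of the effect size used in the ABF.
#' @return a [BFDecisionRule-class] with the derived \code{log10Threshold}.
#' @examples
#' bfDecisionRule()              # threshold 0.695
#' bfDecisionRule(10, 0.9)       # threshold log10(0.9)
#' @export
bfDecisionRule <- function(costRatio = 20, priorNull = 0.99, priorSd = 0.3) {
  new("BFDecisionRule", costRatio = costRatio, priorNull = priorNull,
      log10Threshold = decisionThreshold(costRatio, priorNull),
      priorSd = priorSd)
}

#' Construct a p-value decision rule
#'
#' @param alpha two-sided Wald p-value threshold.
#' @return a [PValueDecisionRule-class].
#' @export
pValueRule <- function(alpha = 5e-6) new("PValueDecisionRule", alpha = alpha)

# Validate one trait's summary statistics and return it with snp/beta/se.
checkStats <- function(stats, trait = "trait") {
  if (!is.data.frame(stats))
    stop("summary statistics for '", trait, "' must be a data.frame")
  need <- c("snp", "beta", "se")
  miss <- setdiff(need, names(stats))
  if (length(miss))
    stop("summary statistics for '", trait, "' lack column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(stats$snp))
    stop("duplicated SNP ids in summary statistics for '", trait, "'")
  if (any(!is.finite(stats$beta)) || any(!is.finite(stats$se)))
    stop("non-finite beta or se in summary statistics for '", trait, "'")
  if (any(stats$se <= 0))
    stop("non-positive se in summary statistics for '", trait, "'")
  stats
}

# Intersect a named list of per-trait summary stats on common SNP ids.
# Returns list(snp, beta (m x R), se (m x R), droppedPerTrait).
harmoniseStats <- function(statsList, verbose = FALSE) {
  if (is.null(names(statsList)) || any(!nzchar(names(statsList))))
    names(statsList) <- paste0("trait", seq_along(statsList))
  statsList <- mapply(checkStats, statsList, names(statsList),
                      SIMPLIFY = FALSE)
  common <- Reduce(intersect, lapply(statsList, `[[`, "snp"))
  if (length(common) == 0L) stop("no SNPs shared across all traits")
  dropped <- vapply(statsList, function(s) nrow(s) - length(common),
                    numeric(1))
  if (verbose && any(dropped > 0))
    message("SNPs absent from some trait and excluded: ",
            paste(sprintf("%s=%d", names(dropped), dropped), collapse = ", "))
  beta <- se <- matrix(NA_real_, length(common), length(statsList),
                       dimnames = list(common, names(statsList)))
  for (r in names(statsList)) {
    s <- statsList[[r]]
    idx <- match(common, s$snp)
    beta[, r] <- s$beta[idx]
    se[, r] <- s$se[idx]
  }
  list(snp = common, beta = beta, se = se, dropped = dropped)
}

#' @describeIn classifyAssociations BF classification of a single trait's
#'   summary statistics; the verdict is \code{y = 1} iff the log10 ABF
#'   strictly exceeds the rule's threshold.
#' @export
setMethod("classifyAssociations", c("data.frame", "BFDecisionRule"),
  function(stats, rule, trait = "trait", ...) {
    stats <- checkStats(stats, trait)
    l10 <- log10ABF(stats$beta, stats$se, rule@priorSd)
    data.frame(snp = stats$snp, trait = trait, statistic = l10,
               y = as.integer(l10 > rule@log10Threshold),
               stringsAsFactors = FALSE)
  })

#' @describeIn classifyAssociations p-value classification of a single
#'   trait's summary statistics.
#' @export
setMethod("classifyAssociations", c("data.frame", "PValueDecisionRule"),
  function(stats, rule, trait = "trait", ...) {
    stats <- checkStats(stats, trait)
    p <- 2 * stats::pnorm(-abs(stats$beta / stats$se))
    data.frame(snp = stats$snp, trait = trait, statistic = p,
               y = as.integer(p < rule@alpha), stringsAsFactors = FALSE)
  })

#' @describeIn classifyAssociations classification of several traits at
#'   once; SNPs missing from any trait are excluded (with a message when
#'   \code{verbose = TRUE}) so that every call refers to a SNP present in all
#'   traits.
#' @export
setMethod("classifyAssociations", c("list", "ANY"),
  function(stats, rule, verbose = FALSE, ...) {
    h <- harmoniseStats(stats, verbose = verbose)
    do.call(rbind, lapply(colnames(h$beta), function(r) {
      classifyAssociations(
        data.frame(snp = h$snp, beta = h$beta[, r], se = h$se[, r],
                   stringsAsFactors = FALSE),
        rule, trait = r)
    }))
  })

# Internal: calls and log10 ABFs as matrices on the intersected SNP set.
callMatrix <- function(statsList, rule, verbose = FALSE) {
  h <- harmoniseStats(statsList, verbose = verbose)
  if (is(rule, "BFDecisionRule")) {
    stat <- vapply(seq_len(ncol(h$beta)),
                   function(j) log10ABF(h$beta[, j], h$se[, j], rule@priorSd),
                   numeric(length(h$snp)))
    y <- (stat > rule@log10Threshold) * 1L
  } else if (is(rule, "PValueDecisionRule")) {
    stat <- 2 * stats::pnorm(-abs(h$beta / h$se))
    y <- (stat < rule@alpha) * 1L
  } else stop("unsupported decision rule of class ", class(rule))
  dimnames(stat) <- dimnames(y) <- list(h$snp, colnames(h$beta))
  list(snp = h$snp, statistic = stat, calls = y, dropped = h$dropped)
}
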