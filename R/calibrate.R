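#' @include simulate.R hypergeom.R
NULL

#' Wilson score confidence interval for a proportion
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return numeric vector \code{c(lo, hi)}.
#' @export
wilsonCI <- function(k, n, conf = 0.95) {
  if (n < 1 || k < 0 || k > n) stop("need 0 <= k <= n, n >= 1")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lo = max(0, ctr - hw), hi = min(1, ctr + hw))
}

#' Median-chi-square inflation factor
#'
#' \eqn{\lambda = median(z^2) / 0.4549364} (the median of the chi-square
#' distribution with 1 df); values near 1 indicate calibrated standardized
#' statistics. For one-sided enrichment tests in small categories -- where
#' many replicates exclude the covariate or give negative estimates -- the
#' one-sided variant computed from the positive standardized statistics only
#' is available via \code{positiveOnly = TRUE}.
#'
#' @param z numeric vector of standardized estimates; \code{NA}s are
#'   removed.
#' @param positiveOnly restrict to \code{z > 0} before taking the median.
#' @return the inflation factor.
#' @examples
#' inflationFactor(c(-0.67449, 0.67449, 0.67449))  # 1
#' @export
inflationFactor <- function(z, positiveOnly = FALSE) {
  z <- z[is.finite(z)]
  if (positiveOnly) z <- z[z > 0]
  if (length(z) == 0L) stop("no finite standardized estimates")
  stats::median(z^2) / stats::qchisq(0.5, df = 1)
}

#' Normal QQ coordinates for standardized estimates
#'
#' @param z numeric vector of standardized estimates.
#' @return \code{data.frame} with columns \code{expected}
#'   (\eqn{\Phi^{-1}((i - 0.5)/n)}) and \code{observed} (sorted \code{z}).
#' @export
qqPoints <- function(z) {
  z <- z[is.finite(z)]
  if (length(z) == 0L) stop("no finite standardized estimates")
  n <- length(z)
  data.frame(expected = stats::qnorm((seq_len(n) - 0.5) / n),
             observed = sort(z))
}

#' Replicate-level calibration of the overlap enrichment tests
#'
#' Repeatedly simulates an annotated study pair from \code{cfg}, runs the
#' two-stage analysis and the hypergeometric comparator on each replicate,
#' and aggregates per-covariate one-sided rejection rates (with Wilson 95%
#' CIs) and median-chi-square inflation factors. Replicates use independent
#' seeds spawned from \code{seed} and recorded in the result, so any single
#' replicate can be replayed exactly.
#'
#' @param cfg a [SimulationConfig-class].
#' @param nReps number of replicates.
#' @param alpha significance level for the rejection rates.
#' @param seed master seed.
#' @param rule decision rule passed to [comet()].
#' @param minCategoryProp small-category guard passed to [comet()].
#' @return a [CalibrationResult-class].
#' @examples
#' cfg <- simConfig(m = 5000)
#' cal <- runReplicates(cfg, nReps = 3, seed = 1)
#' rejectionRates(cal)
#' @export
runReplicates <- function(cfg, nReps = 1000, alpha = 0.05, seed = 1L,
                          rule = bfDecisionRule(), minCategoryProp = 2.5e-4) {
  stopifnot(is(cfg, "SimulationConfig"))
  if (nReps < 1) stop("'nReps' must be at least 1")
  if (alpha <= 0 || alpha > 1) stop("'alpha' must lie in (0, 1]")
  set.seed(seed)
  repSeeds <- sample.int(.Machine$integer.max - 1L, nReps)
  covs <- names(cfg@categoryProps)
  K <- length(covs)
  dn <- list(NULL, covs)
  overlapZ <- cometP <- hyperP <- matrix(NA_real_, nReps, K, dimnames = dn)
  marginalZ <- list(trait1 = matrix(NA_real_, nReps, K, dimnames = dn),
                    trait2 = matrix(NA_real_, nReps, K, dimnames = dn))
  for (i in seq_len(nReps)) {
    sp <- simulateStudyPair(cfg, seed = repSeeds[i])
    fit <- suppressWarnings(
      comet(sp@stats, sp@annotations, rule = rule,
            minCategoryProp = minCategoryProp, verbose = FALSE))
    ov <- fit@overlapFit
    idx <- match(names(ov@coef), covs)
    keep <- !is.na(idx)
    overlapZ[i, idx[keep]] <- ov@zValue[keep]
    cometP[i, idx[keep]] <- ov@pOneSided[keep]
    cometP[i, match(ov@excludedCovariates, covs)] <- 1
    for (r in names(marginalZ)) {
      mf <- fit@marginalFits[[r]]
      mi <- match(names(mf@coef), covs)
      mk <- !is.na(mi)
      marginalZ[[r]][i, mi[mk]] <- mf@zValue[mk]
    }
    hyperP[i, ] <- hypergeomOverlapTest(fit@calls, sp@annotations)$p
  }
  summarise <- function(P, Z, method) {
    do.call(rbind, lapply(covs, function(q) {
      p <- P[, q]
      kRej <- sum(p < alpha, na.rm = TRUE)
      nEff <- sum(!is.na(p))
      ci <- wilsonCI(kRej, nEff)
      z <- if (is.null(Z)) NA_real_ else Z[, q]
      data.frame(method = method, covariate = q, nReps = nEff,
                 rate = kRej / nEff, ciLo = ci[["lo"]], ciHi = ci[["hi"]],
                 lambda = if (all(is.na(z))) NA_real_ else inflationFactor(z),
                 lambdaPos = if (all(is.na(z)) || !any(z > 0, na.rm = TRUE))
                   NA_real_ else inflationFactor(z, positiveOnly = TRUE),
                 stringsAsFactors = FALSE)
    }))
  }
  summary <- rbind(summarise(cometP, overlapZ, "comet"),
                   summarise(hyperP, NULL, "hypergeometric"))
  rownames(summary) <- NULL
  new("CalibrationResult", summary = summary, overlapZ = overlapZ,
      marginalZ = marginalZ, cometP = cometP, hyperP = hyperP,
      alpha = alpha, nReps = nReps, repSeeds = as.numeric(repSeeds),
      config = cfg)
}

#' Power sweep over the shared-causal enrichment proportion
#'
#' Repeats [runReplicates()] over a grid of \code{p12Prime} values for one
#' enriched category and reports that category's one-sided rejection rate at
#' each grid point. Including the null point
#' \code{p12Prime = p12 * categoryProps[category]} turns the first row into
#' a type-I-error estimate.
#'
#' @param cfg base [SimulationConfig-class].
#' @param p12PrimeGrid numeric vector of \code{p12Prime} values.
#' @param category enriched category label (default \code{"Q5"}).
#' @param nReps replicates per grid point.
#' @param alpha significance level.
#' @param seed master seed (each grid point gets an independent stream).
#' @param ... further arguments to [runReplicates()].
#' @return \code{data.frame} with columns \code{p12Prime},
#'   \code{fracOfShared} (\code{p12Prime / p12}), \code{rate}, \code{ciLo},
#'   \code{ciHi}, \code{nReps}.
#' @export
powerSweep <- function(cfg, p12PrimeGrid, category = "Q5", nReps = 1000,
                       alpha = 0.05, seed = 1L, ...) {
  stopifnot(is(cfg, "SimulationConfig"))
  if (!category %in% names(cfg@categoryProps))
    stop("'", category, "' is not a configured category")
  set.seed(seed)
  gridSeeds <- sample.int(.Machine$integer.max - 1L, length(p12PrimeGrid))
  rows <- lapply(seq_along(p12PrimeGrid), function(g) {
    cfgG <- cfg
    cfgG@enrichedCategory <- category
    cfgG@p12Prime <- p12PrimeGrid[g]
    validObject(cfgG)
    cal <- runReplicates(cfgG, nReps = nReps, alpha = alpha,
                         seed = gridSeeds[g], ...)
    s <- cal@summary
    s <- s[s$method == "comet" & s$covariate == category, ]
    data.frame(p12Prime = p12PrimeGrid[g],
               fracOfShared = p12PrimeGrid[g] / cfg@p12,
               rate = s$rate, ciLo = s$ciLo, ciHi = s$ciHi,
               nReps = s$nReps, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
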