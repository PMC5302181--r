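#' @include AllClasses.R
NULL

#' Construct a simulation configuration
#'
#' Defaults reproduce the package's reference study conditions: a panel of
#' 208,780 approximately independent SNPs carrying five binary annotation
#' categories with membership proportions 51.5% (Q1), 0.39% (Q2), 0.54%
#' (Q3), 1.40% (Q5) and 64.1% (Q6); causal proportions p1 = 0.04, p2 = 0.02
#' and p12 = 5e-4; and two equal-sized case-control studies of 3000 and 5000
#' cases (and as many controls). Under the null no category is enriched:
#' shared-causal SNPs are allocated uniformly, so the in-category shared
#' proportion is \code{p12 * categoryProps[Q]} for every category Q (for Q5
#' this is 7e-6).
#'
#' @param m panel size.
#' @param categoryProps named category membership proportions.
#' @param p1,p2,p12 causal proportions (trait 1, trait 2, shared).
#' @param enrichedCategory category enriched for shared-causal SNPs, or
#'   \code{NA} (null).
#' @param p12Prime proportion of SNPs that are shared-causal and inside the
#'   enriched category; \code{NA} means the null value
#'   \code{p12 * categoryProps[enrichedCategory]}.
#' @param studyType \code{"case-control"} or \code{"quantitative"}.
#' @param N1,N2 study sizes (per arm for case-control).
#' @param sharedIndividuals fraction of subjects shared between studies.
#' @param effectSd SD of causal effect magnitudes.
#' @param bMin truncation bound on causal effect magnitudes, chosen so that
#'   a boundary effect at the median MAF has roughly 80% detection power at
#'   the default BF threshold in the smaller reference study.
#' @param mafRange uniform MAF sampling range.
#' @param seed default seed used by [simulateStudyPair()] when none is
#'   given; \code{NA} leaves the RNG state alone.
#' @return a validated [SimulationConfig-class].
#' @examples
#' simConfig(m = 1e4)
#' simConfig(enrichedCategory = "Q5", p12Prime = 1e-4)
#' @export
simConfig <- function(m = 208780,
                      categoryProps = c(Q1 = 0.515, Q2 = 0.0039,
                                        Q3 = 0.0054, Q5 = 0.0140,
                                        Q6 = 0.641),
                      p1 = 0.04, p2 = 0.02, p12 = 5e-4,
                      enrichedCategory = NA_character_,
                      p12Prime = NA_real_,
                      studyType = c("case-control", "quantitative"),
                      N1 = 3000, N2 = 5000, sharedIndividuals = 0,
                      effectSd = 0.25, bMin = 0.2,
                      mafRange = c(0.05, 0.5), seed = NA_real_) {
  studyType <- match.arg(studyType)
  new("SimulationConfig", m = m, categoryProps = categoryProps, p1 = p1,
      p2 = p2, p12 = p12, enrichedCategory = as.character(enrichedCategory),
      p12Prime = as.numeric(p12Prime), studyType = studyType, N1 = N1,
      N2 = N2, sharedIndividuals = sharedIndividuals, effectSd = effectSd,
      bMin = bMin, mafRange = mafRange, seed = as.numeric(seed))
}

# Effective p12Prime: the configured value, or the null (uniform) value.
nullP12Prime <- function(cfg) {
  if (is.na(cfg@enrichedCategory)) return(NA_real_)
  if (!is.na(cfg@p12Prime)) return(cfg@p12Prime)
  cfg@p12 * cfg@categoryProps[[cfg@enrichedCategory]]
}

#' Simulate a binary annotation matrix
#'
#' Each category column is drawn independently Bernoulli(prop) per SNP, so a
#' SNP may belong to several categories at once (as annotation tools report
#' in practice). Supply a real joint-membership matrix to [comet()] instead
#' if correlated memberships matter.
#'
#' @param cfg a [SimulationConfig-class].
#' @param seed optional seed; \code{NULL} uses the current RNG state.
#' @return m x K binary matrix with SNP-id rownames.
#' @export
simulateAnnotations <- function(cfg, seed = NULL) {
  stopifnot(is(cfg, "SimulationConfig"))
  if (!is.null(seed)) set.seed(seed)
  m <- cfg@m
  props <- cfg@categoryProps
  X <- vapply(props, function(p) stats::rbinom(m, 1L, p), integer(m))
  rownames(X) <- sprintf("snp%07d", seq_len(m))
  X
}

#' Assign causal status to SNPs
#'
#' Draws the shared-causal set (of expected size \code{m * p12}) and the
#' trait-specific causal sets (topping the marginals up to \code{m * p1} and
#' \code{m * p2}). With an enriched category, an unbiased stochastic
#' rounding of \code{m * p12Prime} shared-causal SNPs is drawn from inside
#' the category and of \code{m * (p12 - p12Prime)} from its complement
#' (exact when the targets are integers); causal SNPs are
#' otherwise unrestricted, so they may well belong to other categories too.
#' Under the null (no enriched category) allocation is uniform, equivalent
#' to \code{p12Prime = p12 * categoryProps[Q]} for every category.
#'
#' @param cfg a [SimulationConfig-class].
#' @param annotations matrix from [simulateAnnotations()].
#' @param seed optional seed.
#' @return \code{data.frame} with columns \code{snp}, \code{causal1},
#'   \code{causal2}, \code{shared} (logicals; \code{causalr} includes the
#'   shared set).
#' @export
assignCausal <- function(cfg, annotations, seed = NULL) {
  stopifnot(is(cfg, "SimulationConfig"))
  if (!is.null(seed)) set.seed(seed)
  m <- cfg@m
  if (nrow(annotations) != m)
    stop("'annotations' does not match the configured panel size")
  snp <- rownames(annotations)
  all <- seq_len(m)
  if (is.na(cfg@enrichedCategory)) {
    shared <- sample(all, round(m * cfg@p12))
  } else {
    p12p <- nullP12Prime(cfg)
    # stochastic rounding keeps the expected in-category count unbiased
    # when m * p12Prime is far from an integer (as it is at reduced panel
    # sizes); for integer targets it is exact
    nIn <- stochasticRound(m * p12p)
    nOut <- stochasticRound(m * (cfg@p12 - p12p))
    inside <- which(annotations[, cfg@enrichedCategory] == 1)
    if (nIn > length(inside))
      stop("infeasible: fewer SNPs in '", cfg@enrichedCategory,
           "' than the requested shared-causal count")
    outside <- setdiff(all, inside)
    if (nOut > length(outside))
      stop("infeasible shared-causal count outside the enriched category")
    shared <- c(sample(inside, nIn), sample(outside, nOut))
  }
  pool <- setdiff(all, shared)
  n1 <- max(0L, round(m * cfg@p1) - length(shared))
  if (n1 > length(pool)) stop("infeasible trait-1 causal count")
  only1 <- sample(pool, n1)
  pool <- setdiff(pool, only1)
  n2 <- max(0L, round(m * cfg@p2) - length(shared))
  if (n2 > length(pool)) stop("infeasible trait-2 causal count")
  only2 <- sample(pool, n2)
  causal1 <- causal2 <- sharedFlag <- logical(m)
  causal1[c(shared, only1)] <- TRUE
  causal2[c(shared, only2)] <- TRUE
  sharedFlag[shared] <- TRUE
  data.frame(snp = snp, causal1 = causal1, causal2 = causal2,
             shared = sharedFlag, stringsAsFactors = FALSE)
}

# floor(x) + 1 with probability frac(x): unbiased integerisation.
stochasticRound <- function(x) {
  f <- floor(x)
  as.integer(f + (stats::runif(1) < (x - f)))
}

# |b| ~ half-N(0, sd^2) conditioned on |b| >= bMin, by inverse CDF.
rTruncMagnitude <- function(n, sd, bMin) {
  lo <- stats::pnorm(bMin / sd)
  sd * stats::qnorm(stats::runif(n, lo, 1))
}

#' Simulate per-trait summary statistics
#'
#' Summary-statistic-level generation: for each SNP a MAF is drawn uniformly
#' from \code{mafRange} and the per-trait standard error follows from MAF
#' and study size (case-control with case fraction 1/2:
#' \code{se = sqrt(2 / (N * maf * (1 - maf)))}; quantitative:
#' \code{se = 1 / sqrt(2 * N * maf * (1 - maf))}). Effect estimates are
#' drawn from the asymptotic sampling distribution: \code{beta ~ N(0, se^2)}
#' for non-causal SNPs and \code{beta ~ N(b, se^2)} for causal SNPs, with
#' the true effect magnitude \code{|b|} drawn once per causal SNP-trait from
#' a half-normal(\code{effectSd}) truncated at \code{bMin}. Shared-causal
#' SNPs receive the same effect sign in both traits; when
#' \code{sharedIndividuals > 0} the two traits' per-SNP noise terms are
#' correlated with that coefficient.
#'
#' @param truth output of [assignCausal()].
#' @param cfg a [SimulationConfig-class].
#' @param seed optional seed.
#' @return list with elements \code{stats} (named list of per-trait
#'   \code{data.frame}s with columns \code{snp}, \code{beta}, \code{se}) and
#'   \code{maf} (the per-SNP MAF vector).
#' @export
simulateSummaryStats <- function(truth, cfg, seed = NULL) {
  stopifnot(is(cfg, "SimulationConfig"))
  if (!is.null(seed)) set.seed(seed)
  m <- cfg@m
  if (nrow(truth) != m) stop("'truth' does not match the panel size")
  maf <- stats::runif(m, cfg@mafRange[1], cfg@mafRange[2])
  het <- maf * (1 - maf)
  seFor <- function(N) {
    if (cfg@studyType == "case-control") sqrt(2 / (N * het))
    else 1 / sqrt(2 * N * het)
  }
  se1 <- seFor(cfg@N1)
  se2 <- seFor(cfg@N2)

  b1 <- b2 <- numeric(m)
  c1 <- which(truth$causal1)
  c2 <- which(truth$causal2)
  sh <- which(truth$shared)
  sign1 <- numeric(m)
  sign1[c1] <- sample(c(-1, 1), length(c1), replace = TRUE)
  b1[c1] <- sign1[c1] * rTruncMagnitude(length(c1), cfg@effectSd, cfg@bMin)
  sign2 <- numeric(m)
  sign2[c2] <- sample(c(-1, 1), length(c2), replace = TRUE)
  sign2[sh] <- sign1[sh]  # concordant direction at shared-causal SNPs
  b2[c2] <- sign2[c2] * rTruncMagnitude(length(c2), cfg@effectSd, cfg@bMin)

  e1 <- stats::rnorm(m)
  u <- stats::rnorm(m)
  rho <- cfg@sharedIndividuals
  e2 <- rho * e1 + sqrt(1 - rho^2) * u

  mk <- function(b, se, e)
    data.frame(snp = truth$snp, beta = b + se * e, se = se,
               stringsAsFactors = FALSE)
  list(stats = list(trait1 = mk(b1, se1, e1), trait2 = mk(b2, se2, e2)),
       maf = maf)
}

#' Simulate a complete annotated study pair
#'
#' Composes [simulateAnnotations()], [assignCausal()] and
#' [simulateSummaryStats()] under a single seed.
#'
#' @param cfg a [SimulationConfig-class].
#' @param seed seed for the whole draw; defaults to \code{cfg@seed}. Use
#'   \code{NULL} explicitly to draw from the current RNG state.
#' @return a [StudyPair-class].
#' @export
simulateStudyPair <- function(cfg, seed = if (!is.na(cfg@seed)) cfg@seed) {
  stopifnot(is(cfg, "SimulationConfig"))
  if (!is.null(seed)) set.seed(seed)
  ann <- simulateAnnotations(cfg)
  truth <- assignCausal(cfg, ann)
  ss <- simulateSummaryStats(truth, cfg)
  truth$maf <- ss$maf
  new("StudyPair", stats = ss$stats, annotations = ann, truth = truth,
      config = cfg)
}

#' @describeIn simulateStudyPair accessor: per-trait summary statistics.
#' @param x a [StudyPair-class].
#' @export
studyStats <- function(x) x@stats

#' @describeIn simulateStudyPair accessor: annotation matrix.
#' @export
studyAnnotations <- function(x) x@annotations

#' @describeIn simulateStudyPair accessor: ground-truth causal table.
#' @export
studyTruth <- function(x) x@truth
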