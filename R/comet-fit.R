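#' @include abf.R
NULL

# Shared logistic-regression backbone. Xd includes the intercept column.
# Returns coef/se from the observed information, treating any offset as
# fixed. Errors on rank deficiency and on (quasi-)complete separation.
#
# Because every covariate is binary, observations are first aggregated by
# (covariate pattern, offset value) into grouped binomial data -- an exact
# reformulation with identical MLE and information matrix -- so the IRLS
# cost is driven by the number of distinct patterns, not the panel size.
logisticFit <- function(Xd, y, offset = NULL, maxit = 100L) {
  if (is.null(offset)) offset <- rep(0, length(y))
  key <- drop(Xd %*% 2^(seq_len(ncol(Xd)) - 1))
  offIdx <- match(offset, unique(offset))
  key <- key + (offIdx - 1) * (max(key) + 1)
  grp <- match(key, unique(key))
  lead <- !duplicated(grp)
  trials <- drop(rowsum(rep(1, length(y)), grp))
  succ <- drop(rowsum(y, grp))
  Xg <- Xd[lead, , drop = FALSE][order(unique(grp)), , drop = FALSE]
  offG <- offset[lead][order(unique(grp))]
  fit <- suppressWarnings(
    stats::glm.fit(Xg, succ / trials, weights = trials,
                   family = stats::binomial(), offset = offG,
                   control = stats::glm.control(maxit = maxit)))
  if (fit$rank < ncol(Xd)) {
    aliased <- colnames(Xd)[fit$qr$pivot[(fit$rank + 1):ncol(Xd)]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  if (any(abs(fit$coefficients) > 12) || !fit$converged)
    stop("perfect (or quasi-complete) separation detected in the logistic ",
         "fit; reduce the covariate set or refit with penalized = TRUE")
  p <- fit$rank
  R <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
  R[lower.tri(R)] <- 0
  cov <- chol2inv(R)
  piv <- fit$qr$pivot[seq_len(p)]
  cov <- cov[order(piv), order(piv), drop = FALSE]
  se <- sqrt(diag(cov))
  names(se) <- names(fit$coefficients)
  fitted <- stats::plogis(drop(Xd %*% fit$coefficients) + offset)
  list(coef = fit$coefficients, se = se, fitted = fitted, vcov = cov)
}

# Firth-type penalised logistic regression (Jeffreys prior), offered as an
# extension for separated designs. Modified-score Newton iterations.
firthFit <- function(Xd, y, offset = NULL, maxit = 200L, tol = 1e-8) {
  if (is.null(offset)) offset <- rep(0, length(y))
  beta <- rep(0, ncol(Xd))
  for (it in seq_len(maxit)) {
    eta <- drop(Xd %*% beta) + offset
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    XW <- Xd * w
    info <- crossprod(Xd, XW)
    infoInv <- solve(info)
    # leverages of sqrt(W) X
    h <- rowSums((Xd %*% infoInv) * XW)
    U <- drop(crossprod(Xd, y - p + h * (0.5 - p)))
    step <- drop(infoInv %*% U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(Xd %*% beta) + offset
  p <- stats::plogis(eta)
  info <- crossprod(Xd, Xd * (p * (1 - p)))
  cov <- solve(info)
  se <- sqrt(diag(cov))
  names(beta) <- names(se) <- colnames(Xd)
  list(coef = beta, se = se, fitted = p, vcov = cov)
}

# Validate a binary covariate matrix; returns it with column names.
checkDesign <- function(X, m = NULL) {
  X <- as.matrix(X)
  if (ncol(X) && is.null(colnames(X)))
    colnames(X) <- paste0("X", seq_len(ncol(X)))
  if (!is.null(m) && nrow(X) != m)
    stop("covariate matrix has ", nrow(X), " rows; expected ", m)
  if (any(!X %in% c(0, 1)))
    stop("covariate matrix entries must be 0/1")
  storage.mode(X) <- "double"
  X
}

checkBinary <- function(y, what = "response") {
  y <- as.numeric(y)
  if (any(!y %in% c(0, 1))) stop("'", what, "' must be binary 0/1")
  y
}

#' Overlap (concordance) response across traits
#'
#' The overlap verdict at a SNP is the product of its per-trait association
#' verdicts: only SNPs with evidence of association for every trait count as
#' overlap SNPs, since absence of evidence for one trait does not establish
#' absence of association.
#'
#' @param calls a binary matrix (SNPs x traits) or a list of equal-length
#'   binary vectors, one per trait (two or more).
#' @return binary vector of length m.
#' @examples
#' overlapResponse(list(c(1, 1, 0), c(1, 0, 0)))  # 1 0 0
#' @export
overlapResponse <- function(calls) {
  if (is.list(calls)) {
    if (length(calls) < 2L) stop("need calls for at least 2 traits")
    len <- lengths(calls)
    if (length(unique(len)) != 1L)
      stop("per-trait call vectors differ in length")
    calls <- do.call(cbind, calls)
  }
  if (ncol(calls) < 2L) stop("need calls for at least 2 traits")
  out <- checkBinary(calls[, 1L], what = "calls")
  for (j in seq.int(2L, ncol(calls)))
    out <- out * checkBinary(calls[, j], what = "calls")
  as.numeric(out)
}

#' Fit a per-trait marginal enrichment model
#'
#' Maximum-likelihood logistic regression of one trait's binary association
#' verdicts on the SNP covariate categories. A full marginal model -- one
#' containing every covariate considered for the overlap model -- is
#' recommended, because its fitted probabilities feed the chance-overlap
#' offset. All-zero covariate columns, and categories containing no
#' associated SNP (whose ML coefficient diverges to -Inf), are dropped with
#' a warning and listed in \code{dropped}; two-sided perfect separation
#' raises an error unless \code{penalized = TRUE} selects the Firth-type
#' fallback (an extension beyond the plain ML fit).
#'
#' @param y binary verdict vector (needs at least one 0 and one 1).
#' @param X binary covariate matrix, one column per category (no intercept
#'   column; one is added).
#' @param traitId label stored in the result.
#' @param penalized use the Firth-type penalised fit.
#' @return a [MarginalFit-class].
#' @examples
#' set.seed(1)
#' y <- rbinom(500, 1, 0.1)
#' X <- cbind(Q = rbinom(500, 1, 0.3))
#' fitMarginal(y, X)
#' @export
fitMarginal <- function(y, X, traitId = "trait", penalized = FALSE) {
  y <- checkBinary(y)
  X <- checkDesign(X, m = length(y))
  if (all(y == 0) || all(y == 1))
    stop("trait '", traitId, "': association verdicts have no variation ",
         "(need at least one associated and one unassociated SNP)")
  counts <- colSums(X * y)
  zero <- colSums(X) == 0
  # a category with no associated SNP has MLE -Inf for its coefficient;
  # drop it from this marginal fit (the analogue of the overlap model's
  # zero-overlap-count exclusion) rather than diverge
  noPos <- counts == 0 & !zero
  dropped <- as.character(colnames(X)[zero | noPos])
  if (any(zero))
    warning("trait '", traitId, "': dropping all-zero covariate column(s): ",
            paste(colnames(X)[zero], collapse = ", "))
  if (any(noPos))
    warning("trait '", traitId, "': dropping covariate(s) with no ",
            "associated SNPs: ", paste(colnames(X)[noPos], collapse = ", "))
  X <- X[, !(zero | noPos), drop = FALSE]
  Xd <- cbind("(Intercept)" = 1, X)
  f <- if (penalized) firthFit(Xd, y) else logisticFit(Xd, y)
  z <- f$coef / f$se
  new("MarginalFit", traitId = traitId, coef = f$coef, se = f$se,
      zValue = z, pOneSided = stats::pnorm(z, lower.tail = FALSE),
      pTwoSided = 2 * stats::pnorm(-abs(z)),
      fitted = pmin(pmax(f$fitted, 1e-12), 1 - 1e-12),
      counts = counts, nAssoc = sum(y), dropped = dropped)
}

#' Log-odds of chance overlap
#'
#' Given fitted per-trait association probabilities, returns the per-SNP
#' offset \code{log(prod_r p_r / (1 - prod_r p_r))}: the log-odds that a SNP
#' would be called associated with every trait if the traits' associations
#' were independent. Including this term as a fixed offset in the overlap
#' model corrects the enrichment test for chance overlap implied by the
#' marginal models. Probabilities are clipped to \code{[1e-12, 1 - 1e-12]}
#' before the transform so the offset stays finite.
#'
#' @param ... two or more numeric vectors of probabilities strictly in
#'   (0, 1), or a single list of such vectors.
#' @return numeric offset vector.
#' @examples
#' chanceOffset(0.5, 0.5)      # -log(3)
#' chanceOffset(0.04, 0.02)    # about -7.13
#' @export
chanceOffset <- function(...) {
  ps <- list(...)
  if (length(ps) == 1L && is.list(ps[[1]])) ps <- ps[[1]]
  if (length(ps) < 2L) stop("need fitted probabilities for at least 2 traits")
  len <- lengths(ps)
  if (length(unique(len)) != 1L)
    stop("probability vectors differ in length")
  for (p in ps)
    if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
      stop("probabilities must lie strictly in (0, 1)")
  pp <- Reduce(`*`, ps)
  pp <- pmin(pmax(pp, 1e-12), 1 - 1e-12)
  log(pp / (1 - pp))
}

#' Fit the offset-corrected overlap enrichment model
#'
#' Logistic regression of the overlap verdicts on the covariate categories
#' with a fixed per-SNP offset (the log-odds of chance overlap). Covariates
#' whose category contains no overlap-positive SNP are removed before the
#' fit and reported in \code{excludedCovariates}; their entries appear in the
#' results with estimate 0, p-value 1 and no standard error. Standard errors
#' come from the information matrix of the known-offset model; one-sided
#' p-values test positive enrichment (H1: beta > 0), and a two-sided p-value
#' is reported for the intercept.
#'
#' @param y binary overlap verdicts (must contain at least one 1).
#' @param X binary covariate matrix.
#' @param offset finite numeric offset vector, one entry per SNP. Use zeros
#'   for the uncorrected sensitivity analysis.
#' @param penalized use the Firth-type penalised fit.
#' @param varMethod \code{"known-offset"} (default) or \code{"jackknife"}
#'   for leave-one-out standard errors (much slower; intended for small
#'   panels).
#' @return an [OverlapFit-class].
#' @export
fitOverlap <- function(y, X, offset, penalized = FALSE,
                       varMethod = c("known-offset", "jackknife")) {
  varMethod <- match.arg(varMethod)
  y <- checkBinary(y)
  X <- checkDesign(X, m = length(y))
  if (length(offset) != length(y)) stop("'offset' length must match 'y'")
  if (any(!is.finite(offset))) stop("'offset' must be finite")
  if (all(y == 0))
    stop("no overlap variants: the overlap response is all zero")
  counts <- colSums(X * y)
  excluded <- as.character(colnames(X)[counts == 0])
  keep <- counts > 0
  Xk <- X[, keep, drop = FALSE]
  Xd <- cbind("(Intercept)" = 1, Xk)
  f <- if (penalized) firthFit(Xd, y, offset) else logisticFit(Xd, y, offset)
  se <- f$se
  if (varMethod == "jackknife") se <- jackknifeSE(Xd, y, offset, penalized)
  z <- f$coef / se
  new("OverlapFit", coef = f$coef, se = se, zValue = z,
      pOneSided = stats::pnorm(z, lower.tail = FALSE),
      pTwoSided = 2 * stats::pnorm(-abs(z)),
      offset = offset, excludedCovariates = excluded, counts = counts,
      nOverlap = sum(y), varMethod = varMethod)
}

# Leave-one-out jackknife SEs for the overlap model; O(m) refits, so only
# sensible for small panels. Provided as an optional hook -- the default
# known-offset SEs are what the method reports.
jackknifeSE <- function(Xd, y, offset, penalized = FALSE) {
  m <- length(y)
  coefs <- matrix(NA_real_, m, ncol(Xd))
  for (i in seq_len(m)) {
    f <- if (penalized) firthFit(Xd[-i, , drop = FALSE], y[-i], offset[-i])
         else logisticFit(Xd[-i, , drop = FALSE], y[-i], offset[-i])
    coefs[i, ] <- f$coef
  }
  bar <- colMeans(coefs)
  se <- sqrt((m - 1) / m * colSums(sweep(coefs, 2, bar)^2))
  stats::setNames(se, colnames(Xd))
}

#' Corrected overlap and marginal enrichment test
#'
#' Runs the full two-stage analysis on two or more traits' summary
#' statistics: (1) classify each SNP's association with each trait by
#' approximate Bayes factor; (2) fit a full marginal logistic enrichment
#' model per trait; (3) form the per-SNP log-odds of chance overlap from the
#' fitted marginal probabilities; (4) fit the overlap model with that offset
#' and test each covariate for positive enrichment of shared-associated
#' SNPs. Inputs are assumed to be LD-clumped already (see [clumpVariants()]).
#' With more than two traits the overlap verdict is the product over all
#' traits and the offset uses the product of all fitted marginals; this
#' R-trait generalisation is experimental (calibration has only been studied
#' for trait pairs).
#'
#' @param statsList named list of per-trait summary-statistic data frames
#'   (columns \code{snp}, \code{beta}, \code{se}).
#' @param annotations binary annotation matrix with SNP ids as rownames (or
#'   a data.frame whose first column is \code{snp}). SNPs present in the
#'   summary statistics but absent here get all-zero annotation rows.
#' @param rule decision rule for classification, default
#'   \code{bfDecisionRule()}.
#' @param includeOffset set \code{FALSE} for the sensitivity analysis that
#'   ignores the marginal distributions (offset excluded).
#' @param minCategoryProp small-category guard: categories whose proportion
#'   of positive SNPs falls below this bound are excluded up front. Default
#'   2.5e-4.
#' @param twoSidedLargeCategories also report two-sided overlap p-values as
#'   primary for categories covering at least \code{largeCategoryProp} of
#'   SNPs (two-sided p-values are reported for every term regardless; this
#'   flag only marks intent and is recorded in the results).
#' @param largeCategoryProp bound defining a large category. Default 0.02.
#' @param penalized use the Firth-type penalised fits.
#' @param varMethod overlap-model variance method, see [fitOverlap()].
#' @param verbose report SNP and category filtering counts.
#' @return a [CometFit-class].
#' @examples
#' cfg <- simConfig(m = 4000, p1 = 0.05, p2 = 0.05, p12 = 0.005,
#'                  categoryProps = c(Q1 = 0.5, Q5 = 0.2))
#' sp <- simulateStudyPair(cfg, seed = 7)
#' fit <- comet(studyStats(sp), studyAnnotations(sp), verbose = FALSE)
#' resultsTable(fit)
#' @export
comet <- function(statsList, annotations, rule = bfDecisionRule(),
                  includeOffset = TRUE, minCategoryProp = 2.5e-4,
                  twoSidedLargeCategories = FALSE, largeCategoryProp = 0.02,
                  penalized = FALSE,
                  varMethod = c("known-offset", "jackknife"),
                  verbose = TRUE) {
  varMethod <- match.arg(varMethod)
  cm <- callMatrix(statsList, rule, verbose = verbose)
  m <- length(cm$snp)
  X <- alignAnnotations(annotations, cm$snp, verbose = verbose)

  prop <- colMeans(X)
  guard <- prop < minCategoryProp
  droppedCategories <- colnames(X)[guard]
  if (any(guard)) {
    if (verbose)
      message("small-category guard (< ", minCategoryProp,
              " of SNPs): excluding ",
              paste(droppedCategories, collapse = ", "))
    X <- X[, !guard, drop = FALSE]
  }
  if (ncol(X) == 0L) stop("no covariate categories left to test")

  traits <- colnames(cm$calls)
  mfits <- lapply(traits, function(r)
    fitMarginal(cm$calls[, r], X, traitId = r, penalized = penalized))
  names(mfits) <- traits

  off <- if (includeOffset)
    chanceOffset(lapply(mfits, slot, "fitted")) else rep(0, m)
  yOv <- overlapResponse(cm$calls)
  ofit <- fitOverlap(yOv, X, off, penalized = penalized,
                     varMethod = varMethod)

  results <- buildResults(mfits, ofit, traits, colnames(X))
  new("CometFit", traits = traits, rule = rule, calls = cm$calls,
      marginalFits = mfits, overlapFit = ofit, results = results,
      droppedCategories = droppedCategories, nSNPs = m)
}

# Align an annotation matrix/data.frame to a SNP order; absent SNPs get
# all-zero rows (logged), unknown SNPs are ignored.
alignAnnotations <- function(annotations, snps, verbose = TRUE) {
  if (is.data.frame(annotations)) {
    rn <- as.character(annotations[[1]])
    annotations <- as.matrix(annotations[, -1, drop = FALSE])
    rownames(annotations) <- rn
  }
  X <- checkDesign(annotations)
  if (is.null(rownames(X))) {
    if (nrow(X) != length(snps))
      stop("annotation matrix without rownames must have one row per SNP")
    rownames(X) <- snps
    return(X)
  }
  idx <- match(snps, rownames(X))
  missing <- sum(is.na(idx))
  if (missing && verbose)
    message(missing, " SNP(s) absent from the annotations; ",
            "assigned all-zero annotation rows")
  out <- matrix(0, length(snps), ncol(X),
                dimnames = list(snps, colnames(X)))
  out[!is.na(idx), ] <- X[idx[!is.na(idx)], , drop = FALSE]
  out
}

# Long-format results table: marginal models then the overlap model.
buildResults <- function(mfits, ofit, traits, covariates) {
  rows <- list()
  addModel <- function(model, coef, se, z, p1s, p2s, counts, excluded) {
    terms <- c("(Intercept)", covariates)
    df <- data.frame(model = model, term = terms, estimate = NA_real_,
                     se = NA_real_, z = NA_real_, p_one_sided = NA_real_,
                     p_two_sided = NA_real_, count = NA_real_,
                     stringsAsFactors = FALSE)
    idx <- match(names(coef), terms)
    df$estimate[idx] <- coef
    df$se[idx] <- se
    df$z[idx] <- z
    df$p_one_sided[idx] <- p1s
    df$p_two_sided[idx] <- p2s
    df$count[match(names(counts), terms)] <- counts
    if (length(excluded)) {
      ex <- match(excluded, terms)
      df$estimate[ex] <- 0
      df$p_one_sided[ex] <- 1
      df$count[ex] <- 0
    }
    df
  }
  for (r in traits) {
    f <- mfits[[r]]
    rows[[r]] <- addModel(r, f@coef, f@se, f@zValue, f@pOneSided,
                          f@pTwoSided, f@counts, character(0))
  }
  rows[["overlap"]] <- addModel(paste0("overlap(",
                                       paste(traits, collapse = ","), ")"),
                                ofit@coef, ofit@se, ofit@zValue,
                                ofit@pOneSided, ofit@pTwoSided, ofit@counts,
                                ofit@excludedCovariates)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
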