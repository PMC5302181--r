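#' @include abf.R
NULL

#' Joint association metric across traits
#'
#' Summarises a SNP's per-trait association evidence into a single ranking
#' score for clumping. The default (\code{"min"}) is the minimum log10 ABF
#' across traits, which favours retention of SNPs with evidence in every
#' trait over SNPs with strong evidence for one trait only; ties are broken
#' downstream by the sum across traits. \code{"max"} and \code{"sum"} are
#' provided as pluggable alternatives.
#'
#' @param x numeric vector of per-trait log10 ABFs (length >= 2), or a
#'   numeric matrix with one row per SNP and one column per trait.
#' @param method \code{"min"} (default), \code{"sum"} or \code{"max"}.
#' @return a single score for a vector input, or a per-SNP vector of scores
#'   for a matrix input.
#' @examples
#' jointMetric(c(3, 3)) > jointMetric(c(6, 0.1))  # multi-trait SNP wins
#' @export
jointMetric <- function(x, method = c("min", "sum", "max")) {
  method <- match.arg(method)
  f <- switch(method, min = min, sum = sum, max = max)
  if (is.matrix(x)) {
    if (ncol(x) < 2L) stop("need evidence for at least 2 traits")
    if (any(!is.finite(x))) stop("non-finite association evidence")
    return(apply(x, 1L, f))
  }
  if (length(x) < 2L) stop("need evidence for at least 2 traits")
  if (any(!is.finite(x))) stop("non-finite association evidence")
  f(x)
}

#' Greedy LD clumping under a score ranking
#'
#' Reduces a SNP set to approximately independent variants: SNPs failing the
#' MAF filter are removed first, then SNPs are visited in decreasing score
#' order (ties broken by decreasing \code{total}, then increasing SNP id);
#' each visited SNP is retained and all not-yet-visited SNPs with
#' \code{r2 > r2Max} against it are discarded. Pairs absent from \code{ld}
#' are treated as r2 = 0 (independent), so sparse LD tables are fine.
#'
#' @param scores \code{data.frame} with columns \code{snp}, \code{score} and
#'   optionally \code{total} (the tie-break sum; defaults to 0).
#' @param ld \code{data.frame} of pairwise LD with columns \code{snpA},
#'   \code{snpB}, \code{r2} (first three columns are used positionally), or
#'   \code{NULL} for no LD.
#' @param r2Max retained pairs must have r2 <= this bound. Default 0.1.
#' @param maf optional per-SNP minor allele frequencies: a named numeric
#'   vector or a \code{data.frame} with columns \code{snp}, \code{maf}.
#' @param mafMin retained SNPs must have MAF > this bound. Default 0.05.
#' @return character vector of retained SNP ids, with attribute
#'   \code{"nFilteredMAF"} giving the number of SNPs removed by the MAF
#'   filter.
#' @examples
#' sc <- data.frame(snp = c("a", "b", "c"), score = c(3, 2, 1))
#' ld <- data.frame(snpA = c("a", "a", "b"), snpB = c("b", "c", "c"),
#'                  r2 = c(0.5, 0.5, 0.5))
#' greedyClump(sc, ld)  # only "a" survives a fully correlated clump
#' @export
greedyClump <- function(scores, ld = NULL, r2Max = 0.1, maf = NULL,
                        mafMin = 0.05) {
  if (!is.data.frame(scores) || !all(c("snp", "score") %in% names(scores)))
    stop("'scores' must be a data.frame with columns 'snp' and 'score'")
  if (anyDuplicated(scores$snp)) stop("duplicated SNP ids in 'scores'")
  total <- if ("total" %in% names(scores)) scores$total else
    rep(0, nrow(scores))
  snp <- as.character(scores$snp)
  score <- scores$score

  nFiltered <- 0L
  if (!is.null(maf)) {
    if (is.data.frame(maf)) {
      if (!all(c("snp", "maf") %in% names(maf)))
        stop("'maf' data.frame needs columns 'snp' and 'maf'")
      maf <- stats::setNames(maf$maf, maf$snp)
    }
    mafv <- maf[snp]
    if (any(is.na(mafv)))
      stop("MAF missing for SNP(s): ",
           paste(utils::head(snp[is.na(mafv)], 5), collapse = ", "))
    keep <- mafv > mafMin
    nFiltered <- sum(!keep)
    snp <- snp[keep]; score <- score[keep]; total <- total[keep]
  }

  adj <- list()
  if (!is.null(ld) && nrow(ld) > 0) {
    a <- as.character(ld[[1]]); b <- as.character(ld[[2]]); r2 <- ld[[3]]
    if (any(!is.finite(r2)) || any(r2 < 0) || any(r2 > 1))
      stop("r2 values must lie in [0, 1]")
    hot <- r2 > r2Max & a %in% snp & b %in% snp
    if (any(hot))
      adj <- split(c(b[hot], a[hot]), c(a[hot], b[hot]))
  }

  ord <- order(-score, -total, snp)
  state <- stats::setNames(rep.int(0L, length(snp)), snp)  # 0 free 1 keep -1 drop
  for (id in snp[ord]) {
    if (state[[id]] != 0L) next
    state[[id]] <- 1L
    nb <- adj[[id]]
    if (!is.null(nb)) {
      free <- nb[state[nb] == 0L]
      if (length(free)) state[free] <- -1L
    }
  }
  retained <- snp[state[snp] == 1L]
  attr(retained, "nFilteredMAF") <- nFiltered
  retained
}

#' Clump multi-trait summary statistics in one call
#'
#' Convenience pipeline: intersect the per-trait summary statistics, compute
#' log10 ABFs, score each SNP with the joint association metric (minimum
#' across traits, sum as tie-break) and run [greedyClump()]. Clumping only
#' needs to be done once per trait set; the retained ids can then be used to
#' subset the inputs of [comet()] for any covariate set.
#'
#' @param statsList named list of per-trait summary-statistic data frames.
#' @param ld pairwise LD table, as in [greedyClump()].
#' @param maf per-SNP MAF, as in [greedyClump()].
#' @param rule a [BFDecisionRule-class]; only \code{priorSd} is used here.
#' @param r2Max,mafMin clumping thresholds (defaults 0.1 and 0.05).
#' @param metric joint metric variant passed to [jointMetric()].
#' @param verbose report filtering counts.
#' @return character vector of retained SNP ids (see [greedyClump()]).
#' @export
clumpVariants <- function(statsList, ld = NULL, maf = NULL,
                          rule = bfDecisionRule(), r2Max = 0.1,
                          mafMin = 0.05, metric = "min", verbose = TRUE) {
  h <- harmoniseStats(statsList, verbose = verbose)
  abf <- vapply(seq_len(ncol(h$beta)),
                function(j) log10ABF(h$beta[, j], h$se[, j], rule@priorSd),
                numeric(length(h$snp)))
  scores <- data.frame(snp = h$snp,
                       score = jointMetric(abf, method = metric),
                       total = rowSums(abf), stringsAsFactors = FALSE)
  out <- greedyClump(scores, ld = ld, r2Max = r2Max, maf = maf,
                     mafMin = mafMin)
  if (verbose)
    message(length(h$snp), " SNPs in all traits; ",
            attr(out, "nFilteredMAF"), " removed by MAF filter; ",
            length(out), " retained after clumping")
  out
}
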