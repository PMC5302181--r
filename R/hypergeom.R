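#' @include comet-fit.R
NULL

#' Hypergeometric (DAVID-style) enrichment p-value
#'
#' Upper-tail probability P(X >= k) for X ~ Hypergeometric(N, K, n): given
#' \code{n} overlap-associated SNPs drawn from a panel of \code{N} SNPs of
#' which \code{K} belong to the category, the probability of seeing at least
#' the attained in-category count \code{k}. This is the single-trait-style
#' annotation-enrichment test that conditions on the number of associated
#' SNPs and treats annotation status as random -- the reverse conditioning of
#' the offset-corrected overlap model -- and it is provided as the comparator
#' whose behaviour on shared variants the corrected test improves on.
#'
#' @param N total SNPs in the panel.
#' @param K SNPs in the category.
#' @param n overlap-associated SNPs.
#' @param k overlap-associated SNPs in the category.
#' @return the upper-tail probability. Vectorised over all arguments.
#' @examples
#' hypergeomEnrichmentP(10, 5, 5, 5)  # 1 / choose(10, 5)
#' hypergeomEnrichmentP(20, 4, 5, 0)  # 1
#' @export
hypergeomEnrichmentP <- function(N, K, n, k) {
  bad <- !is.finite(N) | !is.finite(K) | !is.finite(n) | !is.finite(k) |
    N != round(N) | K != round(K) | n != round(n) | k != round(k)
  if (any(bad)) stop("counts must be finite integers")
  if (any(K > N) || any(n > N) || any(k > pmin(K, n)) || any(k < 0) ||
      any(K < 0) || any(n < 0))
    stop("inconsistent counts: need 0 <= k <= min(K, n), K <= N, n <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric enrichment applied to overlap calls
#'
#' Convenience wrapper: forms the overlap SNP set from a call matrix, builds
#' the per-category 2x2 counts against an annotation matrix and returns the
#' upper-tail hypergeometric p-value for each category.
#'
#' @param calls m x R binary call matrix (SNPs x traits).
#' @param annotations m x K binary annotation matrix in the same SNP order.
#' @return \code{data.frame} with columns \code{covariate}, \code{N},
#'   \code{K}, \code{n}, \code{k}, \code{p}.
#' @export
hypergeomOverlapTest <- function(calls, annotations) {
  X <- checkDesign(annotations)
  yOv <- overlapResponse(calls)
  if (nrow(X) != length(yOv))
    stop("'annotations' and 'calls' disagree on the number of SNPs")
  N <- length(yOv)
  K <- colSums(X)
  n <- sum(yOv)
  k <- colSums(X * yOv)
  data.frame(covariate = colnames(X), N = N, K = K, n = n, k = k,
             p = hypergeomEnrichmentP(rep(N, ncol(X)), K, rep(n, ncol(X)), k),
             row.names = NULL, stringsAsFactors = FALSE)
}
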