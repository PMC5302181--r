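# Independent quadrature oracle for the ABF: integrate the normal likelihood
# of betaHat over the N(0, W) effect prior and divide by the null likelihood.
# Kept free of the closed form it checks.
quadratureLog10ABF <- function(betaHat, se, priorSd) {
  lik <- function(b) stats::dnorm(betaHat, mean = b, sd = se)
  marg <- stats::integrate(function(b) lik(b) * stats::dnorm(b, 0, priorSd),
                           lower = -Inf, upper = Inf, rel.tol = 1e-12)$value
  log10(marg / lik(0))
}

# Brute-force hypergeometric upper tail from binomial coefficients.
bruteHyperUpper <- function(N, K, n, k) {
  js <- seq.int(k, min(K, n))
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Closed-form 2x2 logistic algebra: category x outcome counts
# (a = in-category positives, b = in-category negatives,
#  c = out-category positives, d = out-category negatives).
logOR2x2 <- function(a, b, c, d) log(a * d / (b * c))
baselineLogOdds2x2 <- function(c, d) log(c / d)

# Expand a 2x2 table into per-observation response/covariate vectors.
expand2x2 <- function(a, b, c, d) {
  list(y = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d)),
       x = cbind(Q = c(rep(1, a + b), rep(0, c + d))))
}

# Small synthetic two-trait summary-statistic set with planted signals.
makeToyPair <- function(m = 400, seed = 42, nShared = 8, nOnly = 10,
                        b = 1.2, se = 0.12) {
  set.seed(seed)
  snp <- sprintf("rs%04d", seq_len(m))
  eff1 <- eff2 <- numeric(m)
  shared <- seq_len(nShared)
  eff1[shared] <- eff2[shared] <- b
  eff1[nShared + seq_len(nOnly)] <- b
  eff2[nShared + nOnly + seq_len(nOnly)] <- b
  list(
    trait1 = data.frame(snp = snp, beta = eff1 + rnorm(m, 0, se), se = se,
                        stringsAsFactors = FALSE),
    trait2 = data.frame(snp = snp, beta = eff2 + rnorm(m, 0, se), se = se,
                        stringsAsFactors = FALSE))
}

makeToyAnnotations <- function(m = 400, seed = 43,
                               props = c(Q1 = 0.5, Q5 = 0.2)) {
  set.seed(seed)
  X <- vapply(props, function(p) rbinom(m, 1L, p), integer(m))
  rownames(X) <- sprintf("rs%04d", seq_len(m))
  X
}
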