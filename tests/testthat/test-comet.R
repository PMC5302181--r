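test_that("overlap response is the elementwise product of verdicts", {
  expect_equal(overlapResponse(list(c(1, 1, 0), c(1, 0, 0))), c(1, 0, 0))
  expect_equal(overlapResponse(list(c(1, 1), c(0, 0))), c(0, 0))
  expect_equal(overlapResponse(list(c(1, 1), c(1, 1), c(1, 0))), c(1, 0))
  expect_error(overlapResponse(list(c(1, 0), c(1, 0, 1))), "length")
  expect_error(overlapResponse(list(c(1, 2), c(1, 0))), "binary")
})

test_that("intercept-only marginal fit recovers logit of the mean", {
  y <- c(rep(1, 4), rep(0, 96))  # mean 0.04
  X <- matrix(numeric(0), nrow = 100, ncol = 0)
  fit <- fitMarginal(y, X)
  expect_equal(unname(coef(fit)[1]), qlogis(0.04), tolerance = 1e-6)
})

test_that("single-covariate marginal fit equals 2x2 log-odds algebra", {
  # a,b: in-category assoc/non-assoc; c,d: out-of-category
  tab <- list(a = 30, b = 170, c = 25, d = 775)
  dat <- expand2x2(tab$a, tab$b, tab$c, tab$d)
  fit <- fitMarginal(dat$y, dat$x)
  expect_equal(unname(coef(fit)["Q"]),
               logOR2x2(tab$a, tab$b, tab$c, tab$d), tolerance = 1e-6)
  expect_equal(unname(coef(fit)["(Intercept)"]),
               baselineLogOdds2x2(tab$c, tab$d), tolerance = 1e-6)
  expect_equal(unname(enrichmentCounts(fit)["Q"]), tab$a)
  # one-sided p consistent with the Wald z
  z <- fit@zValue["Q"]
  expect_equal(unname(fit@pOneSided["Q"]), unname(pnorm(z, lower.tail = FALSE)))
})

test_that("degenerate marginal designs are rejected or repaired", {
  y <- rep(c(1, 0), each = 25)
  expect_error(fitMarginal(rep(0, 10), cbind(Q = rep(0:1, 5))),
               "no variation")
  # response identical to the covariate: perfect separation
  expect_error(fitMarginal(y, cbind(Q = y)), "separation")
  # all-zero column dropped with warning
  expect_warning(f <- fitMarginal(y, cbind(Q = rep(0, 50))), "all-zero")
  expect_identical(f@dropped, "Q")
  # category with zero associated SNPs dropped, counts still reported
  X <- cbind(Q = c(rep(0, 25), rep(1, 10), rep(0, 15)))
  expect_warning(f2 <- fitMarginal(y, X), "no associated")
  expect_identical(f2@dropped, "Q")
  expect_equal(unname(f2@counts["Q"]), 0)
})

test_that("Firth-penalised fallback fits separated data finitely", {
  y <- rep(c(1, 0), each = 25)
  fit <- fitMarginal(y, cbind(Q = y), penalized = TRUE)
  expect_true(all(is.finite(coef(fit))))
  expect_true(all(is.finite(fit@se)))
})

test_that("chance offset is the log-odds of the product probability", {
  expect_equal(chanceOffset(0.5, 0.5), log(0.25 / 0.75))
  expect_equal(chanceOffset(0.04, 0.02), log(8e-4 / (1 - 8e-4)))
  expect_equal(round(chanceOffset(0.04, 0.02), 3), -7.13)
  # monotone decreasing as the product shrinks
  p <- 10^seq(-1, -5, length.out = 9)
  off <- chanceOffset(p, rep(0.5, 9))
  expect_true(all(diff(off) < 0))
  expect_error(chanceOffset(c(0, 0.5), c(0.5, 0.5)), "strictly in")
  expect_error(chanceOffset(0.5, c(0.5, 0.4)), "length")
})

test_that("overlap fit with constant offset matches 2x2 closed forms", {
  tab <- list(a = 12, b = 188, c = 20, d = 1780)
  dat <- expand2x2(tab$a, tab$b, tab$c, tab$d)
  off <- -3.2
  fit <- fitOverlap(dat$y, dat$x, rep(off, length(dat$y)))
  # constant offset shifts only the intercept in the saturated model
  expect_equal(unname(coef(fit)["Q"]),
               logOR2x2(tab$a, tab$b, tab$c, tab$d), tolerance = 1e-6)
  expect_equal(unname(coef(fit)["(Intercept)"]),
               baselineLogOdds2x2(tab$c, tab$d) - off, tolerance = 1e-6)
  expect_equal(unname(enrichmentCounts(fit)["Q"]), tab$a)
})

test_that("zero-overlap-count covariates are excluded, not fitted", {
  set.seed(8)
  m <- 500
  y <- rbinom(m, 1, 0.05)
  X <- cbind(big = rbinom(m, 1, 0.5), empty = 0)
  X[which(y == 0)[1:10], "empty"] <- 1  # members exist, never overlap-positive
  fit <- fitOverlap(y, X, rep(-2, m))
  expect_identical(excludedCovariates(fit), "empty")
  expect_equal(unname(enrichmentCounts(fit)["empty"]), 0)
  expect_false("empty" %in% names(coef(fit)))
  expect_error(fitOverlap(rep(0, 10), cbind(Q = rep(0:1, 5)), rep(0, 10)),
               "no overlap")
})

test_that("offset-only overlap intercept shrinks to zero under chance-only overlap", {
  # independent verdicts per trait: overlap is exactly chance, so with the
  # true marginal probabilities in the offset the intercept MLE is near 0
  set.seed(21)
  m <- 60000
  p1 <- 0.05; p2 <- 0.04
  y1 <- rbinom(m, 1, p1); y2 <- rbinom(m, 1, p2)
  yo <- overlapResponse(list(y1, y2))
  off <- chanceOffset(rep(p1, m), rep(p2, m))
  fit <- fitOverlap(yo, matrix(numeric(0), m, 0), off)
  expect_lt(abs(unname(coef(fit)[1])), 3 * unname(fit@se[1]))
  expect_lt(abs(unname(coef(fit)[1])), 0.35)
})

test_that("comet orchestrates the two stages and is deterministic", {
  stats <- makeToyPair(m = 600, seed = 31, nShared = 12, nOnly = 15)
  ann <- makeToyAnnotations(m = 600, seed = 32)
  fit1 <- comet(stats, ann, verbose = FALSE)
  fit2 <- comet(stats, ann, verbose = FALSE)
  expect_identical(resultsTable(fit1), resultsTable(fit2))
  res <- resultsTable(fit1)
  expect_setequal(unique(res$model),
                  c("trait1", "trait2", "overlap(trait1,trait2)"))
  expect_setequal(res$term[res$model == "trait1"],
                  c("(Intercept)", "Q1", "Q5"))
  # marginal fit for trait1 ignores trait2 data entirely
  stats2 <- stats
  set.seed(99)
  stats2$trait2$beta <- rnorm(600, 0, stats2$trait2$se)
  fit3 <- comet(stats2, ann, verbose = FALSE)
  expect_equal(coef(marginalFits(fit1)$trait1),
               coef(marginalFits(fit3)$trait1))
  # overlap counts come from the product response
  calls <- associationCalls(fit1)
  yo <- overlapResponse(calls)
  expect_equal(overlapFit(fit1)@nOverlap, sum(yo))
})

test_that("no-offset mode drops the correction and changes the intercept", {
  stats <- makeToyPair(m = 600, seed = 51, nShared = 12, nOnly = 15)
  ann <- makeToyAnnotations(m = 600, seed = 52)
  withOff <- comet(stats, ann, verbose = FALSE)
  noOff <- comet(stats, ann, includeOffset = FALSE, verbose = FALSE)
  expect_true(all(overlapFit(noOff)@offset == 0))
  expect_gt(abs(coef(overlapFit(withOff))[1] - coef(overlapFit(noOff))[1]),
            1)
})

test_that("small-category guard removes ultra-rare covariates up front", {
  stats <- makeToyPair(m = 600, seed = 61)
  ann <- makeToyAnnotations(m = 600, seed = 62)
  ann <- cbind(ann, Qrare = c(1, rep(0, 599)))  # ~0.17% of SNPs
  fit <- comet(stats, ann, minCategoryProp = 0.01, verbose = FALSE)
  expect_true("Qrare" %in% fit@droppedCategories)
  expect_false("Qrare" %in% resultsTable(fit)$term)
})

test_that("error propagates when one trait has no associated SNPs", {
  stats <- makeToyPair(m = 200, seed = 71)
  stats$trait2$beta <- rnorm(200, 0, 0.01)  # nothing passes the threshold
  stats$trait2$se <- rep(1e6, 200)
  ann <- makeToyAnnotations(m = 200, seed = 72)
  expect_error(suppressWarnings(comet(stats, ann, verbose = FALSE)))
})

test_that("jackknife variance hook runs on a small panel", {
  tab <- expand2x2(8, 40, 10, 140)
  known <- fitOverlap(tab$y, tab$x, rep(-2, length(tab$y)))
  jack <- fitOverlap(tab$y, tab$x, rep(-2, length(tab$y)),
                     varMethod = "jackknife")
  expect_identical(coef(known), coef(jack))
  expect_true(all(is.finite(jack@se)))
  # same order of magnitude as the known-offset SEs
  expect_lt(max(abs(log(jack@se / known@se))), log(3))
})
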