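test_that("simulation configs are validated", {
  expect_s4_class(simConfig(m = 1000), "SimulationConfig")
  expect_error(simConfig(m = 1000, p12 = 0.1), "p12")
  expect_error(simConfig(m = 1000, categoryProps = c(Q1 = 1)), "(0, 1)")
  expect_error(simConfig(m = 1000, enrichedCategory = "Qx"), "category")
  expect_error(simConfig(m = 1000, p12Prime = 1e-4), "enrichedCategory")
  expect_error(simConfig(m = 1000, mafRange = c(0.5, 0.05)), "mafRange")
})

test_that("null enrichment identity holds for the reference Q5 setting", {
  cfg <- simConfig(enrichedCategory = "Q5")  # p12Prime left at its null value
  expect_equal(comet:::nullP12Prime(cfg), 5e-4 * 0.014)
  expect_equal(comet:::nullP12Prime(cfg), 7e-6)
})

test_that("annotation sampling hits configured proportions and reproduces", {
  cfg <- simConfig(m = 1e5)
  A1 <- simulateAnnotations(cfg, seed = 4)
  A2 <- simulateAnnotations(cfg, seed = 4)
  expect_identical(A1, A2)
  for (q in names(cfg@categoryProps)) {
    p <- cfg@categoryProps[[q]]
    expect_lt(abs(mean(A1[, q]) - p), 3 * sqrt(p * (1 - p) / 1e5) + 1e-9)
  }
})

test_that("causal assignment respects the configured proportions", {
  cfg <- simConfig(m = 50000)
  ann <- simulateAnnotations(cfg, seed = 14)
  tr <- assignCausal(cfg, ann, seed = 15)
  m <- cfg@m
  expect_lte(abs(sum(tr$shared) - m * cfg@p12), 1)
  expect_equal(sum(tr$causal1), round(m * cfg@p1))
  expect_equal(sum(tr$causal2), round(m * cfg@p2))
  expect_true(all(tr$causal1[tr$shared] & tr$causal2[tr$shared]))
  # disjoint trait-only sets keep the shared count at exactly the overlap
  expect_equal(sum(tr$causal1 & tr$causal2), sum(tr$shared))
})

test_that("enriched allocation places the required causal mass in-category", {
  cfg <- simConfig(m = 50000, enrichedCategory = "Q5", p12Prime = 1.5e-4)
  ann <- simulateAnnotations(cfg, seed = 24)
  tr <- assignCausal(cfg, ann, seed = 25)
  inQ5 <- ann[, "Q5"] == 1
  expect_gte(sum(tr$shared & inQ5), floor(cfg@m * cfg@p12Prime))
  # boundary: everything shared inside the category
  cfgAll <- simConfig(m = 20000, enrichedCategory = "Q5", p12Prime = 5e-4)
  annA <- simulateAnnotations(cfgAll, seed = 26)
  trA <- assignCausal(cfgAll, annA, seed = 27)
  expect_true(all(annA[trA$shared, "Q5"] == 1))
})

test_that("null allocation leaves category membership at its base rate", {
  # over replicates, shared-causal SNPs should fall in Q1 at the Q1
  # proportion: chi-square goodness of fit on the pooled counts
  cfg <- simConfig(m = 20000)
  inQ1 <- tot <- 0
  for (s in 1:20) {
    ann <- simulateAnnotations(cfg, seed = 100 + s)
    tr <- assignCausal(cfg, ann, seed = 200 + s)
    inQ1 <- inQ1 + sum(ann[tr$shared, "Q1"])
    tot <- tot + sum(tr$shared)
  }
  expect_gt(stats::chisq.test(c(inQ1, tot - inQ1),
                              p = c(0.515, 0.485))$p.value, 0.001)
})

test_that("summary statistics follow the asymptotic sampling model", {
  cfg <- simConfig(m = 40000)
  sp <- simulateStudyPair(cfg, seed = 33)
  st <- studyStats(sp)
  tr <- studyTruth(sp)
  # se formula: case-control with equal arms
  expect_equal(st$trait1$se,
               sqrt(2 / (cfg@N1 * tr$maf * (1 - tr$maf))))
  # null SNPs: realised call rate matches the analytic tail probability
  # implied by inverting the ABF threshold per SNP (independent 1-D root)
  rule <- bfDecisionRule()
  nullIdx <- !tr$causal1
  zCut <- vapply(which(nullIdx)[1:2000], function(i) {
    se <- st$trait1$se[i]
    stats::uniroot(function(z)
      log10ABF(z * se, se, rule@priorSd) - rule@log10Threshold,
      c(0, 50), tol = 1e-10)$root
  }, numeric(1))
  expected <- mean(2 * stats::pnorm(-zCut))
  called <- classifyAssociations(st$trait1[nullIdx, ], rule)$y
  expect_lt(abs(mean(called) - expected),
            3 * sqrt(expected * (1 - expected) / sum(nullIdx)) + 0.002)
  # a causal SNP with |b|/se = 6 is called essentially always
  se0 <- 0.06
  big <- data.frame(snp = sprintf("c%03d", 1:500),
                    beta = 6 * se0 + rnorm(500, 0, se0), se = se0)
  expect_gt(mean(classifyAssociations(big, rule)$y), 0.99)
})

test_that("shared-causal effects are sign-concordant across traits", {
  cfg <- simConfig(m = 30000)
  sp <- simulateStudyPair(cfg, seed = 44)
  tr <- studyTruth(sp)
  st <- studyStats(sp)
  sh <- tr$shared
  # with bMin = 0.2 and small SEs, the observed betas carry the true sign
  agree <- sign(st$trait1$beta[sh]) == sign(st$trait2$beta[sh])
  expect_gt(mean(agree), 0.9)
})

test_that("independent studies give uncorrelated null z-scores; shared subjects correlate them", {
  cfg <- simConfig(m = 30000)
  sp <- simulateStudyPair(cfg, seed = 55)
  tr <- studyTruth(sp)
  st <- studyStats(sp)
  nullBoth <- !tr$causal1 & !tr$causal2
  z1 <- st$trait1$beta[nullBoth] / st$trait1$se[nullBoth]
  z2 <- st$trait2$beta[nullBoth] / st$trait2$se[nullBoth]
  expect_lt(abs(cor(z1, z2)), 3 / sqrt(sum(nullBoth)))
  cfgSh <- simConfig(m = 30000, sharedIndividuals = 0.5)
  spSh <- simulateStudyPair(cfgSh, seed = 56)
  trS <- studyTruth(spSh)
  nullS <- !trS$causal1 & !trS$causal2
  zs1 <- spSh@stats$trait1$beta[nullS] / spSh@stats$trait1$se[nullS]
  zs2 <- spSh@stats$trait2$beta[nullS] / spSh@stats$trait2$se[nullS]
  expect_gt(cor(zs1, zs2), 0.4)
})

test_that("whole study pairs are reproducible under a fixed seed", {
  cfg <- simConfig(m = 5000, seed = 77)
  sp1 <- simulateStudyPair(cfg)
  sp2 <- simulateStudyPair(cfg)
  expect_identical(sp1@stats, sp2@stats)
  expect_identical(sp1@annotations, sp2@annotations)
  expect_identical(sp1@truth, sp2@truth)
})

test_that("quantitative study type uses the quantitative se formula", {
  cfg <- simConfig(m = 2000, studyType = "quantitative")
  sp <- simulateStudyPair(cfg, seed = 88)
  tr <- studyTruth(sp)
  expect_equal(studyStats(sp)$trait2$se,
               1 / sqrt(2 * cfg@N2 * tr$maf * (1 - tr$maf)))
})
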