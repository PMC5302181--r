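test_that("joint metric favours multi-trait evidence", {
  expect_gt(jointMetric(c(3, 3)), jointMetric(c(6, 0.1)))
  expect_equal(jointMetric(c(0.695, 0.695)), 0.695)
  expect_error(jointMetric(numeric(0)), "at least 2")
  expect_error(jointMetric(c(1, NA)), "finite")
  expect_equal(jointMetric(c(2, 5), method = "sum"), 7)
  expect_equal(jointMetric(c(2, 5), method = "max"), 5)
})

test_that("(min, sum) ranking orders SNPs as intended", {
  abf <- rbind(a = c(2, 1), b = c(1.5, 1.5), c = c(4, 0.9))
  sc <- data.frame(snp = rownames(abf), score = jointMetric(abf),
                   total = rowSums(abf))
  ord <- sc$snp[order(-sc$score, -sc$total, sc$snp)]
  expect_identical(ord, c("b", "a", "c"))
})

test_that("greedy clumping matches hand-traced toys", {
  # fully correlated clump: only the top-scoring SNP survives
  sc <- data.frame(snp = c("s1", "s2", "s3"), score = c(3, 2, 1))
  ldFull <- data.frame(snpA = c("s1", "s1", "s2"),
                       snpB = c("s2", "s3", "s3"), r2 = 0.5)
  expect_identical(sort(greedyClump(sc, ldFull)), "s1")
  # no LD: everything survives
  expect_setequal(greedyClump(sc, NULL), c("s1", "s2", "s3"))
  expect_setequal(greedyClump(sc, ldFull[0, ]), c("s1", "s2", "s3"))
  # 5-SNP toy, hand-simulated greedy pass:
  # visit 1 (drop 2), visit 3, visit 4 (r2 .05 with 5 is below .1), visit 5
  sc5 <- data.frame(snp = paste0("s", 1:5), score = 5:1)
  ld5 <- data.frame(snpA = c("s1", "s2", "s4"), snpB = c("s2", "s3", "s5"),
                    r2 = c(0.3, 0.3, 0.05))
  expect_setequal(greedyClump(sc5, ld5), c("s1", "s3", "s4", "s5"))
  expect_error(greedyClump(sc5, data.frame(a = "s1", b = "s2", r2 = 1.2)),
               "\\[0, 1\\]")
})

test_that("clumping output is order-invariant and greedily maximal", {
  set.seed(5)
  n <- 60
  snp <- sprintf("v%02d", seq_len(n))
  sc <- data.frame(snp = snp, score = round(runif(n), 2),
                   total = runif(n))
  pairs <- t(combn(n, 2))
  keepPair <- runif(nrow(pairs)) < 0.1
  ld <- data.frame(snpA = snp[pairs[keepPair, 1]],
                   snpB = snp[pairs[keepPair, 2]],
                   r2 = runif(sum(keepPair)))
  ret1 <- greedyClump(sc, ld)
  perm <- sample(n)
  ret2 <- greedyClump(sc[perm, ], ld[sample(nrow(ld)), ])
  expect_setequal(ret1, ret2)
  # maximality: every discarded SNP conflicts with some retained SNP
  r2lookup <- new.env()
  for (i in seq_len(nrow(ld))) {
    assign(paste(ld$snpA[i], ld$snpB[i]), ld$r2[i], envir = r2lookup)
    assign(paste(ld$snpB[i], ld$snpA[i]), ld$r2[i], envir = r2lookup)
  }
  conflicts <- function(a, b) {
    key <- paste(a, b)
    exists(key, envir = r2lookup) && get(key, envir = r2lookup) > 0.1
  }
  for (d in setdiff(snp, ret1))
    expect_true(any(vapply(ret1, conflicts, logical(1), a = d)),
                label = paste("discarded", d, "conflicts with retained set"))
  # retained set internally independent
  for (a in ret1) for (b in ret1)
    if (a != b) expect_false(conflicts(a, b))
})

test_that("MAF filter applies before clumping and is reported", {
  sc <- data.frame(snp = c("s1", "s2", "s3"), score = c(3, 2, 1))
  ld <- data.frame(snpA = "s2", snpB = "s3", r2 = 0.9)
  maf <- c(s1 = 0.01, s2 = 0.2, s3 = 0.3)
  ret <- greedyClump(sc, ld, maf = maf)
  # s1 fails MAF despite top score; s2 beats s3 in the clump
  expect_setequal(as.character(ret), "s2")
  expect_identical(attr(ret, "nFilteredMAF"), 1L)
  expect_error(greedyClump(sc, ld, maf = maf[1:2]), "MAF missing")
})

test_that("clumpVariants runs the full pipeline on summary statistics", {
  stats <- makeToyPair(m = 50, seed = 9)
  ld <- data.frame(snpA = "rs0001", snpB = "rs0002", r2 = 0.8)
  maf <- stats::setNames(rep(0.3, 50), sprintf("rs%04d", 1:50))
  ret <- suppressMessages(
    clumpVariants(stats, ld = ld, maf = maf, verbose = FALSE))
  expect_true(xor("rs0001" %in% ret, "rs0002" %in% ret))
  expect_length(ret, 49)
})
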