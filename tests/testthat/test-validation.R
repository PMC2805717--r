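test_that("expression permutation shuffles samples jointly", {
  set.seed(1)
  v <- matrix(rnorm(8 * 20), nrow = 8,
              dimnames = list(paste0("s", 1:8), NULL))
  e <- makeExpression(v)
  p <- permuteExpression(e, seed = 3)
  pv <- exprValues(p)
  # per-trait value multisets unchanged
  for (i in seq_len(nrow(pv)))
    expect_equal(sort(unname(pv[i, ])), sort(unname(exprValues(e)[i, ])))
  # trait-trait correlation structure intact
  expect_lt(max(abs(cor(t(pv)) - cor(t(exprValues(e))))), 1e-12)
  # determinism and non-triviality
  expect_identical(exprValues(permuteExpression(e, seed = 3)), pv)
  expect_false(identical(pv, exprValues(e)))

  # 2 samples: swap or identity, both occur over seeds
  e2 <- makeExpression(matrix(c(1, 2), 2, 1,
                              dimnames = list(c("a", "b"), NULL)))
  outs <- vapply(1:40, function(s)
    exprValues(permuteExpression(e2, s))[1, 1], numeric(1))
  expect_setequal(unique(outs), c(1, 2))
})

test_that("empirical FDR cutoffs behave at the extremes and stay monotone", {
  set.seed(2)
  obs <- runif(500)
  nulls <- lapply(1:5, function(i) runif(500))
  # level 1: everything discovered at the maximum observed p
  all <- estimateFdrCutoffs(obs, nulls, fdrLevel = 1)
  expect_equal(all$pCutoff, max(obs))
  expect_equal(all$nDiscoveries, 500L)

  # monotone in the level on a signal-bearing input
  obs2 <- c(runif(50, 0, 1e-6), runif(450))
  dec <- lapply(c(0.05, 0.1, 0.2, 0.5), function(l)
    estimateFdrCutoffs(obs2, nulls, l))
  nd <- vapply(dec, `[[`, integer(1), "nDiscoveries")
  pc <- vapply(dec, `[[`, numeric(1), "pCutoff")
  expect_false(is.unsorted(nd))
  expect_false(is.unsorted(pc[!is.na(pc)]))

  # empty class: a decision with zero discoveries
  none <- estimateFdrCutoffs(numeric(0), nulls, 0.1)
  expect_equal(none$nDiscoveries, 0L)
})

test_that("null draws yield no discoveries; spiked signals are recovered", {
  # the chance of a spurious discovery at the global null decays as
  # roughly 1/(B+1) in the permutation count B, so calibration checks
  # use a generous B
  zero <- 0L
  for (s in 1:20) {
    set.seed(200 + s)
    obs <- runif(300)
    nulls <- lapply(1:50, function(i) runif(300))
    d <- estimateFdrCutoffs(obs, nulls, 0.1)
    if (d$nDiscoveries == 0) zero <- zero + 1L
  }
  expect_gte(zero, 18L)   # >= 90% of seeds

  rec <- fdp <- numeric(20)
  for (s in 1:20) {
    set.seed(300 + s)
    obs <- c(runif(100, 0, 1e-9), runif(9900))
    nulls <- lapply(1:5, function(i) runif(10000))
    d <- estimateFdrCutoffs(obs, nulls, 0.1)
    found <- which(d$discoveries)
    rec[s] <- sum(found <= 100)
    fdp[s] <- if (length(found)) mean(found > 100) else 0
  }
  expect_gte(mean(rec), 95)
  expect_lte(mean(fdp), 0.2)
})

test_that("expected false counts and relative power reproduce the arithmetic", {
  expect_identical(expectedFalseCount(0.10, 65), 6L)
  expect_identical(expectedFalseCount(0.10, 33), 3L)
  expect_identical(expectedFalseCount(0.3, 0), 0L)
  expect_equal(relativePower(65, 18), 65 / 18)
  expect_equal(relativePower(5, 5), 1)
  expect_equal(relativePower(65, 18, fdrLevel = 0.3),
               relativePower(65, 18, fdrLevel = 0.1))
  expect_error(relativePower(5, 0), "positive")
})

test_that("overlap enrichment matches the hypergeometric tail", {
  u <- sprintf("t%02d", 1:20)
  a <- u[1:5]
  b <- c(u[1:4], u[10])
  res <- overlapEnrichment(a, b, u)
  expect_identical(res$overlap, 4L)
  # exact enumeration: sum_{k>=4} C(5,k) C(15,5-k) / C(20,5)
  pExact <- (choose(5, 4) * choose(15, 1) + choose(5, 5)) / choose(20, 5)
  expect_equal(res$p, pExact, tolerance = 1e-12)

  # identical sets in a large universe: overlap maximal, p tiny
  u2 <- sprintf("g%03d", 1:500)
  res2 <- overlapEnrichment(u2[1:30], u2[1:30], u2)
  expect_identical(res2$overlap, 30L)
  expect_lt(res2$p, 1e-30)

  # disjoint halves: no overlap, p about 1
  res3 <- overlapEnrichment(u2[1:250], u2[251:500], u2)
  expect_identical(res3$overlap, 0L)
  expect_gt(res3$p, 0.99)
  expect_error(overlapEnrichment(a, b, character(0)), "empty")
})

test_that("allele-frequency disparity summaries match hand computation", {
  # A: 10 alt / 30 ref alleles; B: 30 alt / 10 ref -> diff 0.5, chisq 20
  dA <- matrix(c(rep(1, 10), rep(0, 10)), nrow = 1,
               dimnames = list("rs1", NULL))
  dB <- matrix(c(rep(2, 10), rep(1, 10)), nrow = 1,
               dimnames = list("rs1", NULL))
  snps <- data.frame(id = "rs1", chrom = "chr1", pos = 1L,
                     ref = "A", alt = "G")
  gA <- GenotypeData(dA, snps, sampleIds = paste0("a", 1:20))
  gB <- GenotypeData(dB, snps, sampleIds = paste0("b", 1:20))
  res <- alleleFreqDisparity(gA, gB)
  expect_equal(unname(res$freqDiff), 0.5)
  expect_equal(unname(res$chisqP), pchisq(20, 1, lower.tail = FALSE))
  expect_equal(res$fractionAboveThreshold, 1)

  # identical cohorts: all zero, all p = 1
  same <- alleleFreqDisparity(gA, gA)
  expect_equal(unname(same$freqDiff), 0)
  expect_equal(unname(same$chisqP), 1)
  expect_equal(same$fractionAboveThreshold, 0)
})

test_that("drifted populations show the expected frequency disparity", {
  cfg <- simulationConfig(fst = 0.2, nSnps = 3000, nRefPerPop = 100,
                          seed = 44)
  panel <- simulateReferencePanel(cfg)
  pop <- SummarizedExperiment::colData(panel)$population
  gA <- panel[, pop == "POP1"]
  gB <- panel[, pop == "POP2"]
  res <- alleleFreqDisparity(gA, gB, diffThreshold = 0.1)
  # direct Monte-Carlo oracle under the same Balding-Nichols draw
  set.seed(45)
  p <- runif(20000, 0.1, 0.9)
  a <- p * 4; b <- (1 - p) * 4          # (1 - F) / F = 4 at F = 0.2
  p1 <- rbeta(20000, a, b); p2 <- rbeta(20000, a, b)
  f1 <- rbinom(20000, 200, p1) / 200
  f2 <- rbinom(20000, 200, p2) / 200
  oracle <- mean(abs(f1 - f2) >= 0.1)
  se <- sqrt(oracle * (1 - oracle) / 3000 + oracle * (1 - oracle) / 20000)
  expect_gt(res$fractionAboveThreshold, 0.2)
  expect_lt(abs(res$fractionAboveThreshold - oracle), 3 * se)
})

test_that("PC adjustment removes ancestry-driven false discoveries", {
  # strong ancestry expression effects, no genetic effects: the
  # unadjusted arm reports confounded discoveries, the 3-PC arm almost
  # none (every discovery here is false by construction)
  unadj <- adj3 <- integer(4)
  for (s in 1:4) {
    cfg <- simulationConfig(nTraits = 300, nCisTrue = 0,
                            ancestryEffectSd = 2, admixAlpha = c(1, 1),
                            seed = 8100 + s)
    st <- simulateStudy(cfg)
    G <- cohortGenotypes(st$cohort)
    self <- fitPCA(G, nPCs = 3)
    counts <- vapply(c(0, 3), function(k) {
      an <- suppressMessages(suppressWarnings(
        eqtlAnalysis(st$expression, G, cohortCovariates(st$cohort),
                     pcs = refCoords(self), nPcs = k, fdrLevel = 0.1,
                     nPermutations = 10, seed = 81000 + s)))
      an$cis$nDiscoveries
    }, integer(1))
    unadj[s] <- counts[1]; adj3[s] <- counts[2]
  }
  expect_gt(sum(unadj), sum(adj3))
  expect_true(all(adj3 <= 2))   # near-calibrated after adjustment
})

test_that("pseudo-cis windows count background only", {
  cfg <- simulationConfig(nSnps = 600, nTraits = 40, nCisTrue = 10,
                          seed = 50)
  st <- simulateStudy(cfg)
  G <- cohortGenotypes(st$cohort)
  adj <- adjustTraits(st$expression, cohortCovariates(st$cohort), nPcs = 0)
  # p cutoff of zero: no pseudo-discoveries in any run
  z <- suppressMessages(pseudoCisNull(adj, G, nRuns = 5, pCutoff = 0,
                                      seed = 60))
  expect_true(all(z$counts == 0))

  # global-null traits: mean pseudo count matches a direct MC estimate
  set.seed(61)
  nullV <- matrix(rnorm(40 * ncol(G)), nrow = 40)
  eNull <- ExpressionData(nullV, data.frame(
    trait_id = paste0("n", 1:40), gene_symbol = paste0("N", 1:40),
    chrom = "chr1", pos = seq_len(40) * 1e5), sampleIds = colnames(G))
  pm <- suppressMessages(scanEqtls(eNull, G, minShared = 10))
  cutoff <- 0.001
  res <- suppressMessages(pseudoCisNull(eNull, G, nRuns = 150,
                                        pCutoff = cutoff, seed = 62))
  # oracle: independent window draws using the same p matrix
  pMat <- matrix(NA_real_, 40, nrow(G),
                 dimnames = list(paste0("n", 1:40), snpInfo(G)$id))
  pMat[cbind(match(pm$trait_id, rownames(pMat)),
             match(pm$snp_id, colnames(pMat)))] <- pm$p
  snps <- snpInfo(G)
  chromLengths <- S4Vectors::metadata(G)$chromLengths
  set.seed(63)
  draws <- replicate(400, {
    hits <- 0
    for (i in 1:40) {
      ch <- sample(names(chromLengths), 1,
                   prob = chromLengths / sum(chromLengths))
      start <- floor(runif(1, 1, chromLengths[[ch]] - 2e6 + 2))
      inWin <- which(snps$chrom == ch & snps$pos >= start &
                       snps$pos <= start + 2e6 - 1)
      if (length(inWin) && any(pMat[i, inWin] <= cutoff, na.rm = TRUE))
        hits <- hits + 1
    }
    hits
  })
  se <- sqrt(var(res$counts) / length(res$counts) + var(draws) / 400)
  expect_lt(abs(res$meanCount - mean(draws)), 2.5 * max(se, 0.05))
})
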