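test_that("call-rate filter removes SNPs strictly below the threshold", {
  d <- matrix(0, nrow = 100, ncol = 3,
              dimnames = list(paste0("s", 1:100), NULL))
  d[, 2][1:11] <- NA    # 89% called: removed
  d[, 3][1:10] <- NA    # exactly 90% called: retained
  g <- makeGenotypes(d)
  expect_message(f <- filterCallRate(g, 0.9), "1 SNP\\(s\\) removed")
  expect_identical(snpInfo(f)$id, c("rs1", "rs3"))
  expect_identical(nrow(filterCallRate(g, 0)), 3L)
})

test_that("batch quantile normalization equalizes distributions, preserves order", {
  set.seed(3)
  n <- 40
  base <- matrix(rnorm(n * 25), n, 25,
                 dimnames = list(paste0("s", 1:n), NULL))
  batch <- rep(c("A", "B"), each = n / 2)
  shifted <- base
  shifted[batch == "B", ] <- shifted[batch == "B", ] + 10
  e <- makeExpression(shifted, batch = batch)
  out <- exprValues(quantileNormalizeBatches(e))
  inA <- batch == "A"; inB <- batch == "B"
  # location shift removed: batch means agree per trait
  expect_lt(max(abs(rowMeans(out[, inA]) - rowMeans(out[, inB]))), 1e-9)
  # equal-size batches land on the same value multiset (KS distance 0)
  ksd <- vapply(seq_len(nrow(out)), function(i)
    max(abs(sort(out[i, inA]) - sort(out[i, inB]))), numeric(1))
  expect_lt(max(ksd), 1e-12)
  # within-batch ordering preserved
  sp <- vapply(seq_len(nrow(out)), function(i)
    cor(shifted[inB, i], out[i, inB], method = "spearman"), numeric(1))
  expect_equal(unname(sp), rep(1, nrow(out)))
})

test_that("trait adjustment removes design signal and resists outliers", {
  set.seed(5)
  n <- 60
  covar <- data.frame(sampleId = paste0("s", 1:n),
                      age = runif(n, 20, 80), sex = rbinom(n, 1, 0.5))
  y1 <- 2 + 0.3 * covar$age          # exactly linear in age
  y2 <- rnorm(n); y2[1] <- 40        # gross outlier in a null trait
  m <- cbind(y1, y2, rnorm(n))
  rownames(m) <- covar$sampleId
  e <- makeExpression(m)
  adj <- suppressWarnings(adjustTraits(e, covar, nPcs = 0))
  r <- exprValues(adj)
  expect_lt(max(abs(r[1, ])), 1e-8)
  expect_lt(max(abs(rowMeans(r))), 1e-6)

  # Huber slope on the outlier trait is nearer zero than the OLS slope
  x <- cbind(1, covar$age, covar$sex)
  ols <- stats::lm.fit(x, y2)$coefficients[2]
  rob <- MASS::rlm(x, y2, psi = MASS::psi.huber, k = 1.345,
                   maxit = 50, acc = 1e-8)$coefficients[2]
  expect_lt(abs(rob), abs(ols))

  # adjusting by a PC equal to the causal dosage removes the eQTL
  set.seed(6)
  gvec <- rbinom(n, 2, 0.5)
  ye <- 1.5 * gvec + rnorm(n, 0, 0.3)
  ee <- makeExpression(matrix(ye, ncol = 1,
                              dimnames = list(covar$sampleId, NULL)))
  pcs <- matrix(gvec, ncol = 1, dimnames = list(covar$sampleId, "PC1"))
  before <- kruskalWallis(ye, gvec)
  expect_lt(before$p, 1e-6)
  adjE <- adjustTraits(ee, covar, pcs = pcs, nPcs = 1)
  after <- kruskalWallis(exprValues(adjE)[1, ], gvec)
  expect_gt(after$p, 0.01)

  # a constant PC column is dropped with a warning, not an error
  pc0 <- matrix(1, n, 1, dimnames = list(covar$sampleId, "PC1"))
  expect_warning(adjustTraits(ee, covar, pcs = pc0, nPcs = 1),
                 "rank-deficient")
})

test_that("Kruskal-Wallis reproduces the mid-rank formula and its limits", {
  res <- kruskalWallis(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(res$K, 2.4)
  expect_equal(res$p, 0.1213, tolerance = 1e-3)
  expect_identical(res$g, 2L)

  # constant values: K = 0, p = 1
  expect_equal(kruskalWallis(rep(7, 9), rep(0:2, 3))[c("K", "p")],
               list(K = 0, p = 1))

  # invariant under strictly monotone transforms of the values
  set.seed(7)
  y <- rnorm(30); g <- rbinom(30, 2, 0.4)
  a <- kruskalWallis(y, g)
  expect_identical(kruskalWallis(exp(y), g), a)
  expect_identical(kruskalWallis(y^3, g), a)

  # fewer than two genotype groups: test skipped
  expect_true(is.na(kruskalWallis(y, rep(1, 30))$K))
})

test_that("Kruskal-Wallis agrees with the independent base implementation", {
  set.seed(8)
  for (i in 1:250) {
    n <- sample(6:40, 1)
    y <- sample(rnorm(n %/% 2 + 2), n, replace = TRUE)   # force ties
    g <- sample(0:2, n, replace = TRUE)
    if (length(unique(g)) < 2) next
    mine <- kruskalWallis(y, g)
    ref <- stats::kruskal.test(y, factor(g))
    expect_equal(mine$K, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("chi-square p stays within the exact permutation envelope at small n", {
  # enumerate all label orders; the documented envelope factor is 3
  permn <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in permn(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  set.seed(9)
  for (case in 1:10) {
    n <- sample(5:7, 1)
    g <- sample(0:2, n, replace = TRUE)
    while (length(unique(g)) < 2) g <- sample(0:2, n, replace = TRUE)
    y <- round(rnorm(n), 1)
    obs <- kruskalWallis(y, g)
    Ks <- vapply(permn(seq_len(n)),
                 function(pm) kruskalWallis(y, g[pm])$K, numeric(1))
    pExact <- mean(Ks >= obs$K - 1e-12)
    expect_gte(obs$p * 3, pExact)
  }
})

test_that("the scan partitions cis and trans by the inclusive 1 Mb rule", {
  set.seed(10)
  n <- 30
  d <- matrix(rbinom(3 * n, 2, 0.5), nrow = n,
              dimnames = list(paste0("s", 1:n), NULL))
  g <- makeGenotypes(d, chrom = c("chr1", "chr1", "chr2"),
                     pos = c(1000000L, 1500001L, 1L))
  v <- matrix(rnorm(2 * n), nrow = n, dimnames = list(paste0("s", 1:n), NULL))
  e <- makeExpression(v, chrom = c("chr1", "chr2"), pos = c(1L, 1L))
  rec <- scanEqtls(e, g, minShared = 10)
  look <- function(t, s) rec$relation[rec$trait_id == t & rec$snp_id == s]
  expect_identical(look("t1", "rs1"), "cis")    # distance exactly 1e6
  expect_identical(look("t1", "rs2"), "trans")  # 1 bp past the boundary
  expect_identical(look("t1", "rs3"), "trans")  # same pos, other chromosome
  expect_identical(look("t2", "rs3"), "cis")
  expect_true(all(rec$relation %in% c("cis", "trans")))
  expect_equal(nrow(rec), 6L)
})

test_that("fast and per-pair scan paths agree, with and without missingness", {
  set.seed(11)
  n <- 25
  d <- matrix(rbinom(5 * n, 2, 0.45), nrow = n,
              dimnames = list(paste0("s", 1:n), NULL))
  v <- matrix(rnorm(4 * n), nrow = n, dimnames = list(paste0("s", 1:n), NULL))
  v[, 1] <- v[, 1] + d[, 2]
  g <- makeGenotypes(d)
  e <- makeExpression(v)
  fast <- scanEqtls(e, g, minShared = 10)
  # force the per-pair path by introducing one missing dosage
  d2 <- d; d2[1, 5] <- NA
  slow <- scanEqtls(e, makeGenotypes(d2), minShared = 10)
  shared <- merge(fast, slow, by = c("trait_id", "snp_id"))
  full <- shared[shared$snp_id != "rs5", ]
  expect_equal(full$K.x, full$K.y, tolerance = 1e-12)
  expect_equal(full$p.x, full$p.y, tolerance = 1e-12)
  # pairwise exclusion applied where the dosage is missing
  miss <- shared[shared$snp_id == "rs5", ]
  expect_true(all(miss$n_used.y == n - 1))
})

test_that("a planted cis effect of r2 about 0.5 is detected at n = 60", {
  hits <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    g <- rbinom(60, 2, 0.4)
    beta <- sqrt(0.5 / 0.5) / sd(g)   # closed-form r2 = 0.5 target
    y <- beta * g + rnorm(60)
    if (kruskalWallis(y, g)$p < 1e-5) hits <- hits + 1
  }
  expect_gte(hits, 16)   # >= 80% of seeds
})

test_that("robust r2 tracks variance explained", {
  set.seed(12)
  g <- rbinom(500, 2, 0.5)
  expect_equal(suppressWarnings(effectSizeR2(3 * g + 1, g)), 1)
  expect_lt(effectSizeR2(rnorm(500), g), 0.05)
  expect_true(is.na(effectSizeR2(rnorm(10), rep(1, 10))))

  r2s <- suppressWarnings(replicate(50, {
    gg <- rbinom(200, 2, 0.4)
    beta <- sqrt(0.5 / 0.5) / sd(gg)
    effectSizeR2(beta * gg + rnorm(200), gg)
  }))
  expect_lt(abs(mean(r2s) - 0.5), 0.1)
})

test_that("differential-expression fraction calibrates at the null and sees shifts", {
  set.seed(13)
  a <- matrix(rnorm(10000 * 30), 10000, 30)
  b <- matrix(rnorm(10000 * 30), 10000, 30)
  frac <- differentialExpressionFraction(a, b, alpha = 0.01)
  expect_lt(abs(frac - 0.01), 0.005)

  # identical groups: nothing significant
  expect_equal(differentialExpressionFraction(a, a), 0)

  # a planted shift in 20% of traits is seen well above alpha
  b2 <- b
  b2[1:2000, ] <- b2[1:2000, ] + 1.5
  expect_gt(differentialExpressionFraction(a, b2, alpha = 0.01), 0.15)
})
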