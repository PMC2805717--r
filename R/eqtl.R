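#' Filter SNPs by genotyping call rate
#'
#' Removes SNPs whose fraction of non-missing calls is strictly below
#' `minRate` (a SNP called in exactly `minRate` of samples is retained).
#'
#' @param x a [GenotypeData-class] object.
#' @param minRate minimum call rate (default 0.9).
#' @return filtered [GenotypeData-class]; a message reports the count
#'   removed.
#' @export
filterCallRate <- function(x, minRate = 0.9) {
  d <- dosage(x)
  rate <- rowMeans(!is.na(d))
  drop <- rate < minRate
  if (any(drop))
    message(sum(drop), " SNP(s) removed at call rate < ", minRate)
  x[!drop, ]
}

#' Quantile-normalize expression batches onto pooled quantiles
#'
#' For every trait, each batch's values are rank-mapped onto the pooled
#' empirical quantiles of that trait, forcing the per-batch distributions
#' to coincide while preserving the ordering within each batch. This
#' removes location/scale differences between collection sites measured at
#' different times. A batch with a single sample is mapped to the pooled
#' median.
#'
#' @param x an [ExpressionData-class] with batch labels in
#'   `colData(x)$batch`.
#' @return an [ExpressionData-class] with normalized values.
#' @export
quantileNormalizeBatches <- function(x) {
  b <- batchLabels(x)
  if (is.null(b)) stop("no batch labels in colData")
  if (length(unique(b)) < 2) stop("need at least two non-empty batches")
  v <- exprValues(x)
  out <- v
  if (any(table(b) == 1))
    message("single-sample batch mapped to the pooled median")
  for (i in seq_len(nrow(v))) {
    pooled <- sort(v[i, ])
    for (bt in unique(b)) {
      cols <- which(b == bt)
      r <- rank(v[i, cols], ties.method = "average")
      out[i, cols] <- quantile(pooled, probs = (r - 0.5) / length(cols),
                               names = FALSE, type = 7)
    }
  }
  y <- x
  SummarizedExperiment::assay(y, "exprs") <- out
  y
}

# robust (Huber) fit residuals with OLS fallback for degenerate fits
.robustResiduals <- function(y, design) {
  fit <- tryCatch(
    MASS::rlm(design, y, psi = MASS::psi.huber, k = 1.345,
              maxit = 50, acc = 1e-8),
    error = function(e) NULL)
  if (is.null(fit)) fit <- stats::lm.fit(design, y)
  r <- stats::residuals(fit)
  r - mean(r)
}

#' Adjust expression traits for covariates and principal components
#'
#' Fits each trait on `intercept + age + sex + PC1..PCn` by Huber
#' M-estimation (tuning constant 1.345, at most 50 iterations) and returns
#' the residuals, mean-centered. With `nPcs = 0` the traits are still
#' adjusted for age and sex (the "unadjusted" analysis arm adjusts
#' covariates but no ancestry axes). Rank-deficient design columns
#' (e.g. a constant PC) are dropped with a warning. A trait that is an
#' exact linear function of the design yields residuals of zero via an
#' ordinary least-squares fallback (the robust scale estimate degenerates).
#'
#' @param x an [ExpressionData-class] object.
#' @param covariates `data.frame` with `sampleId`, `age`, `sex`; defaults
#'   to the age/sex columns of `colData(x)`.
#' @param pcs samples x D coordinate matrix, or the list returned by
#'   [projectOntoSpace()], or `NULL` when `nPcs = 0`.
#' @param nPcs number of leading PCs to include (0, 1, 2, ...).
#' @return an [ExpressionData-class] of residual traits; the adjustment
#'   description is stored in `metadata(x)$adjustmentSpec`.
#' @export
adjustTraits <- function(x, covariates = NULL, pcs = NULL, nPcs = 0) {
  v <- exprValues(x)
  n <- ncol(v)
  if (is.null(covariates)) {
    cd <- SummarizedExperiment::colData(x)
    if (!all(c("age", "sex") %in% colnames(cd)))
      stop("no covariates given and colData lacks age/sex")
    covariates <- data.frame(sampleId = colnames(v),
                             age = cd$age, sex = cd$sex)
  }
  covariates <- covariates[match(colnames(v), covariates$sampleId), ]
  if (anyNA(covariates$sampleId)) stop("covariates missing for some samples")
  design <- cbind(`(Intercept)` = 1, age = covariates$age,
                  sex = covariates$sex)
  if (nPcs > 0) {
    if (is.list(pcs) && !is.null(pcs$coords)) {
      pm <- pcs$coords[match(colnames(v), pcs$sampleIds), , drop = FALSE]
    } else {
      pm <- pcs[match(colnames(v), rownames(pcs)), , drop = FALSE]
    }
    if (anyNA(pm)) stop("PC coordinates missing for some samples")
    if (nPcs > ncol(pm)) stop("fewer PCs available than requested")
    design <- cbind(design, pm[, seq_len(nPcs), drop = FALSE])
  }
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    keep <- qrd$pivot[seq_len(qrd$rank)]
    warning("dropping ", ncol(design) - qrd$rank,
            " rank-deficient design column(s)")
    design <- design[, sort(keep), drop = FALSE]
  }
  res <- t(apply(v, 1, .robustResiduals, design = design))
  dimnames(res) <- dimnames(v)
  y <- x
  SummarizedExperiment::assay(y, "exprs") <- res
  S4Vectors::metadata(y)$adjustmentSpec <- list(
    covariates = c("age", "sex"), nPcs = nPcs,
    pcSource = if (nPcs == 0) "none" else "coords")
  y
}

#' Kruskal-Wallis test of a trait across genotype groups
#'
#' Ranks all trait values regardless of genotype, assigning tied values the
#' average of the ranks they would otherwise receive, and computes
#' `K = 12 / (N (N + 1)) * sum_i n_i (rbar_i - (N + 1) / 2)^2`, where `n_i`
#' and `rbar_i` are the size and mean rank of genotype group i, `N` the
#' number of samples used and `g` the number of genotype groups present
#' (2 or 3). The p value is the upper chi-square tail with `g - 1` degrees
#' of freedom. With `tieCorrection = TRUE` (default) K is divided by
#' `1 - sum(t^3 - t) / (N^3 - N)` over tie groups; with mid-ranks and no
#' correction the statistic is conservative in the presence of ties.
#' Samples with a missing value or genotype are excluded pairwise;
#' genotype groups smaller than `minGroup` are dropped (reducing `g`).
#' All-tied values give `K = 0, p = 1`; fewer than 2 groups gives `K = NA`
#' (the test is skipped).
#'
#' @param values numeric trait vector.
#' @param genotypes dosage vector (0/1/2, NA missing), same length.
#' @param tieCorrection apply the tie-correction divisor (default TRUE).
#' @param minGroup minimum per-group count to keep a group (default 1).
#' @return list with `K`, `p`, `g`, `nUsed`.
#' @export
kruskalWallis <- function(values, genotypes, tieCorrection = TRUE,
                          minGroup = 1) {
  ok <- !is.na(values) & !is.na(genotypes)
  y <- values[ok]
  g <- genotypes[ok]
  tab <- table(g)
  keepLv <- names(tab)[tab >= minGroup]
  keep <- g %in% keepLv
  y <- y[keep]; g <- g[keep]
  N <- length(y)
  ng <- length(unique(g))
  if (ng < 2)
    return(list(K = NA_real_, p = NA_real_, g = ng, nUsed = N))
  r <- rank(y, ties.method = "average")
  sums <- tapply(r, g, sum)
  ns <- tapply(r, g, length)
  K <- 12 / (N * (N + 1)) * sum(sums^2 / ns) - 3 * (N + 1)
  if (tieCorrection) {
    t <- table(y)
    C <- 1 - sum(t^3 - t) / (N^3 - N)
    if (C == 0) return(list(K = 0, p = 1, g = ng, nUsed = N))
    K <- K / C
  }
  K <- max(K, 0)
  list(K = K, p = pchisq(K, ng - 1, lower.tail = FALSE), g = ng, nUsed = N)
}

# Vectorized KW scan over a complete (no-NA) traits x SNPs problem.
# Y: samples x traits; D: samples x SNPs with entries 0/1/2.
# Returns list(K, p) of traits x SNPs matrices.
.kwScanComplete <- function(Y, D, tieCorrection = TRUE) {
  N <- nrow(Y)
  R <- apply(Y, 2, rank, ties.method = "average")   # samples x traits
  Ik <- lapply(0:2, function(k) (D == k) * 1)
  ns <- lapply(Ik, colSums)                         # per-SNP group sizes
  gCount <- Reduce(`+`, lapply(ns, function(n) (n > 0) * 1L))
  Ksum <- 0
  for (k in 1:3) {
    Sk <- crossprod(R, Ik[[k]])                     # traits x SNPs rank sums
    nk <- ns[[k]]
    div <- ifelse(nk > 0, nk, 1)
    Ksum <- Ksum + sweep(Sk^2, 2, div, "/")
  }
  K <- 12 / (N * (N + 1)) * Ksum - 3 * (N + 1)
  if (tieCorrection) {
    C <- apply(Y, 2, function(y) {
      t <- table(y)
      1 - sum(t^3 - t) / (N^3 - N)
    })
    K <- sweep(K, 1, ifelse(C == 0, 1, C), "/")
    K[C == 0, ] <- 0
  }
  K[K < 0] <- 0
  df <- matrix(gCount - 1L, nrow(K), ncol(K), byrow = TRUE)
  p <- matrix(NA_real_, nrow(K), ncol(K), dimnames = dimnames(K))
  testable <- df >= 1
  p[testable] <- pchisq(K[testable], df[testable], lower.tail = FALSE)
  K[!testable] <- NA_real_
  list(K = K, p = p, g = gCount + 0L)
}

# Full KW p/K matrices for aligned expression and genotypes.
# Falls back to the per-pair test when any dosage or value is missing.
.kwMatrix <- function(Y, D, tieCorrection = TRUE, minGroup = 1) {
  if (!anyNA(Y) && !anyNA(D) && minGroup <= 1)
    return(.kwScanComplete(Y, D, tieCorrection))
  Tn <- ncol(Y); S <- ncol(D)
  K <- matrix(NA_real_, Tn, S, dimnames = list(colnames(Y), colnames(D)))
  p <- K
  nUsed <- matrix(nrow(Y), Tn, S)
  g <- integer(S)
  for (j in seq_len(S)) {
    for (i in seq_len(Tn)) {
      res <- kruskalWallis(Y[, i], D[, j], tieCorrection, minGroup)
      K[i, j] <- res$K; p[i, j] <- res$p
      nUsed[i, j] <- res$nUsed
      g[j] <- res$g
    }
  }
  list(K = K, p = p, g = g, nUsed = nUsed)
}

#' Genome-wide Kruskal-Wallis eQTL scan with cis/trans partition
#'
#' Tests every (trait, SNP) pair with [kruskalWallis()] on the shared
#' samples and classifies each record as `cis` when trait gene and SNP lie
#' on the same chromosome within `cisWindow` basepairs (boundary
#' inclusive), `trans` otherwise. Pairs where the test is skipped (fewer
#' than two genotype groups) are omitted; the count is reported in a
#' message.
#'
#' @param traits an [ExpressionData-class], typically adjusted residuals
#'   from [adjustTraits()].
#' @param genotypes a [GenotypeData-class].
#' @param cisWindow cis distance in bp (default 1e6, inclusive).
#' @param tieCorrection passed to the KW statistic.
#' @param minShared minimum shared sample count (default 20).
#' @param computeR2 also fit [effectSizeR2()] per record (slow; default
#'   FALSE leaves the `r2` column `NA`).
#' @return `data.frame` with columns `trait_id`, `snp_id`, `chrom_trait`,
#'   `pos_trait`, `chrom_snp`, `pos_snp`, `K`, `p`, `relation`, `class`,
#'   `r2`, `n_used`, `g`.
#' @export
scanEqtls <- function(traits, genotypes, cisWindow = 1e6,
                      tieCorrection = TRUE, minShared = 20,
                      computeR2 = FALSE) {
  shared <- .alignSamples(colnames(traits), colnames(genotypes), "samples")
  if (length(shared) < minShared)
    stop("only ", length(shared), " shared samples (minimum ", minShared, ")")
  Y <- t(exprValues(traits)[, shared, drop = FALSE])   # samples x traits
  D <- t(dosage(genotypes)[, shared, drop = FALSE])    # samples x SNPs
  res <- .kwMatrix(Y, D, tieCorrection)
  genes <- geneInfo(traits)
  snps <- snpInfo(genotypes)
  Tn <- nrow(genes); S <- nrow(snps)
  cis <- outer(genes$chrom, snps$chrom, "==") &
    abs(outer(genes$pos, snps$pos, "-")) <= cisWindow
  rec <- data.frame(
    trait_id = rep(genes$trait_id, times = S),
    snp_id = rep(snps$id, each = Tn),
    chrom_trait = rep(genes$chrom, times = S),
    pos_trait = rep(genes$pos, times = S),
    chrom_snp = rep(snps$chrom, each = Tn),
    pos_snp = rep(snps$pos, each = Tn),
    K = as.numeric(res$K),
    p = as.numeric(res$p),
    relation = ifelse(as.logical(cis), "cis", "trans"),
    n_used = if (is.null(res$nUsed)) length(shared)
             else as.integer(res$nUsed),
    g = rep(res$g, each = Tn),
    stringsAsFactors = FALSE)
  skipped <- is.na(rec$K)
  if (any(skipped))
    message(sum(skipped), " pair(s) skipped: fewer than 2 genotype groups")
  rec <- rec[!skipped, , drop = FALSE]
  rec$class <- rec$relation
  if (computeR2) {
    rec$r2 <- mapply(function(t, s)
      effectSizeR2(Y[, t], D[, s]),
      match(rec$trait_id, colnames(Y)), match(rec$snp_id, colnames(D)))
  } else rec$r2 <- NA_real_
  rownames(rec) <- NULL
  rec
}

#' Effect size of an association as robust-regression r-squared
#'
#' Fits `trait_adj ~ intercept + dosage` (additive coding) by the same
#' Huber M-estimation used in [adjustTraits()] and returns
#' `r2 = 1 - sum(w e^2) / sum(w (y - ybar_w)^2)` with the converged
#' weights `w` and the weighted mean `ybar_w`. Returns `NA` when the
#' weighted trait variance is zero. An exactly linear relation gives 1.
#'
#' @param traitAdj adjusted trait values.
#' @param genotypes dosage vector.
#' @return r-squared in [0, 1], or `NA` when undefined.
#' @export
effectSizeR2 <- function(traitAdj, genotypes) {
  ok <- !is.na(traitAdj) & !is.na(genotypes)
  y <- traitAdj[ok]; g <- genotypes[ok]
  if (length(y) < 3 || var(g) == 0) return(NA_real_)
  X <- cbind(1, g)
  fit <- tryCatch(
    MASS::rlm(X, y, psi = MASS::psi.huber, k = 1.345,
              maxit = 50, acc = 1e-8),
    error = function(e) NULL)
  if (is.null(fit)) {                 # degenerate scale: exact fit
    e <- stats::lm.fit(X, y)$residuals
    w <- rep(1, length(y))
  } else {
    e <- stats::residuals(fit)
    w <- fit$w
  }
  ybarW <- sum(w * y) / sum(w)
  tot <- sum(w * (y - ybarW)^2)
  if (tot == 0) return(NA_real_)
  max(0, min(1, 1 - sum(w * e^2) / tot))
}

#' Fraction of differentially expressed traits between two groups
#'
#' Welch two-sample t-test per trait between two expression matrices over
#' the same traits; returns the fraction of testable traits with
#' `p < alpha`. Traits constant in both groups are excluded with a
#' message.
#'
#' @param exprA,exprB numeric matrices (traits x samples) or
#'   [ExpressionData-class] objects over the same traits.
#' @param alpha significance level (default 0.01).
#' @return fraction of traits significant at `alpha`.
#' @export
differentialExpressionFraction <- function(exprA, exprB, alpha = 0.01) {
  if (methods::is(exprA, "ExpressionData")) exprA <- exprValues(exprA)
  if (methods::is(exprB, "ExpressionData")) exprB <- exprValues(exprB)
  stopifnot(nrow(exprA) == nrow(exprB))
  nA <- ncol(exprA); nB <- ncol(exprB)
  if (nA < 2 || nB < 2) stop("both groups need at least 2 samples")
  mA <- rowMeans(exprA); mB <- rowMeans(exprB)
  vA <- apply(exprA, 1, var); vB <- apply(exprB, 1, var)
  se2 <- vA / nA + vB / nB
  testable <- se2 > 0
  if (any(!testable))
    message(sum(!testable), " constant trait(s) excluded")
  tstat <- (mA - mB)[testable] / sqrt(se2[testable])
  df <- se2[testable]^2 /
    ((vA[testable] / nA)^2 / (nA - 1) + (vB[testable] / nB)^2 / (nB - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  mean(p < alpha)
}
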