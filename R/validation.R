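#' Permute the sample axis of an expression matrix
#'
#' Applies one random permutation to the sample axis of the whole matrix —
#' all traits move together — breaking any association between expression
#' and genotype while leaving the correlation structure among traits (and
#' among genotypes) intact. Sample ids keep their original order so that
#' downstream matching by id realizes the permutation.
#'
#' @param x an [ExpressionData-class] object (>= 2 samples).
#' @param seed integer seed.
#' @return a permuted [ExpressionData-class].
#' @export
permuteExpression <- function(x, seed) {
  n <- ncol(x)
  if (n < 2) stop("need at least 2 samples")
  set.seed(seed)
  perm <- sample.int(n)
  v <- exprValues(x)[, perm, drop = FALSE]
  colnames(v) <- colnames(x)
  y <- x
  SummarizedExperiment::assay(y, "exprs") <- v
  y
}

#' Empirical FDR cutoff from permutation null statistics
#'
#' For candidate thresholds t (the sorted observed p-values), the estimated
#' FDR is the permutation-averaged count of null p-values at or below t
#' divided by the observed count at or below t (pi0 is set to 1,
#' conservative). The cutoff is the largest t with estimated FDR at or
#' below `fdrLevel`; when no threshold qualifies the cutoff is absent and
#' there are no discoveries. Classes (cis/trans) have separate cutoffs:
#' call this once per class.
#'
#' @param obsP observed p-values for one class.
#' @param nullP list of null p-value vectors, one per permutation.
#' @param fdrLevel target FDR level in (0, 1).
#' @return list with `fdrLevel`, `pCutoff` (`NA` when absent),
#'   `nDiscoveries`, `expectedFalse` (= [expectedFalseCount()]), and
#'   `discoveries` (logical over `obsP`).
#' @export
estimateFdrCutoffs <- function(obsP, nullP, fdrLevel = 0.1) {
  if (!length(obsP))
    return(list(fdrLevel = fdrLevel, pCutoff = NA_real_,
                nDiscoveries = 0L, expectedFalse = 0L,
                discoveries = logical(0)))
  if (!is.list(nullP)) nullP <- list(nullP)
  stopifnot(length(nullP) >= 1)
  ord <- order(obsP)
  t <- obsP[ord]
  nObs <- seq_along(t)
  nullSorted <- sort(unlist(nullP))
  nullCount <- findInterval(t, nullSorted) / length(nullP)
  fdrHat <- nullCount / pmax(1, nObs)
  ok <- which(fdrHat <= fdrLevel)
  if (!length(ok))
    return(list(fdrLevel = fdrLevel, pCutoff = NA_real_,
                nDiscoveries = 0L, expectedFalse = 0L,
                discoveries = rep(FALSE, length(obsP))))
  cutoff <- t[max(ok)]
  disc <- obsP <= cutoff
  nDisc <- sum(disc)
  list(fdrLevel = fdrLevel, pCutoff = cutoff, nDiscoveries = nDisc,
       expectedFalse = expectedFalseCount(fdrLevel, nDisc),
       discoveries = disc)
}

#' Expected number of false discoveries at an FDR level
#'
#' The integer part of `fdrLevel * nDiscoveries`: at a 10% FDR, 65
#' discoveries carry about 6 expected false positives and 33 carry about 3.
#'
#' @param fdrLevel FDR level in (0, 1).
#' @param nDiscoveries number of discoveries (non-negative).
#' @return integer expected false count.
#' @export
expectedFalseCount <- function(fdrLevel, nDiscoveries) {
  stopifnot(fdrLevel >= 0, nDiscoveries >= 0)
  as.integer(floor(fdrLevel * nDiscoveries))
}

#' Relative empirical power of two analyses at a common FDR
#'
#' At a fixed FDR f, analyses discovering N1 and N2 findings contain
#' (1 - f) N1 and (1 - f) N2 true findings, so N1 / N2 is proportional to
#' their relative power; the factor cancels and the ratio is independent
#' of the level.
#'
#' @param n1,n2 discovery counts of the two analyses (n2 > 0).
#' @param fdrLevel FDR level (kept for the record; cancels).
#' @return n1 / n2.
#' @export
relativePower <- function(n1, n2, fdrLevel = 0.1) {
  if (n2 <= 0) stop("n2 must be positive")
  ((1 - fdrLevel) * n1) / ((1 - fdrLevel) * n2)
}

#' Reduce an association table to per-trait minimum p by class
#'
#' The trait-level eQTL count at a p cutoff is the number of traits whose
#' best SNP in the class beats the cutoff; the matching reduction of the
#' p-value table is the per-trait minimum within the class.
#'
#' @param records association `data.frame` from [scanEqtls()].
#' @param relation `"cis"` or `"trans"`.
#' @return named numeric vector, minimum p per trait having any test in
#'   the class.
#' @export
minPByTrait <- function(records, relation = "cis") {
  sub <- records[records$relation == relation & !is.na(records$p), ]
  if (!nrow(sub)) return(setNames(numeric(0), character(0)))
  tapply(sub$p, sub$trait_id, min)
}

#' Random-window pseudo-cis null
#'
#' Background model for cis discoveries driven by stratification rather
#' than local regulation: per run, every trait is assigned a uniformly
#' random window of `windowBp` fully inside a random chromosome, and
#' counts as a pseudo-discovery when any SNP in the window has KW p at or
#' below `pCutoff`. Windows overlapping the trait's true cis region
#' (gene position plus/minus `cisWindow`) are excluded by default so the
#' pseudo count measures background only. If the allele-frequency
#' structure of the cohort, not local regulation, produced the observed
#' cis discoveries, the mean pseudo count approaches the true count.
#'
#' @param traits an [ExpressionData-class] (adjusted residuals).
#' @param genotypes a [GenotypeData-class].
#' @param windowBp pseudo-cis window width (default 2e6).
#' @param nRuns number of random-window runs (>= 1; 1000 in full use).
#' @param pCutoff p cutoff from the true-cis FDR decision.
#' @param seed integer seed.
#' @param chromLengths named chromosome lengths; default taken from
#'   genotype metadata or the maximum SNP position per chromosome.
#' @param excludeTrueCis exclude windows overlapping the trait's own cis
#'   region (default TRUE).
#' @param cisWindow half-width of the true cis region excluded (1e6).
#' @param pMatrix optional precomputed traits x SNPs KW p matrix (rows
#'   named by trait, columns by SNP id) to avoid rescanning.
#' @return list with `meanCount`, `counts` (per run), `nRuns`.
#' @export
pseudoCisNull <- function(traits, genotypes, windowBp = 2e6,
                          nRuns = 1000, pCutoff, seed = 1L,
                          chromLengths = NULL, excludeTrueCis = TRUE,
                          cisWindow = 1e6, pMatrix = NULL) {
  snps <- snpInfo(genotypes)
  genes <- geneInfo(traits)
  if (is.null(chromLengths)) {
    chromLengths <- S4Vectors::metadata(genotypes)$chromLengths
    if (is.null(chromLengths))
      chromLengths <- tapply(snps$pos, snps$chrom, max)
  }
  if (all(windowBp > chromLengths))
    stop("window wider than every chromosome")
  chromOk <- names(chromLengths)[chromLengths >= windowBp]
  if (is.null(pMatrix)) {
    shared <- .alignSamples(colnames(traits), colnames(genotypes))
    Y <- t(exprValues(traits)[, shared, drop = FALSE])
    D <- t(dosage(genotypes)[, shared, drop = FALSE])
    pMatrix <- .kwMatrix(Y, D)$p
  }
  set.seed(seed)
  # per-chromosome SNP position index for fast window lookups
  bychr <- split(seq_len(nrow(snps)), snps$chrom)
  counts <- integer(nRuns)
  Tn <- nrow(genes)
  for (run in seq_len(nRuns)) {
    hits <- 0L
    for (i in seq_len(Tn)) {
      repeat {
        ch <- sample(chromOk, 1,
                     prob = chromLengths[chromOk] / sum(chromLengths[chromOk]))
        start <- floor(runif(1, 1, chromLengths[[ch]] - windowBp + 2))
        if (!excludeTrueCis) break
        if (ch != genes$chrom[i]) break
        trueLo <- genes$pos[i] - cisWindow
        trueHi <- genes$pos[i] + cisWindow
        if (start + windowBp - 1 < trueLo || start > trueHi) break
      }
      idx <- bychr[[ch]]
      if (is.null(idx)) next
      inWin <- idx[snps$pos[idx] >= start &
                     snps$pos[idx] <= start + windowBp - 1]
      if (length(inWin) &&
          any(pMatrix[i, inWin] <= pCutoff, na.rm = TRUE))
        hits <- hits + 1L
    }
    counts[run] <- hits
  }
  list(meanCount = mean(counts), counts = counts, nRuns = nRuns)
}

#' Overlap of two discovery sets with Fisher enrichment test
#'
#' Builds the 2x2 membership table of the two trait sets over the universe
#' and returns the overlap count with the one-sided (enrichment) Fisher
#' exact p-value, i.e. the hypergeometric upper tail.
#'
#' @param discoveriesA,discoveriesB character trait sets (subsets of
#'   `universe`).
#' @param universe character vector of all testable traits.
#' @return list with `overlap` and `p`.
#' @export
overlapEnrichment <- function(discoveriesA, discoveriesB, universe) {
  if (!length(universe)) stop("empty universe")
  if (!all(discoveriesA %in% universe) || !all(discoveriesB %in% universe))
    stop("discovery sets must be subsets of the universe")
  a <- unique(discoveriesA); b <- unique(discoveriesB)
  u <- unique(universe)
  inA <- u %in% a
  inB <- u %in% b
  tab <- table(factor(inA, c(TRUE, FALSE)), factor(inB, c(TRUE, FALSE)))
  ft <- fisher.test(tab, alternative = "greater")
  list(overlap = sum(inA & inB), p = ft$p.value)
}

#' Allele-frequency disparity between two cohorts
#'
#' Per shared SNP: the absolute alt-allele frequency difference, the
#' fraction of SNPs at or above `diffThreshold`, and a simple 2x2
#' allele-count chi-square p-value (alleles, 2N per cohort; no continuity
#' correction). SNPs with all-missing calls in either cohort are excluded
#' with a message.
#'
#' @param genoA,genoB [GenotypeData-class] objects over the same SNP set.
#' @param diffThreshold disparity threshold (default 0.1).
#' @return list with `freqDiff` (per SNP), `fractionAboveThreshold`,
#'   `chisqP` (per SNP), `snpIds`.
#' @export
alleleFreqDisparity <- function(genoA, genoB, diffThreshold = 0.1) {
  sa <- snpInfo(genoA); sb <- snpInfo(genoB)
  shared <- intersect(sa$id, sb$id)
  if (!length(shared)) stop("no shared SNPs")
  dA <- dosage(genoA)[match(shared, sa$id), , drop = FALSE]
  dB <- dosage(genoB)[match(shared, sb$id), , drop = FALSE]
  nA <- rowSums(!is.na(dA)); nB <- rowSums(!is.na(dB))
  ok <- nA > 0 & nB > 0
  if (any(!ok))
    message(sum(!ok), " SNP(s) excluded: all-missing in a cohort")
  dA <- dA[ok, , drop = FALSE]; dB <- dB[ok, , drop = FALSE]
  nA <- nA[ok]; nB <- nB[ok]
  altA <- rowSums(dA, na.rm = TRUE); altB <- rowSums(dB, na.rm = TRUE)
  fA <- altA / (2 * nA); fB <- altB / (2 * nB)
  diff <- abs(fA - fB)
  # 2x2 allele-count chi-square without continuity correction
  a <- altA; b <- 2 * nA - altA; c <- altB; d <- 2 * nB - altB
  N <- a + b + c + d
  num <- N * (a * d - b * c)^2
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  stat <- ifelse(den > 0, num / den, 0)
  pv <- pchisq(stat, 1, lower.tail = FALSE)
  pv[den == 0] <- 1
  list(freqDiff = setNames(diff, shared[ok]),
       fractionAboveThreshold = mean(diff >= diffThreshold),
       chisqP = setNames(pv, shared[ok]),
       snpIds = shared[ok])
}

#' End-to-end eQTL discovery analysis at an FDR level
#'
#' Convenience pipeline: adjust traits for covariates and `nPcs` leading
#' PCs, scan all trait-SNP pairs, reduce to per-trait minimum p within the
#' cis (and trans) class, build the permutation null by re-scanning
#' sample-permuted expression, and return the per-class FDR decisions.
#'
#' @param expression an [ExpressionData-class] (raw traits; covariates in
#'   `colData`).
#' @param genotypes a [GenotypeData-class].
#' @param covariates covariate `data.frame` (default from `colData`).
#' @param pcs PC coordinates for adjustment (see [adjustTraits()]).
#' @param nPcs number of PCs to adjust for.
#' @param fdrLevel target FDR (default 0.1).
#' @param nPermutations number of expression permutations (default 10).
#' @param seed integer seed for the permutations.
#' @param cisWindow cis distance in bp.
#' @return list with `cis` and `trans` FDR decisions (see
#'   [estimateFdrCutoffs()]), the `records` of the observed scan, and
#'   `adjusted` traits.
#' @export
eqtlAnalysis <- function(expression, genotypes, covariates = NULL,
                         pcs = NULL, nPcs = 0, fdrLevel = 0.1,
                         nPermutations = 10, seed = 1L,
                         cisWindow = 1e6) {
  adj <- adjustTraits(expression, covariates, pcs = pcs, nPcs = nPcs)
  obs <- scanEqtls(adj, genotypes, cisWindow = cisWindow)
  obsCis <- minPByTrait(obs, "cis")
  obsTrans <- minPByTrait(obs, "trans")
  nullCis <- vector("list", nPermutations)
  nullTrans <- vector("list", nPermutations)
  for (b in seq_len(nPermutations)) {
    perm <- permuteExpression(adj, seed = seed + b)
    prec <- scanEqtls(perm, genotypes, cisWindow = cisWindow)
    nullCis[[b]] <- as.numeric(minPByTrait(prec, "cis"))
    nullTrans[[b]] <- as.numeric(minPByTrait(prec, "trans"))
  }
  list(cis = estimateFdrCutoffs(as.numeric(obsCis), nullCis, fdrLevel),
       trans = estimateFdrCutoffs(as.numeric(obsTrans), nullTrans, fdrLevel),
       cisTraits = names(obsCis),
       records = obs, adjusted = adj)
}
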