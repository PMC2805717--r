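#' Thin SNPs by pairwise linkage disequilibrium
#'
#' Greedy left-to-right positional scan within each chromosome: a SNP is
#' dropped when its squared Pearson correlation of dosages with any
#' already-retained SNP within `windowBp` exceeds `r2Max` (first-kept wins
#' ties, making the result deterministic and order-stable). Monomorphic
#' SNPs, for which correlation is undefined, are dropped with a message.
#'
#' @param x a [GenotypeData-class] object with SNPs position-sorted within
#'   chromosome.
#' @param r2Max maximum allowed squared correlation (default 0.2).
#' @param windowBp comparison window in basepairs (default 1 Mb).
#' @return A [GenotypeData-class] with the retained SNPs, order preserved.
#' @export
thinLD <- function(x, r2Max = 0.2, windowBp = 1e6) {
  d <- dosage(x)
  snps <- snpInfo(x)
  v <- apply(d, 1, function(r) var(r, na.rm = TRUE))
  mono <- !is.na(v) & v == 0 | is.na(v)
  if (any(mono))
    message(sum(mono), " monomorphic SNP(s) dropped before LD thinning")
  keep <- logical(nrow(d))
  for (ch in unique(snps$chrom)) {
    idx <- which(snps$chrom == ch & !mono)
    if (!length(idx)) next
    if (is.unsorted(snps$pos[idx]))
      stop("SNPs must be position-sorted within chromosome")
    kept <- integer(0)
    for (i in idx) {
      near <- kept[snps$pos[kept] >= snps$pos[i] - windowBp]
      drop <- FALSE
      for (j in near) {
        r <- suppressWarnings(
          cor(d[i, ], d[j, ], use = "pairwise.complete.obs"))
        if (!is.na(r) && r * r > r2Max) { drop <- TRUE; break }
      }
      if (!drop) { kept <- c(kept, i); keep[i] <- TRUE }
    }
  }
  x[keep, ]
}

#' EIGENSTRAT genotype normalization
#'
#' Per SNP j, the posterior allele-frequency estimate is
#' `p_j = (1 + sum_i g_ij) / (2 + 2 n_called)`; each called entry is
#' centered by the SNP's mean dosage and divided by `sqrt(p_j (1 - p_j))`;
#' missing entries are set to 0 after centering so they contribute nothing
#' to any principal component. When `center`/`freqs` are supplied (e.g.
#' from a reference panel), they are used instead of being estimated, which
#' is how study samples are placed on a reference panel's scale. SNPs with
#' an all-missing column are dropped with a message.
#'
#' @param x a [GenotypeData-class] object.
#' @param center optional per-SNP centering values (named by SNP id).
#' @param freqs optional per-SNP frequencies for scaling (named by SNP id).
#' @return list with `X` (samples x SNPs normalized matrix), `center`,
#'   `freqs` (both per retained SNP).
#' @export
normalizeGenotypes <- function(x, center = NULL, freqs = NULL) {
  d <- t(dosage(x))                     # samples x SNPs
  nCalled <- colSums(!is.na(d))
  allMissing <- nCalled == 0
  if (any(allMissing) && is.null(freqs)) {
    message(sum(allMissing), " all-missing SNP(s) dropped")
    d <- d[, !allMissing, drop = FALSE]
    nCalled <- nCalled[!allMissing]
  }
  if (is.null(freqs)) {
    sums <- colSums(d, na.rm = TRUE)
    freqs <- (1 + sums) / (2 + 2 * nCalled)
    center <- sums / pmax(nCalled, 1)
    names(freqs) <- names(center) <- colnames(d)
  } else {
    stopifnot(!is.null(center))
    center <- center[colnames(d)]
    freqs <- freqs[colnames(d)]
    if (anyNA(center) || anyNA(freqs))
      stop("center/freqs missing for some SNPs")
  }
  X <- sweep(d, 2, center, "-")
  X <- sweep(X, 2, sqrt(freqs * (1 - freqs)), "/")
  X[is.na(X)] <- 0
  list(X = X, center = center, freqs = freqs)
}

#' Fit a principal-component space on a genotype panel (self-eigen)
#'
#' EIGENSTRAT-normalizes the panel and takes the top-`nPCs` right singular
#' vectors of the normalized samples x SNPs matrix as SNP loadings.
#' Eigenvalues are squared singular values divided by (n - 1); reference
#' coordinates are the normalized matrix times the loadings (identically,
#' U times the singular values). Run on a reference diversity panel this is
#' step 1 of the two-step projection method; run on the study cohort itself
#' it is the conventional self-eigen analysis.
#'
#' @param x a [GenotypeData-class] panel; population labels are taken from
#'   `colData(x)$population` when present.
#' @param nPCs number of dimensions to retain (default 10); truncated with
#'   a warning when it exceeds the matrix rank.
#' @return A [PCSpace-class] object.
#' @export
fitPCA <- function(x, nPCs = 10) {
  if (ncol(x) <= 2) stop("need more than 2 samples")
  nrm <- normalizeGenotypes(x)
  X <- nrm$X
  n <- nrow(X)
  # samples << SNPs: eigendecompose the n x n Gram matrix
  G <- tcrossprod(X)
  ei <- eigen(G, symmetric = TRUE)
  pos <- ei$values > max(ei$values) * 1e-9 & ei$values > 0
  rank <- sum(pos)
  if (nPCs > rank) {
    warning("requested ", nPCs, " PCs but rank is ", rank, "; truncating")
    nPCs <- rank
  }
  dvals <- sqrt(ei$values[seq_len(nPCs)])
  U <- ei$vectors[, seq_len(nPCs), drop = FALSE]
  V <- crossprod(X, U) %*% diag(1 / dvals, nPCs)  # SNPs x nPCs
  coords <- U %*% diag(dvals, nPCs)
  rownames(coords) <- rownames(X)
  colnames(coords) <- colnames(V) <- paste0("PC", seq_len(nPCs))
  pop <- SummarizedExperiment::colData(x)$population
  info <- snpInfo(x)
  methods::new("PCSpace",
               snpIds = colnames(X),
               snpAlleles = info[match(colnames(X), info$id),
                                 c("id", "ref", "alt")],
               normCenter = nrm$center, normFreqs = nrm$freqs,
               loadings = V,
               eigenvalues = dvals^2 / (n - 1),
               spectrum = ei$values[pos] / (n - 1),
               refCoords = coords,
               refPopLabels = if (is.null(pop)) character(0)
                              else as.character(pop),
               nSamples = n, nSnps = ncol(X))
}

#' Project study genotypes onto a reference PC space
#'
#' Step 2 of the two-step projection method: study dosages are normalized
#' with the *reference* panel's per-SNP centering and frequencies and
#' multiplied by the reference loadings, so study and reference samples
#' live in one comparable coordinate system (projecting the reference
#' itself reproduces its own coordinates). SNPs are matched by id; shared
#' SNPs whose ref/alt alleles disagree are excluded with a message.
#'
#' @param space a [PCSpace-class] from [fitPCA()].
#' @param x study [GenotypeData-class].
#' @param minOverlap warn when fewer shared SNPs than this remain
#'   (default 10000).
#' @return list with `sampleIds` and `coords` (samples x D matrix).
#' @export
projectOntoSpace <- function(space, x, minOverlap = 10000) {
  snps <- snpInfo(x)
  shared <- intersect(space@snpIds, snps$id)
  if (!length(shared)) stop("no SNPs shared with the PC space")
  info <- snps[match(shared, snps$id), ]
  # allele consistency at shared ids (dosages count the alt allele as written)
  mism <- rep(FALSE, length(shared))
  ra <- space@snpAlleles
  if (nrow(ra)) {
    mism <- ra$ref[match(shared, ra$id)] != info$ref |
      ra$alt[match(shared, ra$id)] != info$alt
    mism[is.na(mism)] <- FALSE
  }
  if (any(mism)) {
    message(sum(mism), " SNP(s) excluded: allele mismatch with PC space")
    shared <- shared[!mism]
  }
  if (length(shared) < minOverlap)
    warning("only ", length(shared), " SNPs shared with the PC space")
  sub <- x[match(shared, snps$id), ]
  nrm <- normalizeGenotypes(sub, center = space@normCenter,
                            freqs = space@normFreqs)
  L <- space@loadings[match(shared, space@snpIds), , drop = FALSE]
  coords <- nrm$X %*% L
  rownames(coords) <- colnames(sub)
  colnames(coords) <- colnames(space@loadings)
  list(sampleIds = colnames(sub), coords = coords)
}

# Tracy-Widom standardization of the leading eigenvalue of a set
# (moment-based effective marker number, after Patterson/Price).
.twStatistic <- function(ev) {
  m <- length(ev)
  if (m < 2) return(NA_real_)
  S1 <- sum(ev)
  S2 <- sum(ev^2)
  # moment estimator of the effective marker count: matches E[tr W] = mn,
  # E[tr W^2] = mn(m+n+1) for a white Wishart, so n solves S2/S1^2
  nEff <- ((m + 1) * S1^2) / (m * S2 - S1^2)
  if (!is.finite(nEff) || nEff <= 1) return(NA_real_)
  l <- m * ev[1] / S1
  mu <- (sqrt(nEff - 1) + sqrt(m))^2 / nEff
  sig <- ((sqrt(nEff - 1) + sqrt(m)) / nEff) *
    (1 / sqrt(nEff - 1) + 1 / sqrt(m))^(1 / 3)
  (l - mu) / sig
}

#' Count significant principal components by Tracy-Widom statistics
#'
#' For each leading eigenvalue, the effective number of markers is
#' estimated from the moments of the remaining eigenvalues, the normalized
#' largest eigenvalue is standardized by the Tracy-Widom center and scale,
#' and the resulting statistic is compared against the decision rule:
#' `"critical"` (default) counts leading consecutive statistics exceeding
#' the 0.05 critical value 0.9794 of the Tracy-Widom law; `"positive"`
#' counts leading consecutive positive statistics.
#'
#' @param eigenvalues non-increasing eigenvalue vector (length >= 2), e.g.
#'   [pcEigenvalues()] of a fitted space.
#' @param nSamples number of samples behind the eigenvalues (>= 3).
#' @param nSnps number of SNPs (recorded; the effective count is estimated
#'   from the eigenvalue moments themselves).
#' @param rule `"critical"` or `"positive"`.
#' @param criticalValue threshold for the `"critical"` rule (0.9794, the
#'   Tracy-Widom 0.05 point).
#' @return list with `twStats` (one per testable leading eigenvalue) and
#'   `nSignificant`.
#' @export
tracyWidomCount <- function(eigenvalues, nSamples, nSnps,
                            rule = c("critical", "positive"),
                            criticalValue = 0.9794) {
  rule <- match.arg(rule)
  if (nSamples < 3) stop("need at least 3 samples")
  ev <- eigenvalues
  if (length(ev) < 2) stop("need at least 2 eigenvalues")
  if (is.unsorted(rev(ev))) stop("eigenvalues must be non-increasing")
  nTest <- length(ev) - 1L
  tw <- vapply(seq_len(nTest),
               function(k) .twStatistic(ev[k:length(ev)]), numeric(1))
  thr <- if (rule == "critical") criticalValue else 0
  sig <- !is.na(tw) & tw > thr
  nSig <- if (length(sig) && sig[1]) {
    r <- rle(sig)
    r$lengths[1]
  } else 0L
  list(twStats = tw, nSignificant = as.integer(nSig))
}

#' Admixture magnitude along a reference axis
#'
#' Places each projected sample on the axis joining two reference-population
#' centroids: the scalar projection of (x - centroidA) onto
#' (centroidB - centroidA) divided by the centroid distance, clamped to
#' [0, 1]. 0 means "at A", 1 "at B"; a half-admixed individual sits near
#' 0.5. The quantity is invariant under any orthogonal rotation applied
#' jointly to coordinates and centroids.
#'
#' @param coords samples x D coordinate matrix (e.g.
#'   `projectOntoSpace(...)$coords`), or the list returned by
#'   [projectOntoSpace()].
#' @param centroidA,centroidB coordinate vectors of the two reference
#'   population centroids over the same dimensions.
#' @return numeric vector in [0, 1], one value per sample.
#' @seealso [populationCentroid()]
#' @export
ancestryFraction <- function(coords, centroidA, centroidB) {
  if (is.list(coords) && !is.null(coords$coords)) coords <- coords$coords
  axis <- centroidB - centroidA
  len2 <- sum(axis^2)
  if (len2 == 0) stop("centroids coincide")
  dims <- seq_along(centroidA)
  f <- as.numeric((coords[, dims, drop = FALSE] -
                     matrix(centroidA, nrow(coords), length(dims),
                            byrow = TRUE)) %*% axis) / len2
  pmin(pmax(f, 0), 1)
}

#' Centroid of a labeled reference population in PC space
#'
#' @param space a [PCSpace-class] with population labels.
#' @param population label to average over.
#' @param dims leading dimensions to use (default first 2).
#' @return numeric centroid vector of length `length(dims)`.
#' @export
populationCentroid <- function(space, population, dims = 1:2) {
  if (!length(space@refPopLabels)) stop("space carries no population labels")
  rows <- space@refPopLabels == population
  if (!any(rows)) stop("unknown population: ", population)
  colMeans(space@refCoords[rows, dims, drop = FALSE])
}
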