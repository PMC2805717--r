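#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames rowRanges colData
#' @importFrom stats cor pchisq pnorm quantile rbeta rbinom rgamma rnorm runif
#'   sd setNames var median fisher.test lm mad complete.cases coef residuals
#' @importFrom utils read.delim write.table head
NULL

#' Container for SNP dosage genotypes
#'
#' `GenotypeData` extends
#' [SummarizedExperiment::RangedSummarizedExperiment] to hold an integer
#' alt-allele dosage matrix (SNPs in rows, samples in columns, entries 0/1/2
#' or `NA` for missing calls) together with per-SNP metadata (chromosome,
#' position, ref/alt alleles) stored as the `rowRanges`. Population labels for
#' reference panels live in `colData(x)$population`.
#'
#' Coordinates are 1-based and inclusive, following VCF convention. Dosages
#' always count the alt allele as written; no strand flipping is performed
#' (SNP-array context, a single panel of record).
#'
#' @seealso [GenotypeData()], [readGenotypes()], [dosage()]
#' @export
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

setValidity("GenotypeData", function(object) {
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    return("assay 'dosage' is required")
  d <- SummarizedExperiment::assay(object, "dosage")
  v <- d[!is.na(d)]
  if (length(v) && !all(v %in% c(0, 1, 2)))
    return("dosage entries must be 0, 1, 2 or NA")
  if (anyDuplicated(rownames(object)))
    return("SNP ids must be unique")
  if (anyDuplicated(colnames(object)))
    return("sample ids must be unique")
  mc <- S4Vectors::mcols(SummarizedExperiment::rowRanges(object))
  if (!all(c("ref", "alt") %in% colnames(mc)))
    return("rowRanges must carry 'ref' and 'alt' allele columns")
  if (any(!is.na(mc$ref) & !is.na(mc$alt) & mc$ref == mc$alt))
    return("ref and alt alleles must differ")
  TRUE
})

#' Construct a GenotypeData object
#'
#' @param dosage integer matrix of alt-allele dosages, SNPs in rows and
#'   samples in columns; entries 0/1/2 or `NA` (missing call).
#' @param snps `data.frame` with one row per SNP and columns `id`, `chrom`,
#'   `pos` (1-based basepairs), `ref`, `alt`.
#' @param sampleIds character vector of sample identifiers; defaults to
#'   `colnames(dosage)`.
#' @param population optional character vector of per-sample population
#'   labels (reference panels).
#' @param metadata optional list stored as object metadata.
#'
#' @return A [GenotypeData-class] object.
#' @examples
#' snps <- data.frame(id = c("rs1", "rs2"), chrom = "chr1",
#'                    pos = c(100L, 5000L), ref = "A", alt = c("G", "C"))
#' g <- GenotypeData(matrix(c(0, 1, 2, NA, 1, 0), nrow = 2,
#'                          dimnames = list(snps$id, c("s1", "s2", "s3"))),
#'                   snps)
#' dosage(g)
#' @export
GenotypeData <- function(dosage, snps, sampleIds = colnames(dosage),
                         population = NULL, metadata = list()) {
  stopifnot(is.matrix(dosage), nrow(dosage) == nrow(snps))
  if (is.null(sampleIds))
    sampleIds <- paste0("sample", seq_len(ncol(dosage)))
  if (any(snps$pos < 1)) stop("SNP positions must be >= 1")
  rr <- GenomicRanges::GRanges(
    seqnames = as.character(snps$chrom),
    ranges = IRanges::IRanges(start = as.integer(snps$pos), width = 1L),
    id = as.character(snps$id),
    ref = as.character(snps$ref),
    alt = as.character(snps$alt))
  names(rr) <- as.character(snps$id)
  dimnames(dosage) <- list(as.character(snps$id), sampleIds)
  cd <- S4Vectors::DataFrame(row.names = sampleIds)
  if (!is.null(population)) cd$population <- population
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage), rowRanges = rr, colData = cd,
    metadata = metadata)
  methods::new("GenotypeData", se)
}

#' Container for expression traits
#'
#' `ExpressionData` extends
#' [SummarizedExperiment::RangedSummarizedExperiment] to hold a real-valued
#' expression matrix (traits in rows, samples in columns) with per-trait gene
#' location metadata in `rowRanges` (representative gene position, one
#' integer per trait) and optional per-sample batch labels and covariates in
#' `colData` (`batch`, `age`, `sex`).
#'
#' @seealso [ExpressionData()], [readExpression()], [exprValues()]
#' @export
setClass("ExpressionData", contains = "RangedSummarizedExperiment")

setValidity("ExpressionData", function(object) {
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    return("assay 'exprs' is required")
  v <- SummarizedExperiment::assay(object, "exprs")
  if (any(!is.finite(v)))
    return("expression values must be finite")
  if (anyDuplicated(rownames(object)))
    return("trait ids must be unique")
  if (anyDuplicated(colnames(object)))
    return("sample ids must be unique")
  TRUE
})

#' Construct an ExpressionData object
#'
#' @param values numeric matrix of expression values, traits in rows and
#'   samples in columns.
#' @param genes `data.frame` with one row per trait: `trait_id`,
#'   `gene_symbol`, `chrom`, `pos` (representative gene position, 1-based).
#' @param sampleIds character sample identifiers; defaults to
#'   `colnames(values)`.
#' @param batch optional per-sample batch labels (e.g. two collection sites).
#' @param covariates optional `data.frame` with per-sample columns (e.g.
#'   `age`, `sex`) merged into `colData`.
#' @param metadata optional list stored as object metadata.
#'
#' @return An [ExpressionData-class] object.
#' @export
ExpressionData <- function(values, genes, sampleIds = colnames(values),
                           batch = NULL, covariates = NULL,
                           metadata = list()) {
  stopifnot(is.matrix(values), nrow(values) == nrow(genes))
  if (is.null(sampleIds))
    sampleIds <- paste0("sample", seq_len(ncol(values)))
  if (any(genes$pos < 1)) stop("gene positions must be >= 1")
  rr <- GenomicRanges::GRanges(
    seqnames = as.character(genes$chrom),
    ranges = IRanges::IRanges(start = as.integer(genes$pos), width = 1L),
    trait_id = as.character(genes$trait_id),
    gene_symbol = as.character(genes$gene_symbol))
  names(rr) <- as.character(genes$trait_id)
  dimnames(values) <- list(as.character(genes$trait_id), sampleIds)
  cd <- S4Vectors::DataFrame(row.names = sampleIds)
  if (!is.null(batch)) cd$batch <- batch
  if (!is.null(covariates)) {
    for (nm in setdiff(colnames(covariates), "sampleId"))
      cd[[nm]] <- covariates[[nm]]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values), rowRanges = rr, colData = cd,
    metadata = metadata)
  methods::new("ExpressionData", se)
}

#' Principal-component space of a reference panel
#'
#' Holds everything needed to project new genotypes into a reference
#' eigenspace: the post-thinning SNP ids, the per-SNP normalization
#' parameters (mean dosage and posterior allele frequency), the SNP loadings
#' (orthonormal columns), the eigenvalues of the normalized covariance, and
#' the coordinates of the reference samples themselves with their population
#' labels.
#'
#' @slot snpIds character, SNPs defining the space (in loading row order).
#' @slot normCenter numeric, per-SNP mean dosage used for centering.
#' @slot normFreqs numeric, per-SNP posterior allele frequency used for
#'   scaling.
#' @slot loadings matrix (SNPs x D) with orthonormal columns.
#' @slot eigenvalues numeric length D, non-increasing.
#' @slot spectrum full eigenvalue spectrum of the normalized covariance
#'   (all positive eigenvalues, not just the retained D) — the input the
#'   Tracy-Widom dimension test needs.
#' @slot refCoords matrix (reference samples x D), equal to the normalized
#'   reference matrix times the loadings.
#' @slot refPopLabels character per reference sample.
#' @slot nSamples integer, reference sample count (used by Tracy-Widom).
#' @slot nSnps integer, SNP count the space was built on.
#' @seealso [fitPCA()], [projectOntoSpace()], [tracyWidomCount()]
#' @export
setClass("PCSpace", representation(
  snpIds = "character", snpAlleles = "data.frame",
  normCenter = "numeric", normFreqs = "numeric",
  loadings = "matrix", eigenvalues = "numeric", spectrum = "numeric",
  refCoords = "matrix", refPopLabels = "character",
  nSamples = "integer", nSnps = "integer"))

setValidity("PCSpace", function(object) {
  L <- object@loadings
  if (length(object@snpIds) != nrow(L))
    return("snpIds length must match loading rows")
  if (ncol(L) != length(object@eigenvalues))
    return("eigenvalues length must match loading columns")
  g <- crossprod(L)
  if (max(abs(g - diag(ncol(L)))) > 1e-8)
    return("loading columns must be orthonormal")
  ev <- object@eigenvalues
  if (any(ev < -1e-12) || is.unsorted(rev(ev)))
    return("eigenvalues must be non-negative and non-increasing")
  if (ncol(object@refCoords) != ncol(L))
    return("refCoords dimension must match loadings")
  TRUE
})

#' Cohort simulated under the Balding-Nichols admixture model
#'
#' Bundles the admixed study cohort with its ground truth: genotypes, true
#' per-individual admixture proportions, age/sex covariates, the reference
#' panel the cohort descends from, and the ancestral and per-population
#' allele frequencies.
#'
#' @slot genotypes [GenotypeData-class] for the study cohort.
#' @slot trueQ matrix (samples x K) of admixture proportions, rows sum to 1.
#' @slot covariates `data.frame` with `sampleId`, `age`, `sex`.
#' @slot reference [GenotypeData-class] reference panel with population
#'   labels in `colData`.
#' @slot ancestralFreqs numeric per-SNP ancestral allele frequencies.
#' @slot popFreqs matrix (K populations x SNPs) of drifted frequencies.
#' @seealso [simulateAdmixedCohort()], [simulateStudy()]
#' @export
setClass("AdmixedCohort", representation(
  genotypes = "GenotypeData", trueQ = "matrix", covariates = "data.frame",
  reference = "GenotypeData", ancestralFreqs = "numeric",
  popFreqs = "matrix"))

setValidity("AdmixedCohort", function(object) {
  if (max(abs(rowSums(object@trueQ) - 1)) > 1e-12)
    return("rows of trueQ must sum to 1")
  if (any(object@ancestralFreqs <= 0 | object@ancestralFreqs >= 1))
    return("ancestral frequencies must lie in (0,1)")
  if (any(object@popFreqs <= 0 | object@popFreqs >= 1))
    return("population frequencies must lie in (0,1)")
  if (nrow(object@trueQ) != ncol(object@genotypes))
    return("trueQ rows must match cohort samples")
  TRUE
})
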