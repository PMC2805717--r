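#' Extract the dosage matrix
#'
#' @param x a [GenotypeData-class] object.
#' @return integer matrix, SNPs x samples, entries 0/1/2/NA.
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname dosage
#' @export
setMethod("dosage", "GenotypeData",
          function(x) SummarizedExperiment::assay(x, "dosage"))

#' SNP metadata as a data.frame
#'
#' @param x a [GenotypeData-class] object.
#' @return `data.frame` with columns `id`, `chrom`, `pos`, `ref`, `alt`.
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @rdname snpInfo
#' @export
setMethod("snpInfo", "GenotypeData", function(x) {
  rr <- SummarizedExperiment::rowRanges(x)
  data.frame(id = S4Vectors::mcols(rr)$id,
             chrom = as.character(GenomicRanges::seqnames(rr)),
             pos = GenomicRanges::start(rr),
             ref = S4Vectors::mcols(rr)$ref,
             alt = S4Vectors::mcols(rr)$alt,
             row.names = NULL, stringsAsFactors = FALSE)
})

#' Extract the expression matrix
#'
#' @param x an [ExpressionData-class] object.
#' @return numeric matrix, traits x samples.
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname exprValues
#' @export
setMethod("exprValues", "ExpressionData",
          function(x) SummarizedExperiment::assay(x, "exprs"))

#' Gene/trait metadata as a data.frame
#'
#' @param x an [ExpressionData-class] object.
#' @return `data.frame` with columns `trait_id`, `gene_symbol`, `chrom`,
#'   `pos`.
#' @export
setGeneric("geneInfo", function(x) standardGeneric("geneInfo"))

#' @rdname geneInfo
#' @export
setMethod("geneInfo", "ExpressionData", function(x) {
  rr <- SummarizedExperiment::rowRanges(x)
  data.frame(trait_id = S4Vectors::mcols(rr)$trait_id,
             gene_symbol = S4Vectors::mcols(rr)$gene_symbol,
             chrom = as.character(GenomicRanges::seqnames(rr)),
             pos = GenomicRanges::start(rr),
             row.names = NULL, stringsAsFactors = FALSE)
})

#' Per-sample batch labels
#'
#' @param x an [ExpressionData-class] object.
#' @return character vector of batch labels, or `NULL` when absent.
#' @export
setGeneric("batchLabels", function(x) standardGeneric("batchLabels"))

#' @rdname batchLabels
#' @export
setMethod("batchLabels", "ExpressionData", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("batch" %in% colnames(cd)) as.character(cd$batch) else NULL
})

setMethod("show", "PCSpace", function(object) {
  cat("PCSpace with", ncol(object@loadings), "dimensions\n")
  cat("  SNPs:", length(object@snpIds),
      " reference samples:", nrow(object@refCoords), "\n")
  cat("  eigenvalues:",
      paste(signif(head(object@eigenvalues, 5), 4), collapse = ", "),
      if (length(object@eigenvalues) > 5) "..." else "", "\n")
  if (length(object@refPopLabels))
    cat("  populations:",
        paste(unique(object@refPopLabels), collapse = ", "), "\n")
})

setMethod("show", "AdmixedCohort", function(object) {
  cat("AdmixedCohort:", ncol(object@genotypes), "study samples,",
      nrow(object@genotypes), "SNPs,",
      ncol(object@trueQ), "ancestral populations\n")
  cat("  reference panel:", ncol(object@reference), "samples\n")
})

#' Accessors for AdmixedCohort components
#'
#' @param x an [AdmixedCohort-class] object.
#' @return `cohortGenotypes` and `cohortReference` return
#'   [GenotypeData-class]; `trueAdmixture` the samples x K proportion
#'   matrix; `cohortCovariates` the covariate `data.frame`.
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
setGeneric("cohortGenotypes", function(x) standardGeneric("cohortGenotypes"))
#' @rdname cohort-accessors
#' @export
setMethod("cohortGenotypes", "AdmixedCohort", function(x) x@genotypes)

#' @rdname cohort-accessors
#' @export
setGeneric("trueAdmixture", function(x) standardGeneric("trueAdmixture"))
#' @rdname cohort-accessors
#' @export
setMethod("trueAdmixture", "AdmixedCohort", function(x) x@trueQ)

#' @rdname cohort-accessors
#' @export
setGeneric("cohortCovariates", function(x) standardGeneric("cohortCovariates"))
#' @rdname cohort-accessors
#' @export
setMethod("cohortCovariates", "AdmixedCohort", function(x) x@covariates)

#' @rdname cohort-accessors
#' @export
setGeneric("cohortReference", function(x) standardGeneric("cohortReference"))
#' @rdname cohort-accessors
#' @export
setMethod("cohortReference", "AdmixedCohort", function(x) x@reference)

#' Accessors for PCSpace components
#'
#' @param x a [PCSpace-class] object.
#' @return `pcLoadings` the SNPs x D loading matrix; `pcEigenvalues` the
#'   eigenvalue vector; `refCoords` the reference-sample coordinates;
#'   `refPopLabels` their population labels.
#' @name pcspace-accessors
NULL

#' @rdname pcspace-accessors
#' @export
setGeneric("pcLoadings", function(x) standardGeneric("pcLoadings"))
#' @rdname pcspace-accessors
#' @export
setMethod("pcLoadings", "PCSpace", function(x) x@loadings)

#' @rdname pcspace-accessors
#' @export
setGeneric("pcEigenvalues", function(x) standardGeneric("pcEigenvalues"))
#' @rdname pcspace-accessors
#' @export
setMethod("pcEigenvalues", "PCSpace", function(x) x@eigenvalues)

#' @rdname pcspace-accessors
#' @export
setGeneric("pcSpectrum", function(x) standardGeneric("pcSpectrum"))
#' @rdname pcspace-accessors
#' @export
setMethod("pcSpectrum", "PCSpace", function(x) x@spectrum)

#' @rdname pcspace-accessors
#' @export
setGeneric("refCoords", function(x) standardGeneric("refCoords"))
#' @rdname pcspace-accessors
#' @export
setMethod("refCoords", "PCSpace", function(x) x@refCoords)

#' @rdname pcspace-accessors
#' @export
setGeneric("refPopLabels", function(x) standardGeneric("refPopLabels"))
#' @rdname pcspace-accessors
#' @export
setMethod("refPopLabels", "PCSpace", function(x) x@refPopLabels)
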