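#' Read a genotype matrix from VCF or the dosage TSV dialect
#'
#' Two formats are supported. `"vcf"` reads a VCF (v4.x) through
#' \pkg{vcfR}, using only the GT field; records that are not biallelic SNPs
#' (multi-allelic ALT or indel alleles) are skipped with a message giving
#' the count. Missing calls (`./.`) become `NA`, never 0. `"dosage"` reads
#' the package's documented TSV dialect: first column `sample_id`, header
#' row of SNP ids, entries 0/1/2/NA (samples in rows). SNP map metadata
#' (id, chrom, pos, ref, alt) is read from `mapPath`, by default
#' `<path>.snps.tsv` as written by [writeGenotypes()].
#'
#' @param path path to the genotype file.
#' @param format `"vcf"` or `"dosage"`.
#' @param mapPath for `format = "dosage"`, path to the SNP map TSV; if the
#'   file does not exist, placeholder map metadata is synthesized.
#' @return A [GenotypeData-class] object with dosages counting the alt
#'   allele as written.
#' @export
readGenotypes <- function(path, format = c("dosage", "vcf"),
                          mapPath = paste0(path, ".snps.tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") return(.readVcfGenotypes(path))

  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2 || colnames(tab)[1] != "sample_id")
    stop("malformed dosage TSV header: first column must be 'sample_id'")
  sampleIds <- as.character(tab[[1]])
  d <- t(as.matrix(tab[, -1, drop = FALSE]))   # SNPs x samples
  storage.mode(d) <- "double"
  snpIds <- rownames(d)
  if (anyDuplicated(snpIds)) stop("duplicate SNP ids in dosage file")
  if (file.exists(mapPath)) {
    snps <- read.delim(mapPath, stringsAsFactors = FALSE)
    if (!all(c("id", "chrom", "pos", "ref", "alt") %in% colnames(snps)))
      stop("malformed SNP map header in ", mapPath)
    snps <- snps[match(snpIds, snps$id), ]
    if (anyNA(snps$id)) stop("SNP map is missing entries for some SNP ids")
  } else {
    snps <- data.frame(id = snpIds, chrom = "chrUn",
                       pos = seq_along(snpIds), ref = "A", alt = "G",
                       stringsAsFactors = FALSE)
  }
  GenotypeData(d, snps, sampleIds = sampleIds)
}

.readVcfGenotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ok <- !is.na(fix$REF) & !is.na(fix$ALT) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE)
  if (any(!ok))
    message(sum(!ok), " non-biallelic-SNP record(s) skipped")
  if (!any(ok)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[ok, , drop = FALSE]
  fix <- fix[ok, , drop = FALSE]
  ids <- fix$ID
  noId <- is.na(ids) | ids == "."
  ids[noId] <- paste0(fix$CHROM[noId], "_", fix$POS[noId])
  if (anyDuplicated(ids)) stop("duplicate SNP ids in VCF")
  d <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  called <- !is.na(gt) & !grepl("\\.", gt)
  d[called] <- vapply(strsplit(gsub("\\|", "/", gt[called]), "/"),
                      function(a) sum(a == "1"), numeric(1))
  rownames(d) <- ids
  snps <- data.frame(id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  GenotypeData(d, snps, sampleIds = colnames(gt))
}

#' Write a genotype matrix in the dosage TSV dialect
#'
#' Writes two files: the dosage table (`sample_id` column, SNP-id header,
#' entries 0/1/2/NA, samples in rows) and a SNP map TSV
#' (`id`, `chrom`, `pos`, `ref`, `alt`).
#'
#' @param x a [GenotypeData-class] object.
#' @param path output path for the dosage TSV.
#' @param mapPath output path for the SNP map (default `<path>.snps.tsv`).
#' @return Invisibly, `path`.
#' @export
writeGenotypes <- function(x, path, mapPath = paste0(path, ".snps.tsv")) {
  d <- t(dosage(x))   # samples x SNPs
  out <- data.frame(sample_id = rownames(d), d, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(snpInfo(x), mapPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix with gene annotation
#'
#' The expression TSV has traits in rows: first column `trait_id`, header
#' row of sample ids, numeric entries. The annotation TSV supplies columns
#' `trait_id`, `gene_symbol`, `chrom`, `pos`; traits without annotation are
#' dropped with a message giving the count.
#'
#' @param path expression TSV path.
#' @param annotationPath gene annotation TSV path.
#' @return An [ExpressionData-class] object.
#' @export
readExpression <- function(path, annotationPath) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(tab) < 2 || colnames(tab)[1] != "trait_id")
    stop("malformed expression TSV header: first column must be 'trait_id'")
  traitIds <- tab[[1]]
  vals <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals),
                                 dimnames = dimnames(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric expression value at trait '", traitIds[bad[1]],
         "', sample '", colnames(vals)[bad[2]], "'")
  }
  rownames(num) <- traitIds
  ann <- read.delim(annotationPath, stringsAsFactors = FALSE)
  if (!all(c("trait_id", "gene_symbol", "chrom", "pos") %in% colnames(ann)))
    stop("malformed annotation header in ", annotationPath)
  keep <- traitIds %in% ann$trait_id
  if (any(!keep))
    message(sum(!keep), " trait(s) dropped: no gene annotation")
  if (!any(keep)) stop("no annotated traits in ", path)
  num <- num[keep, , drop = FALSE]
  genes <- ann[match(rownames(num), ann$trait_id), ]
  ExpressionData(num, genes, sampleIds = colnames(num))
}

#' Write an expression matrix and its gene annotation
#'
#' @param x an [ExpressionData-class] object.
#' @param path output expression TSV path.
#' @param annotationPath output annotation TSV path.
#' @return Invisibly, `path`.
#' @export
writeExpression <- function(x, path, annotationPath) {
  v <- exprValues(x)
  out <- data.frame(trait_id = rownames(v),
                    apply(v, 2, function(col) sprintf("%.17g", col)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out) <- c("trait_id", colnames(v))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(geneInfo(x), annotationPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write an association result table
#'
#' Writes the documented association TSV dialect: columns `trait_id`,
#' `snp_id`, `chrom_trait`, `pos_trait`, `chrom_snp`, `pos_snp`, `K`, `p`,
#' `class` (cis/trans), `r2`; rows sorted by `(trait_id, p)`. Numeric
#' columns are written with full double precision so that
#' [readAssociationTable()] reproduces the records exactly. An empty record
#' set yields a header-only file.
#'
#' @param records association `data.frame` as returned by [scanEqtls()].
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
writeAssociationTable <- function(records, path) {
  cols <- c("trait_id", "snp_id", "chrom_trait", "pos_trait",
            "chrom_snp", "pos_snp", "K", "p", "class", "r2")
  if (is.null(records) || nrow(records) == 0) {
    writeLines(paste(cols, collapse = "\t"), path)
    return(invisible(path))
  }
  rec <- records
  if ("relation" %in% colnames(rec) && !"class" %in% colnames(rec))
    rec$class <- rec$relation
  if (!"r2" %in% colnames(rec)) rec$r2 <- NA_real_
  missing <- setdiff(cols, colnames(rec))
  if (length(missing))
    stop("records lack column(s): ", paste(missing, collapse = ", "))
  rec <- rec[order(rec$trait_id, rec$p), cols]
  for (nm in c("K", "p", "r2"))
    rec[[nm]] <- ifelse(is.na(rec[[nm]]), "NA", sprintf("%.17g", rec[[nm]]))
  write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an association result table
#'
#' @param path TSV written by [writeAssociationTable()].
#' @return association `data.frame` with a `relation` column mirroring the
#'   file's `class` column.
#' @export
readAssociationTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  for (nm in c("K", "p", "r2"))
    if (nm %in% colnames(tab)) tab[[nm]] <- as.numeric(tab[[nm]])
  tab$relation <- tab$class
  tab
}

#' Read a covariate table
#'
#' TSV with columns `sample_id`, `age` (years, > 0), `sex` (0/1).
#'
#' @param path covariate TSV path.
#' @return `data.frame` with columns `sampleId`, `age`, `sex`.
#' @export
readCovariates <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "age", "sex") %in% colnames(tab)))
    stop("malformed covariate header in ", path)
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample ids")
  if (any(tab$age <= 0)) stop("ages must be positive")
  if (!all(tab$sex %in% c(0, 1))) stop("sex must be coded 0/1")
  data.frame(sampleId = tab$sample_id, age = tab$age, sex = tab$sex,
             stringsAsFactors = FALSE)
}

# intersect sample ids across objects, warning when some are lost
.alignSamples <- function(idsA, idsB, what = "samples") {
  shared <- intersect(idsA, idsB)
  if (length(shared) == 0) stop("no overlapping ", what)
  if (length(shared) < max(length(idsA), length(idsB)))
    warning(length(shared), " shared ", what, " retained; ",
            max(length(idsA), length(idsB)) - length(shared), " dropped")
  shared
}
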