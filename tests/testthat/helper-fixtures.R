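# small in-code fixtures shared across test files

# tiny genotype object: dosage given samples x SNPs for readability
makeGenotypes <- function(dosageBySample, chrom = NULL, pos = NULL,
                          ids = NULL) {
  S <- ncol(dosageBySample)
  if (is.null(ids)) ids <- paste0("rs", seq_len(S))
  if (is.null(chrom)) chrom <- rep("chr1", S)
  if (is.null(pos)) pos <- seq_len(S) * 1000L
  snps <- data.frame(id = ids, chrom = chrom, pos = pos,
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  GenotypeData(t(dosageBySample), snps,
               sampleIds = rownames(dosageBySample))
}

makeExpression <- function(valuesBySample, chrom = NULL, pos = NULL,
                           batch = NULL, covariates = NULL) {
  Tn <- ncol(valuesBySample)
  if (is.null(chrom)) chrom <- rep("chr1", Tn)
  if (is.null(pos)) pos <- seq_len(Tn) * 10000L
  genes <- data.frame(trait_id = paste0("t", seq_len(Tn)),
                      gene_symbol = paste0("G", seq_len(Tn)),
                      chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  ExpressionData(t(valuesBySample), genes,
                 sampleIds = rownames(valuesBySample),
                 batch = batch, covariates = covariates)
}

# Hudson FST estimator (ratio of averages), independent of the generator
hudsonFst <- function(p1, p2, n1, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

writeTestVcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           "s1\ts2\ts3"),
    "chr1\t100\tsnpA\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\tsnpB\tC\tT\t.\tPASS\t.\tGT\t0/1\t./.\t1/1",
    "chr1\t300\tsnpC\tG\tA,C\t.\tPASS\t.\tGT\t0/1\t0/2\t0/0",
    "chr1\t400\tsnpD\tGA\tG\t.\tPASS\t.\tGT\t0/1\t0/0\t0/0"
  ), path)
  path
}
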