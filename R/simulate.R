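#' Simulation configuration for the admixed study test-bed
#'
#' Bundles and validates the parameters of the Balding-Nichols generator.
#' Defaults emulate a small admixed cohort of the kind where stratification
#' adjustment matters most: 60 study samples descending from two ancestral
#' populations (African-weighted Dirichlet admixture), a two-population
#' reference panel of 100 samples each at FST 0.2, 1000 independent SNPs on
#' a 5-chromosome x 50 Mbp map, 300 expression traits of which 60 carry a
#' planted cis effect, ancestry-driven expression shifts, and age/sex
#' covariate effects. The ancestry shift scale (`ancestryEffectSd = 0.1`)
#' is set so that a two-group expression comparison at this cohort size
#' reproduces the small differential-expression fractions (1-2% of traits
#' at alpha 0.01) typical of bulk contrasts between admixed ancestry
#' groups.
#'
#' `cisBeta` is expressed in noise-SD units per alt allele; the default 1.4
#' puts the variance explained by a typical planted cis effect (dosage
#' variance about 2p(1-p) at intermediate frequency) in the 0.4-0.55 range
#' observed for strong liver cis-eQTLs. `causalMinFreqDiff` restricts
#' causal SNPs to those with at least that absolute frequency difference
#' between the first two ancestral populations, making planted effects
#' collide with ancestry the way stratification-confounded signals do.
#'
#' @param nPopulations number of ancestral populations K (>= 2).
#' @param fst per-population Balding-Nichols drift, recycled to K; in (0,1).
#' @param nRefPerPop reference samples per population.
#' @param nStudy study cohort size.
#' @param nSnps number of SNPs.
#' @param admixAlpha Dirichlet concentration, length K.
#' @param nTraits number of expression traits.
#' @param nCisTrue number of traits with a planted cis effect.
#' @param cisBeta genetic effect size (noise-SD units per alt allele).
#' @param cisR2Mean,cisR2Sd optional per-trait variance-explained target:
#'   when `cisR2Mean` is not `NA`, each cis trait's effect is drawn as
#'   `beta = noiseSd * sqrt(r2 / (1 - r2)) / sd(dosage)` with
#'   `r2 ~ N(cisR2Mean, cisR2Sd)` truncated to (0.05, 0.85), overriding
#'   `cisBeta`; useful for emulating a heterogeneous effect-size spectrum.
#' @param causalMinMaf optional minimum cohort-level minor-allele
#'   frequency for eligible causal SNPs (default 0: effects are planted
#'   at all frequencies and detection does the filtering, as in real
#'   cohorts).
#' @param ancestryEffectSd per-trait ancestry shift scale (SD of the
#'   N(0, sd) draw multiplying the first admixture proportion).
#' @param ageBeta,sexBeta covariate effects (per year; per sex class).
#' @param noiseSd residual SD of the trait model.
#' @param cisWindow cis window in basepairs for causal SNP placement.
#' @param causalMinFreqDiff minimum |p1 - p2| for eligible causal SNPs.
#' @param batchShift,batchScale optional location/scale distortion applied
#'   to the second collection batch (defaults: none).
#' @param chromLengths named vector of chromosome lengths in bp.
#' @param seed master seed; submodule seeds are derived at fixed offsets
#'   (+1 reference panel, +2 cohort, +3 expression).
#' @return A validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(nPopulations = 2,
                             fst = 0.2,
                             nRefPerPop = 100,
                             nStudy = 60,
                             nSnps = 1000,
                             admixAlpha = c(3, 1),
                             nTraits = 300,
                             nCisTrue = 60,
                             cisBeta = 1.4,
                             cisR2Mean = NA_real_,
                             cisR2Sd = 0.14,
                             causalMinMaf = 0,
                             ancestryEffectSd = 0.1,
                             ageBeta = 0.01,
                             sexBeta = 0.2,
                             noiseSd = 1,
                             cisWindow = 1e6,
                             causalMinFreqDiff = 0.1,
                             batchShift = 0,
                             batchScale = 1,
                             chromLengths = setNames(rep(5e7, 5),
                                                     paste0("chr", 1:5)),
                             seed = 1L) {
  cfg <- list(nPopulations = as.integer(nPopulations),
              fst = rep_len(fst, nPopulations),
              nRefPerPop = as.integer(nRefPerPop),
              nStudy = as.integer(nStudy),
              nSnps = as.integer(nSnps),
              admixAlpha = admixAlpha,
              nTraits = as.integer(nTraits),
              nCisTrue = as.integer(nCisTrue),
              cisBeta = cisBeta,
              cisR2Mean = cisR2Mean, cisR2Sd = cisR2Sd,
              causalMinMaf = causalMinMaf,
              ancestryEffectSd = ancestryEffectSd,
              ageBeta = ageBeta, sexBeta = sexBeta,
              noiseSd = noiseSd,
              cisWindow = cisWindow,
              causalMinFreqDiff = causalMinFreqDiff,
              batchShift = batchShift, batchScale = batchScale,
              chromLengths = chromLengths,
              seed = as.integer(seed))
  if (cfg$nPopulations < 2) stop("nPopulations must be >= 2")
  if (any(cfg$fst <= 0 | cfg$fst >= 1)) stop("fst must lie in (0,1)")
  if (length(cfg$admixAlpha) != cfg$nPopulations)
    stop("admixAlpha must have length nPopulations")
  if (cfg$nCisTrue > cfg$nTraits) stop("nCisTrue must be <= nTraits")
  if (any(c(cfg$nRefPerPop, cfg$nStudy, cfg$nSnps, cfg$nTraits) <= 0))
    stop("counts must be positive")
  class(cfg) <- "SimulationConfig"
  cfg
}

# SNP positions drawn uniformly over the chromosome map, returned sorted
.drawSnpMap <- function(nSnps, chromLengths) {
  chrom <- sample(names(chromLengths), nSnps, replace = TRUE,
                  prob = chromLengths / sum(chromLengths))
  pos <- floor(runif(nSnps, 1, chromLengths[chrom] + 1))
  ord <- order(match(chrom, names(chromLengths)), pos)
  data.frame(id = sprintf("snp%05d", seq_len(nSnps)),
             chrom = chrom[ord], pos = as.integer(pos[ord]),
             ref = "A", alt = "G", stringsAsFactors = FALSE)
}

#' Simulate a multi-population reference panel
#'
#' Balding-Nichols drift: per SNP, an ancestral frequency p ~ Uniform(0.1,
#' 0.9); population k's frequency p_k ~ Beta(p(1-F_k)/F_k,
#' (1-p)(1-F_k)/F_k); genotypes ~ Binomial(2, p_k). SNPs whose drifted
#' frequency is numerically 0 or 1 in any population are resampled. SNP
#' positions are uniform over the configured chromosome map; SNPs are
#' independent (no LD).
#'
#' @param config a [simulationConfig()] object.
#' @param seed integer seed (default derived from `config$seed + 1`).
#' @return A [GenotypeData-class] panel with `colData(x)$population` labels
#'   `POP1..POPK` and `metadata(x)$popFreqs` (K x SNPs) /
#'   `metadata(x)$ancestralFreqs`.
#' @export
simulateReferencePanel <- function(config, seed = config$seed + 1L) {
  set.seed(seed)
  K <- config$nPopulations
  S <- config$nSnps
  eps <- 1e-6
  p <- runif(S, 0.1, 0.9)
  popFreqs <- matrix(NA_real_, K, S,
                     dimnames = list(paste0("POP", seq_len(K)), NULL))
  for (k in seq_len(K)) {
    Fk <- config$fst[k]
    popFreqs[k, ] <- rbeta(S, p * (1 - Fk) / Fk, (1 - p) * (1 - Fk) / Fk)
  }
  bad <- which(apply(popFreqs, 2, function(q) any(q < eps | q > 1 - eps)))
  while (length(bad)) {
    p[bad] <- runif(length(bad), 0.1, 0.9)
    for (k in seq_len(K)) {
      Fk <- config$fst[k]
      popFreqs[k, bad] <- rbeta(length(bad), p[bad] * (1 - Fk) / Fk,
                                (1 - p[bad]) * (1 - Fk) / Fk)
    }
    bad <- which(apply(popFreqs, 2, function(q) any(q < eps | q > 1 - eps)))
  }
  snps <- .drawSnpMap(S, config$chromLengths)
  n <- config$nRefPerPop * K
  popLabels <- rep(paste0("POP", seq_len(K)), each = config$nRefPerPop)
  # dosage SNPs x samples
  d <- matrix(NA_real_, S, n)
  for (k in seq_len(K)) {
    cols <- which(popLabels == paste0("POP", k))
    d[, cols] <- matrix(rbinom(S * length(cols), 2, popFreqs[k, ]),
                        nrow = S)
  }
  sampleIds <- sprintf("ref%04d", seq_len(n))
  GenotypeData(d, snps, sampleIds = sampleIds, population = popLabels,
               metadata = list(popFreqs = popFreqs, ancestralFreqs = p,
                               chromLengths = config$chromLengths))
}

#' Simulate an admixed study cohort
#'
#' Per individual, admixture proportions q ~ Dirichlet(alpha); per SNP, the
#' individual allele frequency is the q-weighted mixture of the drifted
#' population frequencies, and the dosage is Binomial(2, .). Covariates:
#' age ~ Uniform(20, 80), sex ~ Bernoulli(0.5). The true admixture matrix
#' is recorded for parameter-recovery checks.
#'
#' @param config a [simulationConfig()] object.
#' @param panel reference panel from [simulateReferencePanel()]; the cohort
#'   uses the same SNPs and drifted population frequencies.
#' @param seed integer seed (default `config$seed + 2`).
#' @return An [AdmixedCohort-class] object.
#' @export
simulateAdmixedCohort <- function(config, panel,
                                  seed = config$seed + 2L) {
  set.seed(seed)
  md <- S4Vectors::metadata(panel)
  popFreqs <- md$popFreqs
  K <- nrow(popFreqs)
  if (length(config$admixAlpha) != K)
    stop("admixAlpha length must equal the number of panel populations")
  n <- config$nStudy
  g <- matrix(rgamma(n * K, shape = rep(config$admixAlpha, each = n)),
              n, K)
  Q <- g / rowSums(g)
  indFreq <- Q %*% popFreqs               # samples x SNPs
  d <- matrix(rbinom(length(indFreq), 2, t(indFreq)),
              nrow = ncol(indFreq))       # SNPs x samples
  sampleIds <- sprintf("study%04d", seq_len(n))
  rownames(Q) <- sampleIds
  colnames(Q) <- rownames(popFreqs)
  covar <- data.frame(sampleId = sampleIds,
                      age = runif(n, 20, 80),
                      sex = rbinom(n, 1, 0.5),
                      stringsAsFactors = FALSE)
  geno <- GenotypeData(d, snpInfo(panel), sampleIds = sampleIds,
                       metadata = list(chromLengths = config$chromLengths))
  methods::new("AdmixedCohort", genotypes = geno, trueQ = Q,
               covariates = covar, reference = panel,
               ancestralFreqs = md$ancestralFreqs, popFreqs = popFreqs)
}

#' Simulate expression traits with planted cis effects
#'
#' Each trait's value is `beta * dosage(causal SNP)` (0 for null traits)
#' `+ a_t * q1 + ageBeta * age + sexBeta * sex + Normal(0, noiseSd)`, where
#' `q1` is the individual's first admixture proportion and the per-trait
#' ancestry shift `a_t ~ Normal(0, ancestryEffectSd)`. Causal SNPs are
#' drawn from SNPs whose inter-population frequency difference is at least
#' `causalMinFreqDiff`; the trait's gene position is placed uniformly
#' within the cis window of its causal SNP (null traits get a uniform
#' position on the map). Two collection batches are assigned
#' (alternating), with an optional location/scale distortion of batch B.
#'
#' @param cohort an [AdmixedCohort-class] object.
#' @param config the [simulationConfig()] used to build the cohort.
#' @param seed integer seed (default `config$seed + 3`).
#' @return list with `expression` ([ExpressionData-class]; batch, age and
#'   sex in `colData`) and `truth` (`data.frame`: `trait_id`,
#'   `causal_snp_id` (`NA` for nulls), `beta`, `ancestry_effect`).
#' @export
simulateExpression <- function(cohort, config, seed = config$seed + 3L) {
  set.seed(seed)
  geno <- cohortGenotypes(cohort)
  snps <- snpInfo(geno)
  d <- dosage(geno)                        # SNPs x samples
  n <- ncol(d)
  Tn <- config$nTraits
  nc <- config$nCisTrue
  freqDiff <- abs(cohort@popFreqs[1, ] - cohort@popFreqs[2, ])
  # cohort-level frequency under the mean admixture proportions
  qbar <- colMeans(trueAdmixture(cohort))
  pMix <- as.numeric(qbar %*% cohort@popFreqs)
  eligible <- which(freqDiff >= config$causalMinFreqDiff &
                      pMix >= config$causalMinMaf &
                      pMix <= 1 - config$causalMinMaf)
  if (length(eligible) < 1)
    stop("no SNPs satisfy causalMinFreqDiff")
  causalIdx <- sample(eligible, nc, replace = nc > length(eligible))
  chromLen <- config$chromLengths

  traitIds <- sprintf("trait%05d", seq_len(Tn))
  genePos <- integer(Tn)
  geneChrom <- character(Tn)
  # cis traits: gene within the cis window of the causal SNP
  for (i in seq_len(nc)) {
    s <- causalIdx[i]
    L <- chromLen[[snps$chrom[s]]]
    lo <- max(1, snps$pos[s] - config$cisWindow)
    hi <- min(L, snps$pos[s] + config$cisWindow)
    genePos[i] <- floor(runif(1, lo, hi + 1))
    geneChrom[i] <- snps$chrom[s]
  }
  if (Tn > nc) {
    idx <- (nc + 1):Tn
    geneChrom[idx] <- sample(names(chromLen), length(idx), replace = TRUE,
                             prob = chromLen / sum(chromLen))
    genePos[idx] <- floor(runif(length(idx), 1, chromLen[geneChrom[idx]] + 1))
  }

  if (nc == 0) {
    betaCis <- numeric(0)
  } else if (!is.na(config$cisR2Mean)) {
    # per-trait effect targeting r2 ~ N(cisR2Mean, cisR2Sd), truncated
    r2t <- rnorm(nc, config$cisR2Mean, config$cisR2Sd)
    r2t <- pmin(pmax(r2t, 0.05), 0.85)
    sdg <- apply(d[causalIdx, , drop = FALSE], 1, sd)
    sdg[sdg == 0] <- 1
    betaCis <- config$noiseSd * sqrt(r2t / (1 - r2t)) / sdg
  } else {
    betaCis <- rep(config$cisBeta, nc)
  }
  beta <- c(betaCis, rep(0, Tn - nc))
  aEff <- rnorm(Tn, 0, config$ancestryEffectSd)
  q1 <- trueAdmixture(cohort)[, 1]
  covar <- cohortCovariates(cohort)

  Y <- matrix(rnorm(n * Tn, 0, config$noiseSd), n, Tn)  # samples x traits
  for (i in seq_len(nc)) Y[, i] <- Y[, i] + beta[i] * d[causalIdx[i], ]
  Y <- Y + outer(q1, aEff) +
    config$ageBeta * covar$age + config$sexBeta * covar$sex

  batch <- rep(c("siteA", "siteB"), length.out = n)
  if (config$batchShift != 0 || config$batchScale != 1) {
    b2 <- batch == "siteB"
    Y[b2, ] <- Y[b2, ] * config$batchScale + config$batchShift
  }

  genes <- data.frame(trait_id = traitIds,
                      gene_symbol = toupper(traitIds),
                      chrom = geneChrom, pos = genePos,
                      stringsAsFactors = FALSE)
  expr <- ExpressionData(t(Y), genes, sampleIds = colnames(d),
                         batch = batch,
                         covariates = covar[, c("age", "sex")])
  truth <- data.frame(trait_id = traitIds,
                      causal_snp_id = c(snps$id[causalIdx],
                                        rep(NA_character_, Tn - nc)),
                      beta = beta, ancestry_effect = aEff,
                      stringsAsFactors = FALSE)
  list(expression = expr, truth = truth)
}

#' Simulate the full study: panel, cohort, and expression
#'
#' Convenience wrapper chaining [simulateReferencePanel()],
#' [simulateAdmixedCohort()] and [simulateExpression()] with submodule
#' seeds derived from `config$seed` at fixed offsets (+1, +2, +3), so that
#' identical configurations yield bit-identical studies.
#'
#' @param config a [simulationConfig()] object.
#' @return list with `panel`, `cohort`, `expression`, `truth`.
#' @export
simulateStudy <- function(config) {
  panel <- simulateReferencePanel(config)
  cohort <- simulateAdmixedCohort(config, panel)
  ex <- simulateExpression(cohort, config)
  list(panel = panel, cohort = cohort,
       expression = ex$expression, truth = ex$truth)
}
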