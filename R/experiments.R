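## Study-condition validation experiments. Each function rebuilds its
## inputs with the synthetic generator at the dimensions of the maize RIL
## study (275 lines, 10 chromosomes, ~2,181 cM, 1% call error, 5%
## missingness) or a documented reduction of them, runs the pipeline stage
## under test, and returns the measured quantities. They back both the
## package's acceptance tests and scripts/acceptance.R.

#' Simulate an observed population at study dimensions
#'
#' Maize-scale chromosomes (subset of the 10), selfed-RIL lines, symmetric
#' call errors and missingness, then QC-free bin calling and map building.
#'
#' @param seed integer seed (all stages derive substreams from it).
#' @param chromIdx which maize chromosomes to include (default all 10).
#' @param nLines number of RILs (default 275).
#' @param nSnpsPerChrom SNPs per chromosome (default 300).
#' @param errorRate,missingRate corruption rates (defaults 0.01 / 0.05).
#' @param selfingGenerations selfing generations (default 6).
#' @return list with `template`, `truth`, `calls` (clean), `observed`
#'   (corrupted), `binCall` (result of [callBinMap()]), `map`
#'   ([GeneticMap-class]).
#' @export
studyPopulation <- function(seed, chromIdx = 1:10, nLines = 275L,
                            nSnpsPerChrom = 300L, errorRate = 0.01,
                            missingRate = 0.05, selfingGenerations = 6L) {
  template <- buildGenomeTemplate(length(chromIdx),
    MAIZE_BP_LENGTHS[chromIdx], MAIZE_CM_LENGTHS[chromIdx],
    nSnpsPerChrom, seed = deriveSeed(seed, 1),
    chromNames = paste0("chr", chromIdx))
  pop <- simulateRILPopulation(template, nLines, selfingGenerations,
    seed = deriveSeed(seed, 2))
  observed <- if (errorRate > 0 || missingRate > 0)
    corruptGenotypes(pop$calls, errorRate, missingRate,
      seed = deriveSeed(seed, 3))
  else pop$calls
  lens <- setNames(template@chromosomes$bpLength, template@chromosomes$name)
  binCall <- callBinMap(observed, lens)
  map <- buildGeneticMap(binCall$binMap, generations = selfingGenerations)
  list(template = template, truth = pop$truth, calls = pop$calls,
    observed = observed, binCall = binCall, map = map)
}

#' Genome-wide permutation LOD threshold under study conditions
#'
#' A 275-line, 10-chromosome (~2,181 cM nominal) population with a null
#' standard-normal phenotype, scanned at the bin-marker positions; the
#' threshold is the 95th percentile of the genome-wide maximum LOD over
#' `nPerm` phenotype permutations.
#'
#' @param seed integer seed.
#' @param nPerm permutations (default 1000).
#' @param alpha genome-wide level (default 0.05).
#' @return list with `threshold`, `mapCM` (estimated map length), `nBins`,
#'   `n` (lines).
#' @export
permutationThresholdExperiment <- function(seed = 1L, nPerm = 1000L,
                                           alpha = 0.05) {
  sp <- studyPopulation(seed)
  probs <- genotypeProbs(sp$map, gridStep = 1e6)   # marker positions only
  lines <- lineIds(sp$binCall$binMap)
  y <- setNames(withSeed(deriveSeed(seed, 4), rnorm(length(lines))), lines)
  thr <- permutationThreshold(probs, y, sp$map, nPerm = nPerm,
    alpha = alpha, seed = deriveSeed(seed, 5))
  list(threshold = as.numeric(thr),
    mapCM = mapSummary(sp$map)[mapSummary(sp$map)$chrom == "Total",
      "geneticCM"],
    nBins = nrow(mapTable(sp$map)), n = length(lines))
}

#' Bin-genotype accuracy and crossover recovery under noise
#'
#' Two chromosomes of 2,000 SNPs each at the study's GBS marker density
#' (~33 SNPs/Mb, ~1.07 cM/Mb), 200 lines, 1% genotype error and 5%
#' missingness. Bin genotypes are compared with the ground
#' truth at the bin midpoints; every true breakpoint is checked for a
#' detected breakpoint interval (same line and chromosome) containing its
#' position.
#'
#' @param seed integer seed.
#' @param nLines lines (default 200).
#' @param nSnpsPerChrom SNPs per chromosome (default 2000).
#' @return list with `accuracy` (fraction of line-bin genotypes matching
#'   truth), `recovery` (fraction of true breakpoints covered by a
#'   detected interval), `nTrueBreakpoints`, `nBins`.
#' @export
binAccuracyExperiment <- function(seed = 1L, nLines = 200L,
                                  nSnpsPerChrom = 2000L) {
  template <- buildGenomeTemplate(2, c(6e7, 6e7), c(64, 64),
    nSnpsPerChrom, seed = deriveSeed(seed, 1))
  pop <- simulateRILPopulation(template, nLines, 6L,
    seed = deriveSeed(seed, 2))
  observed <- corruptGenotypes(pop$calls, 0.01, 0.05,
    seed = deriveSeed(seed, 3))
  lens <- setNames(template@chromosomes$bpLength, template@chromosomes$name)
  bc <- callBinMap(observed, lens)
  bm <- bc$binMap
  gr <- binRanges(bm)
  geno <- genotypeCalls(bm)
  ## accuracy against truth at bin midpoints
  match <- total <- 0
  for (cc in template@chromosomes$name) {
    sel <- as.character(seqnames(gr)) == cc
    mid <- (start(gr)[sel] + end(gr)[sel]) / 2
    tg <- truthGenotypeAt(pop$truth, cc, mid)
    match <- match + sum(geno[, sel] == tg)
    total <- total + length(tg)
  }
  ## breakpoint recovery
  tb <- trueBreakpoints(pop$truth)
  det <- bc$smoothed$breakpoints
  hit <- 0L
  for (k in seq_len(nrow(tb))) {
    d <- det[det$line == tb$line[k] & det$chrom == tb$chrom[k], ]
    if (any(d$bpLow <= tb$posBp[k] & d$bpHigh >= tb$posBp[k])) hit <- hit + 1L
  }
  list(accuracy = match / total, recovery = hit / nrow(tb),
    nTrueBreakpoints = nrow(tb), nBins = ncol(geno))
}

#' Error-free map-length recovery at GBS density
#'
#' Two maize chromosomes (9 and 10) carrying their published GBS SNP
#' counts (~33 SNPs/Mb), error-free calls; the estimated Kosambi map is
#' compared with the simulated genetic lengths.
#'
#' @param seed integer seed.
#' @param nLines lines (default 150).
#' @return list with `estimatedCM`, `trueCM`, `ratio`.
#' @export
mapRecoveryExperiment <- function(seed = 1L, nLines = 150L) {
  chromIdx <- c(9, 10)
  nSnps <- MAIZE_SNP_COUNTS[chromIdx]
  template <- buildGenomeTemplate(2, MAIZE_BP_LENGTHS[chromIdx],
    MAIZE_CM_LENGTHS[chromIdx], nSnps, seed = deriveSeed(seed, 1),
    chromNames = paste0("chr", chromIdx))
  pop <- simulateRILPopulation(template, nLines, 6L,
    seed = deriveSeed(seed, 2))
  lens <- setNames(template@chromosomes$bpLength, template@chromosomes$name)
  bc <- callBinMap(pop$calls, lens)
  gm <- buildGeneticMap(bc$binMap)
  est <- mapSummary(gm)[mapSummary(gm)$chrom == "Total", "geneticCM"]
  true <- sum(MAIZE_CM_LENGTHS[chromIdx])
  list(estimatedCM = est, trueCM = true, ratio = est / true)
}

#' Type-I error, power and interval coverage of the QTL scan
#'
#' A reduced genome (maize chromosomes 8-10, ~496 cM) with 275 lines under
#' the study noise conditions, replicated over `nPop` independent
#' population simulations so the measurement is not conditional on one
#' map's local marker layout. Per population the permutation threshold is
#' computed once (1-df scan, no cofactors, marker grid); fresh null
#' phenotypes measure the genome-wide type-I rate against it, and
#' phenotypes with one additive QTL (position drawn anew on chromosome 9
#' per population) explaining `pve` of the variance measure detection
#' power (peak above threshold within 20 Mb of the truth) and 1.5-LOD
#' support-interval coverage among detections.
#'
#' @param seed integer seed.
#' @param nNull,nPower total replicate counts, split evenly over the
#'   populations (defaults 400 / 200).
#' @param nPerm permutations for each population's threshold
#'   (default 1000).
#' @param pve planted single-QTL heritability (default 0.10).
#' @param nPop independent population simulations (default 10).
#' @return list with `threshold` (mean over populations), `typeI`,
#'   `power`, `coverage`, `meanPeakOffsetMb`.
#' @export
scanCalibrationExperiment <- function(seed = 1L, nNull = 400L,
                                      nPower = 200L, nPerm = 1000L,
                                      pve = 0.10, nPop = 10L) {
  ## type-I is a property of the permutation quantile, not of a map
  ## realization: all null replicates run against the first population's
  ## threshold. Power and interval coverage depend on the local marker
  ## layout around the QTL and are averaged over the populations.
  nPowerK <- ceiling(nPower / nPop)
  thrs <- numeric(nPop)
  nullTot <- 0L; exceed <- 0L
  detected <- covered <- powerTot <- 0L
  offsets <- numeric(0)
  for (k in seq_len(nPop)) {
    sk <- deriveSeed(seed, 1000 + k)
    sp <- studyPopulation(sk, chromIdx = 8:10)
    probs <- genotypeProbs(sp$map, gridStep = 1e6)
    lines <- lineIds(sp$binCall$binMap)
    n <- length(lines)
    yRef <- setNames(withSeed(deriveSeed(sk, 4), rnorm(n)), lines)
    thrs[k] <- as.numeric(permutationThreshold(probs, yRef, sp$map,
      nPerm = nPerm, alpha = 0.05, seed = deriveSeed(sk, 5)))

    ## type-I: fresh null phenotypes (first population only)
    if (k == 1L) {
      Y0 <- withSeed(deriveSeed(sk, 6), matrix(rnorm(n * nNull), n,
        dimnames = list(lines, NULL)))
      prof0 <- cimScan(probs, Y0, sp$map)
      exceed <- exceed + sum(apply(prof0$lod, 2, max) > thrs[k])
      nullTot <- nullTot + nNull
    }

    ## power: one additive QTL, position drawn per population
    qtlChrom <- "chr9"
    chromLen <- sp$template@chromosomes$bpLength[
      sp$template@chromosomes$name == qtlChrom]
    qtlPos <- withSeed(deriveSeed(sk, 8),
      round(runif(1, 0.2, 0.8) * chromLen))
    x <- codeToNumeric(truthGenotypeAt(sp$truth, qtlChrom, qtlPos)[lines, 1])
    x[is.na(x)] <- 0
    a <- sqrt(pve / (1 - pve)) / stats::sd(x)
    Y1 <- withSeed(deriveSeed(sk, 7), a * x +
      matrix(rnorm(n * nPowerK), n, dimnames = list(lines, NULL)))
    prof1 <- cimScan(probs, Y1, sp$map)
    pos <- prof1$positions
    powerTot <- powerTot + nPowerK
    for (j in seq_len(nPowerK)) {
      i <- which.max(prof1$lod[, j])
      if (prof1$lod[i, j] <= thrs[k]) next
      if (!(pos$chrom[i] == qtlChrom &&
        abs(pos$posMb[i] - qtlPos / 1e6) <= 20)) next
      detected <- detected + 1L
      offsets <- c(offsets, abs(pos$posMb[i] - qtlPos / 1e6))
      profJ <- structure(list(positions = pos,
        lod = prof1$lod[, j, drop = FALSE], n = n, cofactors = integer(0)),
        class = "LODProfile")
      ci <- supportInterval(profJ, i, drop = 1.5)
      if (ci$mbLow <= qtlPos / 1e6 && ci$mbHigh >= qtlPos / 1e6)
        covered <- covered + 1L
    }
  }
  list(threshold = mean(thrs), typeI = exceed / nullTot,
    power = detected / powerTot,
    coverage = if (detected) covered / detected else NA_real_,
    meanPeakOffsetMb = mean(offsets))
}

#' Heritability recovery for an architecture tuned to H2 = 0.81
#'
#' Phenotypes are simulated repeatedly from [paperTraitArchitecture()]
#' (balanced 2-year x 2-location x 3-replicate design) on one simulated
#' RIL population; each replicate is refit by REML and the entry-mean
#' heritability recomputed.
#'
#' @param seed integer seed.
#' @param nRep phenotype replicates (default 50).
#' @param nLines lines (default 275).
#' @return list with `meanH2`, `sdH2`, `expectedH2`, `h2` (vector).
#' @export
heritabilityRecoveryExperiment <- function(seed = 1L, nRep = 50L,
                                           nLines = 275L) {
  template <- maizeGenomeTemplate(10L, seed = deriveSeed(seed, 1))
  pop <- simulateRILPopulation(template, nLines, 6L,
    seed = deriveSeed(seed, 2))
  arch <- paperTraitArchitecture(0.81, 6L)
  h2 <- vapply(seq_len(nRep), function(k) {
    ph <- simulatePhenotypes(pop$truth, arch, seed = deriveSeed(seed, 10 + k))
    suppressMessages(fitMixedModel(ph, fitBlues = FALSE, polish = FALSE))$H2
  }, numeric(1))
  list(meanH2 = mean(h2), sdH2 = sd(h2),
    expectedH2 = expectedArchitectureH2(arch), h2 = h2)
}
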