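## Peak calling, support intervals, effects and PVE on a LOD profile.

#' 1.5-LOD support interval around a peak
#'
#' The widest contiguous run of evaluation points around the peak with
#' `LOD >= peak - drop`, expanded outward to the first flanking
#' evaluation points below the cutoff (the usual support-interval
#' convention for LOD profiles evaluated on a grid); clipped, with a
#' flag, at chromosome ends.
#'
#' @param profile a `LODProfile` from [cimScan()] (single-phenotype).
#' @param peakIdx row index of the peak in `profile$positions`.
#' @param drop LOD drop defining the interval (default 1.5).
#' @return list with `cmLow`, `cmHigh`, `mbLow`, `mbHigh`, `lowIdx`,
#'   `highIdx`, `clipped`.
#' @export
supportInterval <- function(profile, peakIdx, drop = 1.5) {
  pos <- profile$positions
  lod <- profile$lod[, 1]
  cc <- pos$chrom[peakIdx]
  onChrom <- which(pos$chrom == cc)
  i <- match(peakIdx, onChrom)
  l <- lod[onChrom]
  stopIfNot(l[i] >= drop || l[i] == max(l), "peak LOD below the requested drop")
  cutoff <- l[i] - drop
  lo <- i
  while (lo > 1 && l[lo - 1] >= cutoff) lo <- lo - 1
  hi <- i
  while (hi < length(l) && l[hi + 1] >= cutoff) hi <- hi + 1
  ## bounds at a chromosome end mean the drop was never reached there
  clipped <- lo == 1L || hi == length(l)
  lo <- max(lo - 1L, 1L)
  hi <- min(hi + 1L, length(l))
  ## physical bounds span the full flanking bin markers (a bin is an
  ## interval, not a point)
  mbL <- if ("mbLow" %in% names(pos)) pos$mbLow else pos$posMb
  mbH <- if ("mbHigh" %in% names(pos)) pos$mbHigh else pos$posMb
  list(cmLow = pos$posCM[onChrom[lo]], cmHigh = pos$posCM[onChrom[hi]],
    mbLow = mbL[onChrom[lo]], mbHigh = mbH[onChrom[hi]],
    lowIdx = onChrom[lo], highIdx = onChrom[hi], clipped = clipped)
}

#' Additive effect and single-QTL PVE at a peak
#'
#' `ADD = (mean of A-class lines - mean of B-class lines) / 2` using the
#' expected genotype probabilities as weights; positive values mean the
#' parent-1 (female) allele increases the trait. The single-scan PVE is
#' `100 * (1 - 10^(-2 LOD / n))`.
#'
#' @param pA,pB numeric vectors of genotype probabilities at the peak.
#' @param phenotype numeric vector aligned to the probabilities.
#' @param lod peak LOD (for the PVE formula); optional.
#' @return list with `add`, `meanA`, `meanB`, `pve` (NA when `lod`
#'   missing).
#' @export
estimateEffects <- function(pA, pB, phenotype, lod = NA_real_) {
  wA <- sum(pA); wB <- sum(pB)
  if (wA <= 0 || wB <= 0) {
    warning("a genotype class is empty; additive effect undefined")
    return(list(add = NA_real_, meanA = NA_real_, meanB = NA_real_,
      pve = NA_real_))
  }
  meanA <- sum(pA * phenotype) / wA
  meanB <- sum(pB * phenotype) / wB
  n <- length(phenotype)
  pve <- if (is.na(lod)) NA_real_ else 100 * (1 - 10^(-2 * lod / n))
  list(add = (meanA - meanB) / 2, meanA = meanA, meanB = meanB, pve = pve)
}

#' Joint multi-QTL fit and drop-one PVE
#'
#' Additive linear model of the phenotype on the expected genotype scores
#' of all peaks jointly; the PVE of each QTL is the drop-one difference in
#' R-squared times 100. Peaks closer than `minSeparation` cM on one
#' chromosome are merged (highest-LOD member kept) before fitting.
#'
#' @param peaks data.frame with columns `chrom`, `posCM`, `lod` and one
#'   row per peak.
#' @param scores matrix lines x peaks of expected genotype scores at the
#'   peaks.
#' @param phenotype numeric vector aligned to `scores` rows.
#' @param minSeparation merge distance in cM (default 1).
#' @return list with `pve` (per retained peak), `r2` (joint model),
#'   `kept` (row indices of retained peaks).
#' @export
fitMultiQTL <- function(peaks, scores, phenotype, minSeparation = 1) {
  if (nrow(peaks) == 0)
    return(list(pve = numeric(0), r2 = 0, kept = integer(0)))
  ord <- order(peaks$chrom, peaks$posCM)
  kept <- integer(0)
  for (i in ord) {
    close <- kept[peaks$chrom[kept] == peaks$chrom[i] &
      abs(peaks$posCM[kept] - peaks$posCM[i]) < minSeparation]
    if (length(close)) {
      if (peaks$lod[i] > max(peaks$lod[close])) kept <- c(setdiff(kept, close), i)
    } else kept <- c(kept, i)
  }
  kept <- sort(kept)
  if (length(kept) < nrow(peaks))
    message(nrow(peaks) - length(kept), " peak(s) merged before the joint fit")
  X <- scores[, kept, drop = FALSE]
  y <- phenotype
  tss <- sum((y - mean(y))^2)
  r2of <- function(Xm) {
    if (ncol(Xm) == 0) return(0)
    fit <- lm.fit(cbind(1, Xm), y)
    1 - sum(fit$residuals^2) / tss
  }
  r2 <- r2of(X)
  pve <- vapply(seq_along(kept), function(j)
    100 * (r2 - r2of(X[, -j, drop = FALSE])), numeric(1))
  list(pve = pve, r2 = r2, kept = kept)
}

## Iteratively pick peaks above the threshold, masking each peak's support
## interval (extended to the surrounding below-cutoff flanks) plus the
## cofactor exclusion window around the peak — the CIM profile has sharp
## steps where cofactors enter/leave the model, which would otherwise
## split one locus into several "peaks" — before searching again.
findPeaks <- function(profile, threshold, drop = 1.5, exclusionWindow = 10,
                      maxPerChrom = 10L) {
  pos <- profile$positions
  lod <- profile$lod[, 1]
  peaks <- integer(0)
  for (cc in unique(pos$chrom)) {
    onChrom <- which(pos$chrom == cc)
    l <- lod[onChrom]
    cm <- pos$posCM[onChrom]
    masked <- rep(FALSE, length(l))
    for (k in seq_len(maxPerChrom)) {
      l2 <- ifelse(masked, -Inf, l)
      i <- which.max(l2)
      if (!is.finite(l2[i]) || l2[i] <= threshold) break
      peaks <- c(peaks, onChrom[i])
      cutoff <- l[i] - drop
      lo <- i; while (lo > 1 && l[lo - 1] >= cutoff) lo <- lo - 1
      hi <- i; while (hi < length(l) && l[hi + 1] >= cutoff) hi <- hi + 1
      masked[max(lo - 1, 1):min(hi + 1, length(l))] <- TRUE
      masked[abs(cm - cm[i]) <= exclusionWindow] <- TRUE
    }
  }
  sort(peaks)
}

#' Full QTL scan for one phenotype
#'
#' Cofactor selection, CIM scan, permutation threshold, peak calling,
#' 1.5-LOD support intervals, additive effects and joint-model PVE.
#'
#' @inheritParams cimScan
#' @param phenotype named numeric vector (BLUEs or single-environment line
#'   means).
#' @param env environment tag stored with each QTL record.
#' @param nCofactors,pEnter cofactor-selection controls.
#' @param nPerm,alpha permutation-threshold controls; set `nPerm = 0` to
#'   use `fixedThreshold` instead.
#' @param fixedThreshold LOD threshold used when `nPerm = 0` (default 3).
#' @param drop LOD drop for support intervals (default 1.5).
#' @param seed integer seed for the permutations.
#' @param gridStep pseudomarker spacing in cM.
#' @param probs optional precomputed `GenoProbs` (skips recomputation).
#' @return list with `qtl` (data.frame: `name`, `chrom`, `env`, `peakCM`,
#'   `peakMb`, `lod`, `markerLow`, `markerHigh`, `mbLow`, `mbHigh`, `pve`,
#'   `add`), `profile`, `threshold`, `cofactors`.
#' @export
scanQTL <- function(map, binMap = NULL, phenotype, env = "BLUE",
                    nCofactors = 5L, pEnter = 0.05, exclusionWindow = 10,
                    nPerm = 1000L, alpha = 0.05, fixedThreshold = 3,
                    drop = 1.5, seed = 1L, gridStep = 1, probs = NULL) {
  if (is.null(binMap)) binMap <- attr(map, "binMap")
  if (is.null(probs)) probs <- genotypeProbs(map, binMap, gridStep)
  lines <- rownames(probs[[1]]$pA)
  y <- phenotype[lines]
  cof <- selectCofactors(binMap, y, nCofactors, pEnter)
  profile <- cimScan(probs, y, map, binMap, cof, exclusionWindow)
  threshold <- if (nPerm > 0)
    permutationThreshold(probs, y, map, binMap, cof, exclusionWindow,
      nPerm = nPerm, alpha = alpha, seed = seed)
  else fixedThreshold
  peakIdx <- findPeaks(profile, as.numeric(threshold), drop, exclusionWindow)

  emptyQtl <- data.frame(name = character(0), chrom = character(0),
    env = character(0), peakCM = numeric(0), peakMb = numeric(0),
    lod = numeric(0), markerLow = character(0), markerHigh = character(0),
    mbLow = numeric(0), mbHigh = numeric(0), pve = numeric(0),
    add = numeric(0), stringsAsFactors = FALSE)
  if (!length(peakIdx))
    return(list(qtl = emptyQtl, profile = profile,
      threshold = as.numeric(threshold), cofactors = cof))

  pos <- profile$positions
  ## per-chromosome offsets to index back into the GenoProbs matrices
  chromOffsets <- c(0, cumsum(vapply(probs, function(p) nrow(p$positions), 1)))
  names(chromOffsets) <- c(names(probs), "end")
  scores <- vapply(peakIdx, function(i) {
    cc <- pos$chrom[i]
    probs[[cc]]$score[lines, i - chromOffsets[[cc]]]
  }, numeric(length(lines)))
  peaks <- data.frame(chrom = pos$chrom[peakIdx], posCM = pos$posCM[peakIdx],
    lod = profile$lod[peakIdx, 1], stringsAsFactors = FALSE)
  mq <- suppressMessages(fitMultiQTL(peaks, scores, y))
  peakIdx <- peakIdx[mq$kept]
  scores <- scores[, mq$kept, drop = FALSE]

  rows <- lapply(seq_along(peakIdx), function(k) {
    i <- peakIdx[k]
    cc <- pos$chrom[i]
    ci <- supportInterval(profile, i, drop)
    j <- i - chromOffsets[[cc]]
    eff <- estimateEffects(probs[[cc]]$pA[lines, j], probs[[cc]]$pB[lines, j],
      y, lod = profile$lod[i, 1])
    idxMk <- which(pos$chrom == cc & !is.na(pos$binId))
    lowCand <- idxMk[pos$posCM[idxMk] <= ci$cmLow + 1e-9]
    highCand <- idxMk[pos$posCM[idxMk] >= ci$cmHigh - 1e-9]
    mkLow <- pos$binId[if (length(lowCand)) max(lowCand) else idxMk[1]]
    mkHigh <- pos$binId[if (length(highCand)) min(highCand) else
      idxMk[length(idxMk)]]
    data.frame(name = NA_character_, chrom = cc, env = env,
      peakCM = pos$posCM[i], peakMb = pos$posMb[i], lod = profile$lod[i, 1],
      markerLow = mkLow, markerHigh = mkHigh,
      mbLow = ci$mbLow, mbHigh = ci$mbHigh,
      pve = mq$pve[k], add = eff$add, stringsAsFactors = FALSE)
  })
  qtl <- do.call(rbind, rows)
  list(qtl = qtl, profile = profile, threshold = as.numeric(threshold),
    cofactors = cof)
}
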