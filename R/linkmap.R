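#' Kosambi map function and its inverse
#'
#' `kosambi()` converts a meiotic recombination fraction to centimorgans,
#' `d = 25 * ln((1 + 2r) / (1 - 2r))`; `kosambiInverse()` converts back,
#' `tanh(d / 50) / 2`.
#'
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @param d map distance(s) in cM, `>= 0`.
#' @return numeric vector of distances (cM) or fractions.
#' @examples
#' kosambi(0.1)          # 10.137 cM
#' kosambiInverse(27.465) # ~0.25
#' @export
kosambi <- function(r) {
  stopIfNot(all(r >= 0 & r < 0.5), "kosambi is defined for r in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi
#' @export
kosambiInverse <- function(d) {
  stopIfNot(all(d >= 0), "map distances must be >= 0")
  tanh(d / 50) / 2
}

#' Selfed-RIL correction between meiotic and observed recombination
#'
#' In a population derived by repeated selfing, recombination accumulates
#' over meioses: two fixed lines differ at linked loci with probability
#' `R = 2r / (1 + 2r)` where `r` is the per-meiosis recombination
#' fraction. `rilObservedToMeiotic()` inverts this, `R / (2 (1 - R))`.
#'
#' @param r meiotic recombination fraction(s).
#' @param R observed RIL recombination frequency(ies).
#' @return transformed fraction(s).
#' @export
rilMeioticToObserved <- function(r) 2 * r / (1 + 2 * r)

#' @rdname rilMeioticToObserved
#' @export
rilObservedToMeiotic <- function(R) R / (2 * (1 - R))

#' Recombination fraction between two bins
#'
#' Observed RIL recombination `R` = discordant homozygous pairs /
#' homozygous pairs (heterozygous and missing calls excluded), converted
#' to the meiotic `r` with the selfed-RIL correction and capped at 0.4999.
#'
#' @param genoA,genoB character vectors of bin genotypes across lines.
#' @return list with `r`, `R`, `nPairs`, `nDiscordant`; `r` is `NA` when no
#'   informative pair exists.
#' @export
estimateRF <- function(genoA, genoB) {
  hom <- genoA %in% c("A", "B") & genoB %in% c("A", "B")
  n <- sum(hom)
  if (n == 0) return(list(r = NA_real_, R = NA_real_, nPairs = 0L,
    nDiscordant = 0L))
  disc <- sum(genoA[hom] != genoB[hom])
  R <- disc / n
  r <- min(rilObservedToMeiotic(min(R, 1 - 1e-12)), 0.4999)
  list(r = r, R = R, nPairs = n, nDiscordant = disc)
}

## ---- finite-generation selfing correction ---------------------------------
## Expected discordance between two linked loci in lines selfed from the F1
## for `generations` generations, measured as E[|x1 - x2|] / 2 with
## genotype scores x in {+1 (A), 0 (H), -1 (B)} (so an A-H pair counts one
## half). Computed exactly from the two-locus diploid selfing Markov chain
## (10 unordered gamete-pair states). At generations = Inf this reduces to
## the classical Haldane-Waddington fixation value 2r / (1 + 2r).
twoLocusSelfingR <- function(r, generations) {
  if (!is.finite(generations)) return(rilMeioticToObserved(r))
  gam <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  states <- which(upper.tri(diag(4), diag = TRUE), arr.ind = TRUE)
  ns <- nrow(states)
  gameteDist <- function(i, j) {
    p <- numeric(4)
    pick <- function(a, b) which(gam[, 1] == a & gam[, 2] == b)
    g1 <- gam[i, ]; g2 <- gam[j, ]
    p[pick(g1[1], g1[2])] <- p[pick(g1[1], g1[2])] + (1 - r) / 2
    p[pick(g2[1], g2[2])] <- p[pick(g2[1], g2[2])] + (1 - r) / 2
    p[pick(g1[1], g2[2])] <- p[pick(g1[1], g2[2])] + r / 2
    p[pick(g2[1], g1[2])] <- p[pick(g2[1], g1[2])] + r / 2
    p
  }
  Tm <- matrix(0, ns, ns)
  for (s in seq_len(ns)) {
    p <- gameteDist(states[s, 1], states[s, 2])
    M <- outer(p, p)
    for (s2 in seq_len(ns)) {
      i <- states[s2, 1]; j <- states[s2, 2]
      Tm[s, s2] <- if (i == j) M[i, i] else M[i, j] + M[j, i]
    }
  }
  v <- numeric(ns)
  v[which(states[, 1] == 1 & states[, 2] == 4)] <- 1  # F1 = AB/ab
  for (k in seq_len(generations)) v <- as.numeric(v %*% Tm)
  w <- apply(states, 1, function(ij) {
    x1 <- 1 - (gam[ij[1], 1] + gam[ij[2], 1])
    x2 <- 1 - (gam[ij[1], 2] + gam[ij[2], 2])
    abs(x1 - x2) / 2
  })
  sum(v * w)
}

## Cached monotone R_t(r) curves for fast numeric inversion.
.rilCurveCache <- new.env(parent = emptyenv())

rilFiniteCurve <- function(generations) {
  key <- as.character(generations)
  if (!is.null(.rilCurveCache[[key]])) return(.rilCurveCache[[key]])
  rGrid <- seq(0, 0.4999, length.out = 513)
  RGrid <- vapply(rGrid, twoLocusSelfingR, numeric(1),
    generations = generations)
  curve <- list(r = rGrid, R = RGrid)
  .rilCurveCache[[key]] <- curve
  curve
}

#' Generation-aware inverse of the selfed-RIL correction
#'
#' Converts an observed between-line recombination frequency to the
#' meiotic fraction for lines selfed a finite number of generations, by
#' numerically inverting the exact two-locus selfing-chain expectation.
#' `generations = Inf` gives the classical `R / (2 (1 - R))`.
#'
#' @param R observed recombination frequency(ies).
#' @param generations number of selfing generations from the F1.
#' @return meiotic recombination fraction(s), capped at 0.4999.
#' @export
rilFiniteInverse <- function(R, generations = Inf) {
  if (!is.finite(generations))
    return(pmin(rilObservedToMeiotic(pmin(R, 1 - 1e-12)), 0.4999))
  cv <- rilFiniteCurve(generations)
  pmin(pmax(approx(cv$R, cv$r, xout = pmin(R, max(cv$R)), rule = 2,
    ties = "ordered")$y, 0), 0.4999)
}

## Vectorized adjacent-pair recombination over a numeric score matrix
## (+1/0/-1/NA): discordance weight |x1 - x2| / 2, so a homozygote-
## heterozygote pair counts one half.
adjacentRil <- function(M) {
  m <- ncol(M)
  if (m < 2) return(data.frame(R = numeric(0), nPairs = integer(0)))
  M1 <- M[, -m, drop = FALSE]
  M2 <- M[, -1, drop = FALSE]
  both <- !is.na(M1) & !is.na(M2)
  nPairs <- colSums(both)
  nHom <- colSums(both & M1 != 0 & M2 != 0)
  disc <- colSums(abs(M1 - M2) / 2, na.rm = TRUE)
  data.frame(R = ifelse(nPairs > 0, disc / nPairs, NA_real_),
    nPairs = nPairs, nHom = nHom)
}

#' Build the Kosambi genetic map from a bin map
#'
#' Marker order is fixed by physical position. The adjacent-bin
#' recombination frequency is the mean pairwise discordance with
#' heterozygote pairs counted one half (`|x1 - x2| / 2` on the +1/0/-1
#' score scale); it is converted to the meiotic fraction with the
#' generation-aware selfing correction ([rilFiniteInverse()];
#' `generations = Inf` gives the classical `R = 2r / (1 + 2r)` fixation
#' correction) and to centimorgans with the Kosambi function. Adjacent
#' bins with no homozygous informative pair are merged into their left
#' neighbour (union physical interval; missing calls filled from the
#' right) before distances are computed.
#'
#' @param binMap a [BinMap-class].
#' @param generations number of selfing generations of the population
#'   (default 6, matching [simulateRILPopulation()]); `Inf` for fully
#'   inbred lines.
#' @return a [GeneticMap-class]; the possibly merged [BinMap-class] is
#'   attached as attribute `binMap`, and the number of merged bins as
#'   attribute `nMerged`.
#' @export
buildGeneticMap <- function(binMap, generations = 6L) {
  gr <- binMap@bins
  geno <- binMap@genotypes
  chroms <- unique(as.character(seqnames(gr)))
  nMerged <- 0L
  keepCols <- list(); rows <- list()
  newStarts <- start(gr); newEnds <- end(gr)

  for (cc in chroms) {
    idx <- which(as.character(seqnames(gr)) == cc)
    ## merge uninformative adjacencies (rare; loop until clean)
    repeat {
      M <- codeToNumeric(geno[, idx, drop = FALSE])
      adj <- adjacentRil(M)
      bad <- which(adj$nHom == 0)
      if (!length(bad)) break
      j <- bad[1L]
      a <- idx[j]; b <- idx[j + 1L]
      fill <- geno[, a] == "N"
      geno[fill, a] <- geno[fill, b]
      newEnds[a] <- newEnds[b]
      idx <- idx[-(j + 1L)]
      nMerged <- nMerged + 1L
    }
    keepCols[[cc]] <- idx
    if (length(idx) < 2) {
      message("chromosome ", cc, " has fewer than 2 bins; zero-length map")
      rows[[cc]] <- data.frame(chrom = cc, col = idx, rAdj = NA_real_,
        dcM = 0, stringsAsFactors = FALSE)[seq_along(idx), ]
      next
    }
    r <- rilFiniteInverse(adj$R, generations)
    d <- kosambi(r)
    rows[[cc]] <- data.frame(chrom = cc, col = idx,
      rAdj = c(NA, r), dcM = c(0, d), stringsAsFactors = FALSE)
  }

  tb <- do.call(rbind, rows)
  rownames(tb) <- NULL
  tb$binId <- mcols(gr)$binId[tb$col]
  tb$bpStart <- newStarts[tb$col]
  tb$bpEnd <- newEnds[tb$col]
  cum <- unlist(lapply(split(tb$dcM, tb$chrom)[unique(tb$chrom)], cumsum),
    use.names = FALSE)
  tb$cumCM <- cum
  tb <- tb[, c("chrom", "binId", "bpStart", "bpEnd", "rAdj", "dcM", "cumCM")]

  perChrom <- do.call(rbind, lapply(unique(tb$chrom), function(cc) {
    s <- tb[tb$chrom == cc, ]
    data.frame(chrom = cc, nMarkers = nrow(s),
      physicalMb = max(s$bpEnd) / 1e6,
      geneticCM = max(s$cumCM),
      avgDistCM = if (nrow(s) > 1) max(s$cumCM) / (nrow(s) - 1) else 0,
      maxGapCM = if (nrow(s) > 1) max(s$dcM[-1]) else 0)
  }))
  total <- data.frame(chrom = "Total", nMarkers = sum(perChrom$nMarkers),
    physicalMb = sum(perChrom$physicalMb),
    geneticCM = sum(perChrom$geneticCM),
    avgDistCM = sum(perChrom$geneticCM) /
      max(sum(perChrom$nMarkers) - length(chroms), 1),
    maxGapCM = max(perChrom$maxGapCM))
  summ <- rbind(perChrom, total)

  cols <- sort(unlist(keepCols, use.names = FALSE))
  mergedGr <- GRanges(as.character(seqnames(gr))[cols],
    IRanges(start = newStarts[cols], end = newEnds[cols]),
    binId = mcols(gr)$binId[cols])
  mergedBinMap <- new("BinMap", bins = mergedGr,
    genotypes = geno[, cols, drop = FALSE], grid = binMap@grid)

  gm <- new("GeneticMap", table = tb, summary = summ)
  attr(gm, "binMap") <- mergedBinMap
  attr(gm, "nMerged") <- nMerged
  gm
}
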