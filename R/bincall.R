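## Sliding-window genotype smoothing, breakpoint detection and
## population-wide 100-kb bin construction.

#' Sliding-window genotype calls for one line on one chromosome
#'
#' Missing calls are skipped so every window holds `window` non-missing
#' codes. A window is called `A` if at least `majority` of its codes are
#' `A`, `B` if at least `majority` are `B`, otherwise `H` (heterozygous
#' codes count toward neither parent).
#'
#' @param codes character vector of SNP codes (`A`/`B`/`H`/`N`) in physical
#'   order.
#' @param window window size in SNPs (default 15).
#' @param step step in (non-missing) SNPs between window starts (default 1).
#' @param majority count required to call a parental homozygote
#'   (default 11); must satisfy `window >= majority > window/2`.
#' @return list with `windows` (data.frame `firstSnp`, `lastSnp` — indices
#'   into `codes` — and `call`) and `nonMissing` (indices of non-missing
#'   codes). Zero windows if fewer than `window` non-missing codes.
#' @export
callWindows <- function(codes, window = 15L, step = 1L, majority = 11L) {
  stopIfNot(window >= majority && majority >= floor(window / 2) + 1L,
    "need window >= majority > window/2 so only one parent can reach majority")
  nm <- which(codes != "N")
  k <- length(nm)
  if (k < window) {
    return(list(windows = data.frame(firstSnp = integer(0),
      lastSnp = integer(0), call = character(0)), nonMissing = nm))
  }
  v <- codes[nm]
  cntA <- cumsum(v == "A")
  cntB <- cumsum(v == "B")
  starts <- seq.int(1L, k - window + 1L, by = step)
  ends <- starts + window - 1L
  nA <- cntA[ends] - c(0, cntA)[starts]
  nB <- cntB[ends] - c(0, cntB)[starts]
  call <- ifelse(nA >= majority, "A", ifelse(nB >= majority, "B", "H"))
  list(windows = data.frame(firstSnp = nm[starts], lastSnp = nm[ends],
    call = call, stringsAsFactors = FALSE), nonMissing = nm)
}

## SNP codes that count as evidence for the left/right genotype of an
## L -> R transition. For a heterozygous side, evidence is any code showing
## the allele absent from the opposite (homozygous) side.
transitionEvidence <- function(left, right) {
  ev <- function(side, other) {
    if (side == "A") "A"
    else if (side == "B") "B"
    else if (other == "A") c("B", "H")
    else c("A", "H")
  }
  list(left = ev(left, right), right = ev(right, left))
}

#' Merge adjacent equal windows into blocks and locate breakpoints
#'
#' Maximal runs of equal window calls collapse to blocks; between
#' consecutive blocks a recombination-breakpoint interval is recorded,
#' spanning from the last SNP supporting the left block's genotype to the
#' first SNP supporting the right block's genotype within the transition
#' region (the union of the two windows flanking the call change).
#'
#' @param track result of [callWindows()].
#' @param codes,positions the SNP codes and bp positions given to
#'   [callWindows()].
#' @return list with `blocks` (data.frame `call`, `firstSnp`, `lastSnp`)
#'   and `breakpoints` (data.frame `bpLow`, `bpHigh`, `leftCall`,
#'   `rightCall`, `mid`).
#' @export
mergeBlocks <- function(track, codes, positions) {
  w <- track$windows
  emptyBp <- data.frame(bpLow = numeric(0), bpHigh = numeric(0),
    leftCall = character(0), rightCall = character(0), mid = numeric(0))
  if (nrow(w) == 0)
    return(list(blocks = data.frame(call = character(0),
      firstSnp = integer(0), lastSnp = integer(0)), breakpoints = emptyBp))
  r <- rle(w$call)
  nb <- length(r$values)
  lastWin <- cumsum(r$lengths)
  firstWin <- c(1L, head(lastWin, -1L) + 1L)
  blocks <- data.frame(call = r$values,
    firstSnp = w$firstSnp[firstWin], lastSnp = w$lastSnp[lastWin],
    stringsAsFactors = FALSE)
  if (nb == 1L) return(list(blocks = blocks, breakpoints = emptyBp))

  bp <- vector("list", nb - 1L)
  for (j in seq_len(nb - 1L)) {
    wL <- lastWin[j]; wR <- firstWin[j + 1L]
    lo <- w$firstSnp[wL]; hi <- w$lastSnp[wR]
    region <- lo:hi
    region <- region[codes[region] != "N"]
    L <- r$values[j]; R <- r$values[j + 1L]
    ev <- transitionEvidence(L, R)
    ## evidence must be corroborated: an isolated miscall mimicking the
    ## other genotype must not truncate the interval, so the boundary SNP
    ## is the first (last) whose neighbour in the evidence subsequence
    ## agrees with it
    evSeq <- region[codes[region] %in% c(ev$left, ev$right)]
    isR <- codes[evSeq] %in% ev$right
    high <- region[length(region)]
    if (any(isR)) {
      k <- length(isR)
      okR <- isR & c(isR[-1], TRUE)         # next evidence agrees (or last)
      if (any(okR)) high <- evSeq[which(okR)[1L]]
    }
    isL <- codes[evSeq] %in% ev$left & evSeq < high
    low <- region[1L]
    if (any(isL)) {
      okL <- isL & c(TRUE, isL[-length(isL)])  # previous evidence agrees
      if (any(okL)) low <- evSeq[max(which(okL))]
    }
    if (positions[low] >= positions[high]) {
      low <- region[1L]; high <- region[length(region)]
    }
    bp[[j]] <- data.frame(bpLow = positions[low], bpHigh = positions[high],
      leftCall = L, rightCall = R, stringsAsFactors = FALSE)
  }
  bp <- do.call(rbind, bp)

  ## Phantom-H suppression: a window track sliding across a clean A->B
  ## crossover necessarily passes through the no-majority zone and emits a
  ## short H run whose physical cover is empty (its flanking breakpoint
  ## intervals overlap). Such runs are artifacts of the window rule, not
  ## heterozygous segments: collapse them, either merging the flanking
  ## blocks (same call, e.g. an error cluster) or fusing the two
  ## breakpoints into one. Genuine H segments have positive cover and are
  ## kept.
  repeat {
    nb <- nrow(blocks)
    if (nb < 3) break
    phantom <- which(blocks$call[-c(1, nb)] == "H" &
      bp$bpHigh[-nrow(bp)] >= bp$bpLow[-1]) + 1L
    if (!length(phantom)) break
    j <- phantom[1L]
    left <- j - 1L; right <- j + 1L
    if (blocks$call[left] == blocks$call[right]) {
      blocks$lastSnp[left] <- blocks$lastSnp[right]
      blocks <- blocks[-c(j, right), , drop = FALSE]
      bp <- bp[-c(j - 1L, j), , drop = FALSE]
    } else {
      newLow <- min(bp$bpLow[j - 1L], bp$bpLow[j])
      newHigh <- max(bp$bpHigh[j - 1L], bp$bpHigh[j])
      bp$bpLow[j - 1L] <- newLow
      bp$bpHigh[j - 1L] <- newHigh
      bp$leftCall[j - 1L] <- blocks$call[left]
      bp$rightCall[j - 1L] <- blocks$call[right]
      bp <- bp[-j, , drop = FALSE]
      blocks <- blocks[-j, , drop = FALSE]
    }
    rownames(blocks) <- rownames(bp) <- NULL
  }

  bp$mid <- (bp$bpLow + bp$bpHigh) / 2
  list(blocks = blocks, breakpoints = bp)
}

#' Window-smooth a population and collect blocks and breakpoints
#'
#' Applies [callWindows()] and [mergeBlocks()] to every line and
#' chromosome.
#'
#' @param scm a [SNPCallMatrix-class].
#' @inheritParams callWindows
#' @return list of class `WindowBlocks`: `blocks[[chrom]][[line]]`,
#'   `lineBreakpoints[[chrom]][[line]]`, pooled `breakpoints` data.frame
#'   (`line`, `chrom`, `bpLow`, `bpHigh`, `leftCall`, `rightCall`, `mid`),
#'   and the window parameters.
#' @export
smoothPopulation <- function(scm, window = 15L, step = 1L, majority = 11L) {
  mk <- scm@markers
  chroms <- unique(mk$chrom)
  lines <- rownames(scm@calls)
  blocks <- lineBp <- setNames(vector("list", length(chroms)), chroms)
  pooled <- list()
  for (cc in chroms) {
    sel <- which(mk$chrom == cc)
    pos <- mk$pos[sel]
    blocks[[cc]] <- lineBp[[cc]] <- setNames(vector("list", length(lines)), lines)
    for (ln in lines) {
      codes <- scm@calls[ln, sel]
      tr <- callWindows(codes, window, step, majority)
      mb <- mergeBlocks(tr, codes, pos)
      blocks[[cc]][[ln]] <- mb$blocks
      lineBp[[cc]][[ln]] <- mb$breakpoints
      if (nrow(mb$breakpoints))
        pooled[[length(pooled) + 1L]] <-
          cbind(line = ln, chrom = cc, mb$breakpoints)
    }
  }
  pooled <- if (length(pooled)) do.call(rbind, pooled) else
    data.frame(line = character(0), chrom = character(0), bpLow = numeric(0),
      bpHigh = numeric(0), leftCall = character(0), rightCall = character(0),
      mid = numeric(0))
  structure(list(blocks = blocks, lineBreakpoints = lineBp,
    breakpoints = pooled, window = window, step = step, majority = majority),
    class = "WindowBlocks")
}

#' Population-wide bin boundaries on the 100-kb grid
#'
#' The chromosome is partitioned into grid intervals; every grid interval
#' containing at least one breakpoint midpoint (in any line) starts a new
#' bin. A bin is the maximal run of grid intervals from one boundary to the
#' next; the terminal bin ends at the chromosome end.
#'
#' @param breakpoints pooled breakpoint data.frame (needs `chrom`, `mid`),
#'   e.g. from [smoothPopulation()].
#' @param chromLengths named numeric vector of chromosome lengths (bp).
#' @param grid grid size in bp (default 1e5).
#' @return `GRanges` of bins (1-based closed intervals on the 0-based
#'   half-open grid) with mcols `binId`.
#' @export
detectPopulationBins <- function(breakpoints, chromLengths, grid = 1e5) {
  out <- list()
  for (cc in names(chromLengths)) {
    len <- chromLengths[[cc]]
    mids <- breakpoints$mid[breakpoints$chrom == cc]
    cells <- sort(unique(floor(mids / grid))) * grid
    starts0 <- sort(unique(c(0, cells[cells > 0 & cells < len])))
    ends0 <- c(starts0[-1], len)
    out[[cc]] <- GRanges(cc, IRanges(start = starts0 + 1, end = ends0))
  }
  gr <- suppressWarnings(do.call(c, unname(out)))
  mcols(gr)$binId <- sprintf("mk%d", seq_along(gr))
  gr
}

#' Genotype the population at the bins
#'
#' Each bin is assigned, per line, the call of the block covering it. If a
#' line's own breakpoint interval overlaps the bin, the genotype is the
#' majority of that line's raw SNP calls inside the bin; on ties or with no
#' SNPs, the call shared by the blocks flanking the bin is used if they
#' agree, otherwise `N`. Lines with too few non-missing SNPs for a single
#' window fall back to the raw-majority rule everywhere.
#'
#' @param smoothed a `WindowBlocks` from [smoothPopulation()].
#' @param scm the [SNPCallMatrix-class] that was smoothed.
#' @param bins bin `GRanges` from [detectPopulationBins()].
#' @param grid grid size used to build the bins.
#' @return a [BinMap-class].
#' @export
genotypeBins <- function(smoothed, scm, bins, grid = 1e5) {
  mk <- scm@markers
  lines <- rownames(scm@calls)
  geno <- matrix("N", length(lines), length(bins),
    dimnames = list(lines, mcols(bins)$binId))
  binChrom <- as.character(seqnames(bins))
  for (cc in unique(binChrom)) {
    bIdx <- which(binChrom == cc)
    bStart <- start(bins)[bIdx]
    bEnd <- end(bins)[bIdx]
    sel <- which(mk$chrom == cc)
    pos <- mk$pos[sel]
    snpBin <- findInterval(pos, bStart)
    for (ln in lines) {
      codes <- scm@calls[ln, sel]
      blocks <- smoothed$blocks[[cc]][[ln]]
      bp <- smoothed$lineBreakpoints[[cc]][[ln]]
      if (nrow(blocks) == 0) {
        ## no complete window: direct majority everywhere
        maj <- binMajority(codes, snpBin, length(bIdx))
        maj[is.na(maj)] <- "N"
        geno[ln, bIdx] <- maj
        next
      }
      ## block cover intervals: block k runs from the previous breakpoint's
      ## bpHigh (or chromosome start) to its own bpLow (or chromosome end);
      ## consecutive breakpoint intervals may overlap, so enforce monotone
      ## cover starts
      coverStart <- cummax(c(1, bp$bpHigh))
      calls <- blocks$call
      assigned <- calls[pmax(findInterval(bStart, coverStart), 1L)]
      if (nrow(bp)) {
        marked <- logical(length(bIdx))
        for (j in seq_len(nrow(bp))) {
          i1 <- findInterval(bp$bpLow[j], bEnd) + 1L          # first bin with end > bpLow
          i2 <- findInterval(bp$bpHigh[j] - 1, bStart)        # last bin with start < bpHigh
          if (i1 <= i2) marked[i1:i2] <- TRUE
        }
        if (any(marked)) {
          maj <- binMajority(codes, snpBin, length(bIdx), which(marked))
          fl <- which(marked & is.na(match(maj, c("A", "B", "H"))))
          ## flanking-agreement fill where the majority is undecided
          if (length(fl)) {
            leftCall <- calls[pmax(findInterval(bStart[fl], coverStart), 1L)]
            rightCall <- calls[pmax(findInterval(bEnd[fl], coverStart), 1L)]
            maj[fl] <- ifelse(leftCall == rightCall, leftCall, "N")
          }
          assigned[marked] <- maj[marked]
        }
      }
      geno[ln, bIdx] <- assigned
    }
  }
  new("BinMap", bins = bins, genotypes = geno, grid = grid)
}

## Majority vote of raw SNP calls per bin; ties and empty bins give NA
## (restricted to `subset` bin indices when given).
binMajority <- function(codes, snpBin, nBins, subset = seq_len(nBins)) {
  out <- rep(NA_character_, nBins)
  use <- which(snpBin %in% subset & codes != "N" & snpBin >= 1)
  if (!length(use)) return(out)
  f <- factor(snpBin[use], levels = subset)
  cnt <- vapply(c("A", "B", "H"), function(code)
    as.vector(table(f[codes[use] == code])), numeric(length(subset)))
  if (length(subset) == 1L) cnt <- matrix(cnt, nrow = 1)
  top <- max.col(cnt, ties.method = "first")
  best <- cnt[cbind(seq_along(subset), top)]
  tied <- rowSums(cnt == best) > 1L | best == 0
  out[subset] <- ifelse(tied, NA_character_, c("A", "B", "H")[top])
  out
}

#' Build the bin map in one call
#'
#' Runs [smoothPopulation()], [detectPopulationBins()] and
#' [genotypeBins()].
#'
#' @inheritParams smoothPopulation
#' @inheritParams detectPopulationBins
#' @return list with `binMap` ([BinMap-class]), `smoothed`
#'   (`WindowBlocks`) and `summary` (from [breakpointSummary()]).
#' @export
callBinMap <- function(scm, chromLengths, window = 15L, step = 1L,
                       majority = 11L, grid = 1e5) {
  smoothed <- smoothPopulation(scm, window, step, majority)
  bins <- detectPopulationBins(smoothed$breakpoints, chromLengths, grid)
  binMap <- genotypeBins(smoothed, scm, bins, grid)
  list(binMap = binMap, smoothed = smoothed,
    summary = breakpointSummary(smoothed$breakpoints, rownames(scm@calls)))
}

#' Breakpoint summary statistics
#'
#' @param breakpoints pooled breakpoint data.frame (needs `line`).
#' @param lines character vector of all line ids (so lines with zero
#'   breakpoints are counted).
#' @return list with `perLine` (named counts), `total` and `meanPerLine`.
#' @export
breakpointSummary <- function(breakpoints, lines) {
  perLine <- table(factor(breakpoints$line, levels = lines))
  list(perLine = perLine, total = sum(perLine),
    meanPerLine = as.numeric(mean(perLine)))
}
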