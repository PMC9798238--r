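## Meiosis-level simulation of a selfed RIL population.
##
## A haplotype is a parental-origin mosaic on the cM scale:
##   list(br = interior breakpoint positions (cM, strictly increasing),
##        or = integer origins per segment (0 = parent 1, 1 = parent 2),
##        length(or) == length(br) + 1)
## Crossovers per meiosis are Poisson with mean = genetic length in Morgans,
## placed uniformly on the cM scale (no interference); lines descend from
## the F1 by single-seed descent.

originAt <- function(hap, posCm) {
  hap$or[findInterval(posCm, hap$br) + 1L]
}

collapseMosaic <- function(br, or) {
  if (length(or) > 1L) {
    keep <- which(diff(or) != 0L)
    br <- br[keep]
    or <- or[c(1L, keep + 1L)]
  }
  list(br = br, or = or)
}

## One gamete from a diploid (hap1, hap2) on a chromosome of length cmLen.
meiosisGamete <- function(hap1, hap2, cmLen) {
  nxo <- if (cmLen > 0) rpois(1L, cmLen / 100) else 0L
  src <- if (runif(1L) < 0.5) 1L else 2L
  if (nxo == 0L) return(if (src == 1L) hap1 else hap2)
  cuts <- sort(runif(nxo, 0, cmLen))
  bounds <- c(0, cuts, cmLen)
  outBr <- numeric(0)
  outOr <- integer(0)
  for (k in seq_len(length(bounds) - 1L)) {
    a <- bounds[k]; b <- bounds[k + 1L]
    h <- if (src == 1L) hap1 else hap2
    idx <- which(h$br > a & h$br < b)
    pieceOr <- c(h$or[findInterval(a, h$br) + 1L], h$or[idx + 1L])
    if (k == 1L) {
      outBr <- h$br[idx]; outOr <- pieceOr
    } else {
      outBr <- c(outBr, a, h$br[idx])
      outOr <- c(outOr, pieceOr)
    }
    src <- 3L - src
  }
  collapseMosaic(outBr, outOr)
}

## Diploid genotype mosaic (A/H/B segments on the cM scale) from two
## haplotypes; returns list(br, label) with adjacent labels distinct.
diploidMosaic <- function(hap1, hap2, cmLen) {
  br <- sort(unique(c(hap1$br, hap2$br)))
  mids <- if (length(br)) (c(0, br) + c(br, cmLen)) / 2 else cmLen / 2
  g <- originAt(hap1, mids) + originAt(hap2, mids)
  lab <- c("A", "H", "B")[g + 1L]
  if (length(lab) > 1L) {
    keep <- which(lab[-1] != lab[-length(lab)])
    br <- br[keep]
    lab <- lab[c(1L, keep + 1L)]
  }
  list(br = br, label = lab)
}

#' Simulate a selfed RIL population with breakpoint truth
#'
#' Starting from the F1 of two fully inbred parents, each line is propagated
#' by single-seed descent for `selfingGenerations` generations. Each meiosis
#' draws a Poisson number of crossovers (mean = chromosome genetic length in
#' Morgans) placed uniformly on the cM scale, without interference. SNP
#' calls are read off the final diploid genotype: `A` = parent-1 homozygote,
#' `B` = parent-2 homozygote, `H` = heterozygote.
#'
#' @param template a [GenomeTemplate-class].
#' @param nLines number of RILs.
#' @param selfingGenerations number of selfing generations (>= 1; default 6,
#'   leaving ~1.6% residual heterozygosity).
#' @param seed integer seed; the whole population is reproducible from it.
#' @param forceHomozygous if TRUE, each residual heterozygous segment is
#'   resolved to a random parental homozygote (no `H` in the output).
#' @return list with elements `truth` ([TrueGenomeSet-class]) and
#'   `calls` ([SNPCallMatrix-class]).
#' @examples
#' gt <- buildGenomeTemplate(1, 1e7, 100, 60, seed = 1)
#' pop <- simulateRILPopulation(gt, nLines = 20, seed = 2)
#' pop$calls
#' @export
simulateRILPopulation <- function(template, nLines, selfingGenerations = 6L,
                                  seed = 1L, forceHomozygous = FALSE) {
  stopIfNot(selfingGenerations >= 1L, "selfingGenerations must be >= 1")
  stopIfNot(nLines >= 1L, "nLines must be >= 1")
  ch <- template@chromosomes
  nCh <- nrow(ch)
  lineNames <- sprintf("RIL%03d", seq_len(nLines))

  segments <- vector("list", nLines)
  names(segments) <- lineNames
  callCols <- vector("list", nCh)
  names(callCols) <- ch$name
  for (cc in ch$name)
    callCols[[cc]] <- matrix("N", nLines, length(template@snpPositions[[cc]]))

  withSeed(seed, {
    for (li in seq_len(nLines)) {
      lineSegs <- vector("list", nCh)
      names(lineSegs) <- ch$name
      for (ci in seq_len(nCh)) {
        cmLen <- ch$cmLength[ci]
        ## F1 diploid: one chromosome from each parent
        h1 <- list(br = numeric(0), or = 0L)
        h2 <- list(br = numeric(0), or = 1L)
        for (g in seq_len(selfingGenerations)) {
          n1 <- meiosisGamete(h1, h2, cmLen)
          n2 <- meiosisGamete(h1, h2, cmLen)
          h1 <- n1; h2 <- n2
        }
        mos <- diploidMosaic(h1, h2, cmLen)
        if (forceHomozygous && any(mos$label == "H")) {
          mos$label[mos$label == "H"] <-
            sample(c("A", "B"), sum(mos$label == "H"), replace = TRUE)
          if (length(mos$label) > 1L) {
            keep <- which(mos$label[-1] != mos$label[-length(mos$label)])
            mos$br <- mos$br[keep]
            mos$label <- mos$label[c(1L, keep + 1L)]
          }
        }
        ## segment boundaries to physical coordinates
        anchors <- template@mapAnchors[[ci]]
        cutBp <- if (length(mos$br)) floor(bpAtCm(anchors, mos$br)) else numeric(0)
        ## guard against duplicate cuts after rounding
        if (length(cutBp)) {
          ok <- !duplicated(cutBp) & cutBp >= 1 & cutBp < ch$bpLength[ci]
          if (!all(ok)) {
            cutBp <- cutBp[ok]
            lab <- mos$label[c(TRUE, ok)]
            keep <- if (length(lab) > 1L) which(lab[-1] != lab[-length(lab)]) else integer(0)
            cutBp <- cutBp[keep]
            lab <- lab[c(1L, keep + 1L)]
            mos$label <- lab
          }
        }
        seg <- data.frame(
          startBp = c(1, cutBp + 1),
          endBp = c(cutBp, ch$bpLength[ci]),
          label = mos$label, stringsAsFactors = FALSE)
        lineSegs[[ci]] <- seg
        ## SNP calls read off the bp segment table (single source of truth,
        ## so calls and truth segments are mutually consistent by construction)
        callCols[[ci]][li, ] <-
          seg$label[findInterval(template@snpPositions[[ci]], seg$startBp)]
      }
      segments[[li]] <- lineSegs
    }
  })

  calls <- do.call(cbind, callCols)
  rownames(calls) <- lineNames
  markers <- data.frame(
    chrom = rep(ch$name, lengths(template@snpPositions)),
    pos = unlist(template@snpPositions, use.names = FALSE),
    stringsAsFactors = FALSE)
  colnames(calls) <- sprintf("%s_%d", markers$chrom, markers$pos)

  chromLengths <- setNames(ch$bpLength, ch$name)
  list(
    truth = new("TrueGenomeSet", segments = segments, chromLengths = chromLengths),
    calls = new("SNPCallMatrix", calls = calls, markers = markers))
}

#' Corrupt genotype calls with symmetric errors and missingness
#'
#' Each non-missing call is independently flipped to one of the other two
#' genotype codes with probability `errorRate` (uniform over the two), then
#' set to `N` with probability `missingRate`. The input object is not
#' modified.
#'
#' @param scm a [SNPCallMatrix-class].
#' @param errorRate flip probability in `[0, 1]`.
#' @param missingRate missing probability in `[0, 1]`.
#' @param seed integer seed.
#' @return a new [SNPCallMatrix-class].
#' @export
corruptGenotypes <- function(scm, errorRate = 0.01, missingRate = 0.05,
                             seed = 1L) {
  stopIfNot(errorRate >= 0 && errorRate <= 1, "errorRate must be in [0, 1]")
  stopIfNot(missingRate >= 0 && missingRate <= 1, "missingRate must be in [0, 1]")
  calls <- scm@calls
  withSeed(seed, {
    obs <- which(calls != "N")
    if (errorRate > 0 && length(obs)) {
      flip <- obs[runif(length(obs)) < errorRate]
      if (length(flip)) {
        cur <- calls[flip]
        pick <- runif(length(flip)) < 0.5
        others <- rbind(
          A = c("B", "H"), B = c("A", "H"), H = c("A", "B"))
        calls[flip] <- ifelse(pick, others[cur, 1], others[cur, 2])
      }
    }
    if (missingRate > 0 && length(obs)) {
      drop <- obs[runif(length(obs)) < missingRate]
      calls[drop] <- "N"
    }
  })
  new("SNPCallMatrix", calls = calls, markers = scm@markers)
}

#' Ground-truth genotype labels at arbitrary positions
#'
#' @param truth a [TrueGenomeSet-class].
#' @param chrom chromosome name.
#' @param pos numeric vector of 1-based bp positions.
#' @return character matrix lines x positions of labels in `{A, B, H}`.
#' @export
truthGenotypeAt <- function(truth, chrom, pos) {
  lines <- names(truth@segments)
  out <- matrix(NA_character_, length(lines), length(pos),
    dimnames = list(lines, NULL))
  for (ln in lines) {
    seg <- truth@segments[[ln]][[chrom]]
    idx <- findInterval(pos, seg$startBp)
    out[ln, ] <- seg$label[idx]
  }
  out
}

#' Per-line true breakpoint table
#'
#' @param truth a [TrueGenomeSet-class].
#' @return data.frame with columns `line`, `chrom`, `posBp` (last bp of the
#'   left segment), `fromLabel`, `toLabel`.
#' @export
trueBreakpoints <- function(truth) {
  rows <- list()
  for (ln in names(truth@segments)) {
    for (cc in names(truth@segments[[ln]])) {
      seg <- truth@segments[[ln]][[cc]]
      if (nrow(seg) < 2) next
      rows[[length(rows) + 1L]] <- data.frame(
        line = ln, chrom = cc,
        posBp = seg$endBp[-nrow(seg)],
        fromLabel = seg$label[-nrow(seg)],
        toLabel = seg$label[-1], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(line = character(), chrom = character(),
      posBp = numeric(), fromLabel = character(), toLabel = character()))
  do.call(rbind, rows)
}
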