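#' Merge per-environment QTL lists into consensus loci
#'
#' Single-linkage clustering per chromosome under the predicate
#' "confidence intervals overlap OR peak spacing <= `maxPeakGapMb`";
#' chained relations merge (A~B and B~C puts A, B, C in one consensus).
#' Consensus loci are named `q<prefix><chrom>` with an ordinal suffix by
#' ascending peak position when a chromosome hosts more than one
#' (`qPC2-1`, `qPC2-2`, ...). A consensus is flagged stable when detected
#' in at least two environments.
#'
#' @param qtlLists a data.frame of QTL records (as from [scanQTL()]:
#'   columns `chrom`, `env`, `peakMb`, `mbLow`, `mbHigh`, plus any
#'   others), or a list of such data.frames which are row-bound.
#' @param maxPeakGapMb peak-spacing threshold in Mb (default 20).
#' @param prefix trait name prefix (default `"PC"`).
#' @return data.frame of member records with added columns `name`
#'   (consensus name), `consensusLowMb`, `consensusHighMb` (union
#'   interval), `nEnv` (distinct environments in the consensus) and
#'   `stable`.
#' @export
mergeAcrossEnvs <- function(qtlLists, maxPeakGapMb = 20, prefix = "PC") {
  q <- if (is.data.frame(qtlLists)) qtlLists else
    do.call(rbind, c(qtlLists, make.row.names = FALSE))
  if (is.null(q) || nrow(q) == 0)
    return(cbind(emptyConsensus(), data.frame()))
  stopIfNot(all(c("chrom", "env", "peakMb", "mbLow", "mbHigh") %in% names(q)),
    "QTL records need chrom, env, peakMb, mbLow, mbHigh")
  q$cluster <- NA_integer_
  nextCl <- 0L
  for (cc in unique(q$chrom)) {
    idx <- which(q$chrom == cc)
    ## union-find by repeated label propagation (few records per chromosome)
    cl <- seq_along(idx)
    repeat {
      changed <- FALSE
      for (a in seq_along(idx)) for (b in seq_along(idx)) {
        if (cl[a] == cl[b]) next
        ia <- idx[a]; ib <- idx[b]
        overlap <- q$mbLow[ia] <= q$mbHigh[ib] & q$mbLow[ib] <= q$mbHigh[ia]
        near <- abs(q$peakMb[ia] - q$peakMb[ib]) <= maxPeakGapMb
        if (overlap || near) {
          cl[cl == max(cl[a], cl[b])] <- min(cl[a], cl[b])
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    q$cluster[idx] <- nextCl + match(cl, sort(unique(cl)))
    nextCl <- nextCl + length(unique(cl))
  }
  ## name clusters: ordinal by ascending mean peak position per chromosome
  q$name <- NA_character_
  for (cc in unique(q$chrom)) {
    cls <- unique(q$cluster[q$chrom == cc])
    peakOf <- vapply(cls, function(k) mean(q$peakMb[q$cluster == k]), 1)
    cls <- cls[order(peakOf)]
    chromNum <- sub("^chr", "", cc)
    for (k in seq_along(cls)) {
      nm <- if (length(cls) == 1) sprintf("q%s%s", prefix, chromNum) else
        sprintf("q%s%s-%d", prefix, chromNum, k)
      q$name[q$cluster == cls[k]] <- nm
    }
  }
  q$consensusLowMb <- NA_real_
  q$consensusHighMb <- NA_real_
  q$nEnv <- NA_integer_
  for (k in unique(q$cluster)) {
    m <- q$cluster == k
    q$consensusLowMb[m] <- min(q$mbLow[m])
    q$consensusHighMb[m] <- max(q$mbHigh[m])
    q$nEnv[m] <- length(unique(q$env[m]))
  }
  q$stable <- q$nEnv >= 2
  q$cluster <- NULL
  q[order(naturalChromOrder(q$chrom), q$peakMb), , drop = FALSE]
}

emptyConsensus <- function() {
  data.frame(chrom = character(0), env = character(0), peakMb = numeric(0),
    mbLow = numeric(0), mbHigh = numeric(0), name = character(0),
    consensusLowMb = numeric(0), consensusHighMb = numeric(0),
    nEnv = integer(0), stable = logical(0), stringsAsFactors = FALSE)
}

naturalChromOrder <- function(chrom) {
  num <- suppressWarnings(as.numeric(sub("^chr", "", chrom)))
  ifelse(is.na(num), rank(chrom), num)
}

#' Report table of merged QTLs
#'
#' One row per member record (a QTL detected in one environment) with the
#' consensus name, flanking markers, physical interval, PVE and additive
#' effect, sorted by chromosome then position.
#'
#' @param consensus output of [mergeAcrossEnvs()].
#' @return data.frame with columns `Name`, `Chr`, `Env`, `MarkerInterval`,
#'   `IntervalMb`, `PVE`, `ADD`.
#' @export
reportTable <- function(consensus) {
  if (nrow(consensus) == 0)
    return(data.frame(Name = character(0), Chr = character(0),
      Env = character(0), MarkerInterval = character(0),
      IntervalMb = character(0), PVE = numeric(0), ADD = numeric(0),
      stringsAsFactors = FALSE))
  hasMk <- all(c("markerLow", "markerHigh") %in% names(consensus))
  out <- data.frame(
    Name = consensus$name,
    Chr = sub("^chr", "", consensus$chrom),
    Env = consensus$env,
    MarkerInterval = if (hasMk)
      paste0(consensus$markerLow, "-", consensus$markerHigh) else NA_character_,
    IntervalMb = sprintf("%.2f-%.2f", consensus$mbLow, consensus$mbHigh),
    PVE = if ("pve" %in% names(consensus)) round(consensus$pve, 2) else NA_real_,
    ADD = if ("add" %in% names(consensus)) round(consensus$add, 2) else NA_real_,
    stringsAsFactors = FALSE)
  out[order(naturalChromOrder(consensus$chrom), consensus$peakMb), ,
    drop = FALSE]
}
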