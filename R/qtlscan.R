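## Composite interval mapping on the bin map: conditional genotype
## probabilities, cofactor selection, vectorized Haley-Knott LOD scans,
## permutation thresholds.

## RIL-scale recombination probability across a cM distance: Kosambi
## inversion to the meiotic fraction, then the selfed-RIL correction at
## the population's selfing generation (consistent with the transform the
## map builder inverts; generations = Inf gives the classical fixation
## value).
rilRecombAcross <- function(dcm, generations = Inf) {
  r <- kosambiInverse(pmax(dcm, 0))
  if (!is.finite(generations)) return(rilMeioticToObserved(r))
  cv <- rilFiniteCurve(generations)
  approx(cv$r, cv$R, xout = pmin(r, max(cv$r)), rule = 2)$y
}

#' Conditional genotype probabilities at pseudomarkers
#'
#' At every evaluation position (all bin positions plus a regular cM grid)
#' the probability of the parent-1 (`A`) and parent-2 (`B`) genotype is
#' computed for each line conditional on the nearest informative flanking
#' bin calls, treating the RIL genome as a two-state Markov chain with
#' recombination probabilities derived from Kosambi-inverted interval
#' distances and the selfed-RIL correction. At a genotyped bin the
#' distribution is degenerate on the observed call; observed heterozygotes
#' are degenerate `H` at their own bin and treated as missing when
#' conditioning elsewhere. Lines with no informative call on a chromosome
#' get the uniform prior.
#'
#' @param map a [GeneticMap-class] from [buildGeneticMap()].
#' @param binMap the matching [BinMap-class] (defaults to the merged bin
#'   map attached to `map`).
#' @param gridStep pseudomarker spacing in cM (default 1).
#' @param generations selfing generations of the population (default 6;
#'   `Inf` for fully inbred lines), used for the cM-to-recombination
#'   transform of the conditioning chain.
#' @return list of class `GenoProbs`: per chromosome a list with
#'   `positions` (data.frame `posCM`, `posMb`, `binId`) and matrices
#'   `pA`, `pB`, `pH`, `score` (`pA - pB`) of lines x positions.
#' @export
genotypeProbs <- function(map, binMap = NULL, gridStep = 1,
                          generations = 6L) {
  stopIfNot(gridStep > 0, "gridStep must be positive")
  if (is.null(binMap)) binMap <- attr(map, "binMap")
  stopIfNot(!is.null(binMap), "binMap required (none attached to the map)")
  tb <- map@table
  geno <- binMap@genotypes
  binIds <- mcols(binMap@bins)$binId
  lines <- rownames(geno)
  out <- list()
  for (cc in unique(tb$chrom)) {
    s <- tb[tb$chrom == cc, ]
    col <- match(s$binId, binIds)
    binCM <- s$cumCM
    binMb <- (s$bpStart + s$bpEnd) / 2 / 1e6
    grid <- seq(0, max(binCM), by = gridStep)
    posCM <- sort(unique(round(c(binCM, grid), 9)))
    mIdx <- match(round(binCM, 9), posCM)     # marker slots
    posMb <- approx(binCM, binMb, xout = posCM, rule = 2, ties = "ordered")$y
    binAt <- rep(NA_character_, length(posCM))
    binAt[mIdx] <- s$binId
    ## physical extent of each evaluation position: a bin marker spans its
    ## whole bin; pseudomarkers are points
    mbLow <- mbHigh <- posMb
    mbLow[mIdx] <- s$bpStart / 1e6
    mbHigh[mIdx] <- s$bpEnd / 1e6
    pA <- pB <- pH <- matrix(0, length(lines), length(posCM),
      dimnames = list(lines, NULL))
    for (li in seq_along(lines)) {
      g <- geno[li, col]
      inf <- which(g %in% c("A", "B"))
      if (!length(inf)) {
        pA[li, ] <- 0.5; pB[li, ] <- 0.5
      } else {
        obsCM <- binCM[inf]
        gA <- g[inf] == "A"
        iL <- findInterval(posCM, obsCM)
        iR <- iL + 1L
        hasL <- iL >= 1L
        hasR <- iR <= length(inf)
        p <- rep(0.5, length(posCM))
        ## both flanks
        bb <- hasL & hasR
        if (any(bb)) {
          R1 <- rilRecombAcross(posCM[bb] - obsCM[iL[bb]], generations)
          R2 <- rilRecombAcross(obsCM[iR[bb]] - posCM[bb], generations)
          R12 <- rilRecombAcross(obsCM[iR[bb]] - obsCM[iL[bb]], generations)
          tL <- ifelse(gA[iL[bb]], 1 - R1, R1)
          tR <- ifelse(gA[iR[bb]], 1 - R2, R2)
          den <- ifelse(gA[iL[bb]] == gA[iR[bb]], 1 - R12, R12)
          p[bb] <- tL * tR / pmax(den, 1e-300)
        }
        lo <- hasL & !hasR
        if (any(lo)) {
          R1 <- rilRecombAcross(posCM[lo] - obsCM[iL[lo]], generations)
          p[lo] <- ifelse(gA[iL[lo]], 1 - R1, R1)
        }
        ro <- !hasL & hasR
        if (any(ro)) {
          R2 <- rilRecombAcross(obsCM[iR[ro]] - posCM[ro], generations)
          p[ro] <- ifelse(gA[iR[ro]], 1 - R2, R2)
        }
        pA[li, ] <- pmin(pmax(p, 0), 1)
        pB[li, ] <- 1 - pA[li, ]
      }
      ## degenerate distributions at genotyped bins
      obsIdx <- which(g != "N")
      if (length(obsIdx)) {
        slots <- mIdx[obsIdx]
        gObs <- g[obsIdx]
        pA[li, slots] <- as.numeric(gObs == "A")
        pB[li, slots] <- as.numeric(gObs == "B")
        pH[li, slots] <- as.numeric(gObs == "H")
      }
    }
    out[[cc]] <- list(
      positions = data.frame(posCM = posCM, posMb = posMb, mbLow = mbLow,
        mbHigh = mbHigh, binId = binAt, stringsAsFactors = FALSE),
      pA = pA, pB = pB, pH = pH, score = pA - pB)
  }
  structure(out, class = "GenoProbs")
}

#' Numeric marker scores for regression
#'
#' Additive coding `A = +1`, `H = 0`, `B = -1`; missing calls are imputed
#' with the marker mean.
#'
#' @param binMap a [BinMap-class].
#' @return numeric matrix lines x bins.
#' @export
markerScores <- function(binMap) {
  M <- codeToNumeric(binMap@genotypes)
  mu <- colMeans(M, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(M), arr.ind = TRUE)
  if (nrow(idx)) M[idx] <- mu[idx[, 2]]
  dimnames(M) <- dimnames(binMap@genotypes)
  M
}

#' Forward selection of marker cofactors
#'
#' Greedy forward selection of bin markers by the partial F statistic of
#' single-marker regression conditional on the markers already chosen;
#' stops at `nCofactors` markers or when no addition is nominally
#' significant (p >= `pEnter`).
#'
#' @param binMap a [BinMap-class].
#' @param phenotype numeric vector named by line id (e.g. BLUEs).
#' @param nCofactors maximum number of cofactors (default 5).
#' @param pEnter entry p-value (default 0.05).
#' @return integer vector of selected bin column indices (possibly empty).
#' @export
selectCofactors <- function(binMap, phenotype, nCofactors = 5L,
                            pEnter = 0.05) {
  if (nCofactors < 1L) return(integer(0))
  M <- markerScores(binMap)
  y <- phenotype[rownames(M)]
  stopIfNot(!anyNA(y), "phenotype missing for some lines")
  n <- length(y)
  chosen <- integer(0)
  X <- matrix(1, n, 1)
  repeat {
    qrX <- qr(X)
    ry <- qr.resid(qrX, y)
    RM <- M - qr.fitted(qrX, M)
    ssm <- colSums(RM^2)
    ssy <- sum(ry^2)
    ok <- ssm > 1e-10 * n & !(seq_len(ncol(M)) %in% chosen)
    if (!any(ok) || ssy < 1e-12) break
    rho2 <- rep(-Inf, ncol(M))
    rho2[ok] <- (colSums(RM[, ok, drop = FALSE] * ry)^2) / (ssm[ok] * ssy)
    j <- which.max(rho2)
    dfRes <- n - ncol(X) - 1L
    if (dfRes < 1L) break
    Fj <- dfRes * rho2[j] / (1 - rho2[j])
    p <- pf(Fj, 1, dfRes, lower.tail = FALSE)
    if (!is.finite(Fj) || p >= pEnter) break
    chosen <- c(chosen, j)
    X <- cbind(X, M[, j])
    if (length(chosen) >= nCofactors) break
  }
  chosen
}

## cM position (and chromosome) of every bin column in the map, used for
## the cofactor exclusion window.
binPositionsCM <- function(map) {
  tb <- map@table
  data.frame(binId = tb$binId, chrom = tb$chrom, posCM = tb$cumCM,
    stringsAsFactors = FALSE)
}

#' Composite-interval-mapping LOD scan (vectorized over phenotypes)
#'
#' At every evaluation position the phenotype is regressed on the expected
#' additive genotype score (`P(A) - P(B)`, plus a dominance column `P(H)`
#' where non-constant) together with the retained marker cofactors;
#' cofactors within `exclusionWindow` cM of the test position (same
#' chromosome) are excluded. `LOD = (n/2) log10(RSS0 / RSS1)` where the
#' null model holds the intercept and retained cofactors only.
#'
#' @param probs a `GenoProbs` from [genotypeProbs()].
#' @param phenotype numeric vector named by line, or a matrix with one
#'   column per phenotype (lines x phenotypes) for vectorized scanning.
#' @param map the [GeneticMap-class] (for cofactor positions).
#' @param binMap the matching [BinMap-class]; defaults to the bin map
#'   attached to `map`.
#' @param cofactors integer vector of bin column indices (e.g. from
#'   [selectCofactors()]); empty for simple interval mapping.
#' @param exclusionWindow cM window around the test position within which
#'   cofactors are dropped (default 10).
#' @param dominance add the expected-heterozygote column `P(H)` to the
#'   QTL model (default FALSE: in a selfed RIL population the residual
#'   heterozygotes are so few that the column acts as a sparse indicator
#'   and inflates the genome-wide null LOD).
#' @return list of class `LODProfile`: `positions` (data.frame `chrom`,
#'   `posCM`, `posMb`, `binId`), `lod` (positions x phenotypes matrix),
#'   `n`, `cofactors`.
#' @export
cimScan <- function(probs, phenotype, map, binMap = NULL,
                    cofactors = integer(0), exclusionWindow = 10,
                    dominance = FALSE) {
  if (is.null(binMap)) binMap <- attr(map, "binMap")
  lines <- rownames(probs[[1]]$pA)
  Y <- if (is.matrix(phenotype)) phenotype[lines, , drop = FALSE] else
    matrix(phenotype[lines], ncol = 1, dimnames = list(lines, NULL))
  stopIfNot(!anyNA(Y), "phenotype missing for some lines")
  n <- nrow(Y)
  m <- ncol(Y)
  ## columns with (numerically) zero phenotypic variance get LOD 0
  tss <- colSums(Y^2) - n * colMeans(Y)^2
  varOK <- tss > 1e-10 * pmax(colSums(Y^2), 1)
  binPos <- binPositionsCM(map)
  cof <- if (length(cofactors)) markerScores(binMap)[lines, cofactors, drop = FALSE] else
    matrix(0, n, 0)
  cofChrom <- binPos$chrom[cofactors]
  cofCM <- binPos$posCM[cofactors]

  posList <- list(); lodList <- list()
  for (cc in names(probs)) {
    pr <- probs[[cc]]
    np <- nrow(pr$positions)
    lod <- matrix(0, np, m)
    ## retained-cofactor signature per position
    keepMat <- if (length(cofactors)) {
      sameChrom <- cofChrom == cc
      vapply(seq_len(np), function(i)
        !(sameChrom & abs(cofCM - pr$positions$posCM[i]) <= exclusionWindow),
        logical(length(cofactors)))
    } else matrix(logical(0), 0, np)
    sig <- if (length(cofactors)) apply(keepMat, 2, paste, collapse = "") else
      rep("", np)
    for (sg in unique(sig)) {
      at <- which(sig == sg)
      keep <- if (length(cofactors)) keepMat[, at[1]] else logical(0)
      X0 <- cbind(1, cof[, keep, drop = FALSE])
      qr0 <- qr(X0)
      Q0 <- qr.Q(qr0)
      qty <- crossprod(Q0, Y)
      rss0 <- colSums(Y^2) - colSums(qty^2)
      for (i in at) {
        x <- pr$score[, i]
        X1 <- if (dominance) cbind(x, pr$pH[, i]) else cbind(x)
        Z <- X1 - Q0 %*% crossprod(Q0, X1)
        zss <- colSums(Z^2)
        use <- zss > 1e-10
        if (!any(use)) next
        Z <- Z[, use, drop = FALSE]
        G <- crossprod(Z)
        ## drop a collinear dominance column
        if (ncol(Z) == 2 && abs(det(G)) < 1e-10 * G[1, 1] * G[2, 2]) {
          Z <- Z[, 1, drop = FALSE]; G <- crossprod(Z)
        }
        E <- crossprod(Z, Y)
        expl <- colSums(E * solve(G, E))
        rss1 <- pmax(rss0 - expl, 1e-12 * rss0, 1e-300)
        li <- pmax(n / 2 * log10(pmax(rss0, 1e-300) / rss1), 0)
        li[!varOK] <- 0
        lod[i, ] <- li
      }
    }
    posList[[cc]] <- cbind(chrom = cc, pr$positions)
    lodList[[cc]] <- lod
  }
  positions <- do.call(rbind, c(posList, make.row.names = FALSE))
  structure(list(positions = positions, lod = do.call(rbind, lodList),
    n = n, cofactors = cofactors), class = "LODProfile")
}

#' Genome-wide permutation LOD threshold
#'
#' Phenotype values are permuted across lines; each permutation is scanned
#' and its genome-wide maximum LOD recorded; the threshold is the
#' empirical `1 - alpha` quantile (type-7 interpolation). By default the
#' cofactors selected on the observed phenotype are held fixed across
#' permutations; `policy = "reselect"` re-runs cofactor selection per
#' permutation (slower).
#'
#' @inheritParams cimScan
#' @param nPerm number of permutations (>= 100; default 1000).
#' @param alpha genome-wide significance level (default 0.05).
#' @param seed integer seed; permutation `i` uses a substream derived from
#'   it, so results are independent of execution order.
#' @param policy `"fixed"` or `"reselect"`.
#' @param nCofactors,pEnter passed to [selectCofactors()] under
#'   `"reselect"`.
#' @return numeric threshold; the max-LOD sample is attached as attribute
#'   `maxLod`.
#' @export
permutationThreshold <- function(probs, phenotype, map, binMap = NULL,
                                 cofactors = integer(0),
                                 exclusionWindow = 10, nPerm = 1000L,
                                 alpha = 0.05, seed = 1L,
                                 policy = c("fixed", "reselect"),
                                 nCofactors = 5L, pEnter = 0.05) {
  policy <- match.arg(policy)
  stopIfNot(nPerm >= 100, "use at least 100 permutations")
  if (is.null(binMap)) binMap <- attr(map, "binMap")
  lines <- rownames(probs[[1]]$pA)
  y <- phenotype[lines]
  n <- length(y)
  perms <- vapply(seq_len(nPerm), function(i)
    withSeed(deriveSeed(seed, i), sample.int(n)), integer(n))
  if (policy == "fixed") {
    Y <- matrix(y[perms], n, nPerm, dimnames = list(lines, NULL))
    prof <- cimScan(probs, Y, map, binMap, cofactors, exclusionWindow)
    maxLod <- apply(prof$lod, 2, max)
  } else {
    maxLod <- vapply(seq_len(nPerm), function(i) {
      yi <- setNames(y[perms[, i]], lines)
      cf <- selectCofactors(binMap, yi, nCofactors, pEnter)
      max(cimScan(probs, yi, map, binMap, cf, exclusionWindow)$lod)
    }, numeric(1))
  }
  thr <- as.numeric(quantile(maxLod, 1 - alpha, type = 7))
  attr(thr, "maxLod") <- maxLod
  thr
}
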