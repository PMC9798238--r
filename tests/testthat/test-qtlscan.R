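# Shared small mapping population for the scan tests.
scanFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gt <- buildGenomeTemplate(2, c(6e7, 5e7), c(80, 70), 500, seed = 19)
      pop <- simulateRILPopulation(gt, 120, seed = 20)
      res <- callBinMap(pop$calls, setNames(gt@chromosomes$bpLength,
        gt@chromosomes$name))
      map <- buildGeneticMap(res$binMap)
      probs <- genotypeProbs(map, gridStep = 1)
      cache <<- list(gt = gt, pop = pop, map = map,
        binMap = attr(map, "binMap"), probs = probs)
    }
    cache
  }
})

test_that("genotype probabilities are degenerate at observed markers", {
  fx <- scanFixture()
  pr <- fx$probs$chr1
  geno <- genotypeCalls(fx$binMap)
  binIds <- S4Vectors::mcols(binRanges(fx$binMap))$binId
  mk <- which(!is.na(pr$positions$binId))[1:25]
  for (i in mk) {
    col <- match(pr$positions$binId[i], binIds)
    obs <- geno[, col]
    for (code in c("A", "B", "H")) {
      rows <- which(obs == code)
      if (!length(rows)) next
      p <- switch(code, A = pr$pA, B = pr$pB, H = pr$pH)
      expect_true(all(p[rows, i] == 1))
    }
  }
})

test_that("probabilities between close same-genotype flanks stay near 1", {
  ## hand-built two-marker chromosome: both flanks A, r = 0.01
  geno <- matrix("A", 1, 2, dimnames = list("L1", NULL))
  bm <- mkBinMap(geno)
  gm <- buildGeneticMap(bm, generations = Inf)
  gm@table$rAdj <- c(NA, 0.01)
  gm@table$dcM <- c(0, kosambi(0.01))
  gm@table$cumCM <- c(0, kosambi(0.01))
  attr(gm, "binMap") <- bm
  pr <- genotypeProbs(gm, bm, gridStep = 0.25)$chr1
  expect_gte(min(pr$pA[1, ]), 0.98)
})

test_that("probabilities are symmetric between opposite equidistant flanks", {
  geno <- matrix(c("A", "B"), 1, 2, dimnames = list("L1", NULL))
  bm <- mkBinMap(geno)
  gm <- buildGeneticMap(bm, generations = Inf)
  attr(gm, "binMap") <- bm
  pr <- genotypeProbs(gm, bm, gridStep = 0.5)$chr1
  mid <- which(abs(pr$positions$posCM - max(pr$positions$posCM) / 2) < 1e-9)
  expect_equal(pr$pA[1, mid], pr$pB[1, mid], tolerance = 1e-12)
  ## and a line with no informative markers gets the uniform prior
  geno2 <- rbind(geno, L2 = c("N", "N"))
  rownames(geno2) <- c("L1", "L2")
  bm2 <- mkBinMap(geno2)
  gm2 <- buildGeneticMap(bm2, generations = Inf)
  attr(gm2, "binMap") <- bm2
  pr2 <- genotypeProbs(gm2, bm2, gridStep = 0.5)$chr1
  expect_true(all(pr2$pA["L2", ] == 0.5))
})

test_that("with no cofactors the scan equals a Haley-Knott oracle", {
  fx <- scanFixture()
  lines <- rownames(fx$probs$chr1$pA)
  y <- withr::with_seed(5, rnorm(length(lines)))
  names(y) <- lines
  prof <- cimScan(fx$probs, y, fx$map, fx$binMap, cofactors = integer(0))
  profD <- cimScan(fx$probs, y, fx$map, fx$binMap, cofactors = integer(0),
    dominance = TRUE)
  ## independent oracle: per-position lm of y on the genotype columns
  n <- length(y)
  rss0 <- sum((y - mean(y))^2)
  oracleLod <- function(X) {
    X <- X[, apply(X, 2, sd) > 1e-8, drop = FALSE]
    rss1 <- if (ncol(X)) sum(resid(lm(y ~ X))^2) else rss0
    max(n / 2 * log10(rss0 / rss1), 0)
  }
  for (i in seq(1, nrow(prof$positions), by = 17)) {
    cc <- prof$positions$chrom[i]
    off <- i - match(TRUE, prof$positions$chrom == cc) + 1
    expect_equal(prof$lod[i, 1],
      oracleLod(cbind(fx$probs[[cc]]$score[, off])), tolerance = 1e-10)
    expect_equal(profD$lod[i, 1],
      oracleLod(cbind(fx$probs[[cc]]$score[, off], fx$probs[[cc]]$pH[, off])),
      tolerance = 1e-10)
  }
})

test_that("constant phenotype gives LOD zero everywhere", {
  fx <- scanFixture()
  lines <- rownames(fx$probs$chr1$pA)
  y <- setNames(rep(3.7, length(lines)), lines)
  prof <- cimScan(fx$probs, y, fx$map, fx$binMap)
  expect_true(all(prof$lod == 0))
})

test_that("LOD is invariant under affine phenotype transformation", {
  fx <- scanFixture()
  lines <- rownames(fx$probs$chr1$pA)
  y <- withr::with_seed(6, rnorm(length(lines)))
  names(y) <- lines
  cof <- selectCofactors(fx$binMap, y, 3)
  p1 <- cimScan(fx$probs, y, fx$map, fx$binMap, cof)
  p2 <- cimScan(fx$probs, setNames(-2.5 * y + 7, lines), fx$map, fx$binMap,
    cof)
  expect_equal(p1$lod, p2$lod, tolerance = 1e-8)
})

test_that("a noise-free additive QTL peaks exactly at its marker", {
  fx <- scanFixture()
  geno <- genotypeCalls(fx$binMap)
  binIds <- S4Vectors::mcols(binRanges(fx$binMap))$binId
  tb <- mapTable(fx$map)
  target <- tb$binId[tb$chrom == "chr1"][40]
  x <- codeToNumericPkg <- binQTL:::codeToNumeric(geno[, match(target, binIds)])
  x[is.na(x)] <- 0
  y <- setNames(x, rownames(geno))
  prof <- cimScan(fx$probs, y, fx$map, fx$binMap)
  peak <- prof$positions[which.max(prof$lod[, 1]), ]
  expect_equal(peak$binId, target)
})

test_that("cofactor selection finds a planted QTL and respects its bounds", {
  fx <- scanFixture()
  geno <- genotypeCalls(fx$binMap)
  binIds <- S4Vectors::mcols(binRanges(fx$binMap))$binId
  tb <- mapTable(fx$map)
  target <- tb$binId[tb$chrom == "chr2"][25]
  x <- binQTL:::codeToNumeric(geno[, match(target, binIds)])
  x[is.na(x)] <- 0
  hits <- 0
  for (s in 1:20) {
    y <- setNames(0.8 * x + withr::with_seed(700 + s,
      rnorm(nrow(geno))), rownames(geno))
    cof <- selectCofactors(fx$binMap, y, nCofactors = 5)
    expect_lte(length(cof), 5)
    if (length(cof)) {
      selPos <- tb$cumCM[match(binIds[cof[1]], tb$binId)]
      truePos <- tb$cumCM[match(target, tb$binId)]
      sameChrom <- tb$chrom[match(binIds[cof[1]], tb$binId)] == "chr2"
      if (sameChrom && abs(selPos - truePos) <= 10) hits <- hits + 1
    }
  }
  expect_gte(hits, 18)   # first cofactor lands within 10 cM of truth
  ## nCofactors = 0 gives simple interval mapping (empty set)
  y0 <- setNames(rnorm(nrow(geno)), rownames(geno))
  expect_length(selectCofactors(fx$binMap, y0, nCofactors = 0), 0)
})

test_that("permutation threshold behaves at its quantile limits", {
  fx <- scanFixture()
  lines <- rownames(fx$probs$chr1$pA)
  y <- withr::with_seed(9, rnorm(length(lines)))
  names(y) <- lines
  thr <- permutationThreshold(fx$probs, y, fx$map, fx$binMap, nPerm = 120,
    alpha = 0.05, seed = 3)
  maxLod <- attr(thr, "maxLod")
  expect_length(maxLod, 120)
  expect_equal(as.numeric(thr), as.numeric(quantile(maxLod, 0.95, type = 7)))
  thrAll <- permutationThreshold(fx$probs, y, fx$map, fx$binMap, nPerm = 120,
    alpha = 1, seed = 3)
  expect_equal(as.numeric(thrAll), min(maxLod))
  ## constant phenotype: threshold 0
  yc <- setNames(rep(1, length(lines)), lines)
  thr0 <- permutationThreshold(fx$probs, yc, fx$map, fx$binMap, nPerm = 120,
    seed = 3)
  expect_equal(as.numeric(thr0), 0)
  ## reproducible from the seed, independent of execution order
  thr2 <- permutationThreshold(fx$probs, y, fx$map, fx$binMap, nPerm = 120,
    alpha = 0.05, seed = 3)
  expect_identical(attr(thr, "maxLod"), attr(thr2, "maxLod"))
})

test_that("support interval follows the LOD-drop geometry", {
  ## triangular profile: peak LOD 5 at 50 cM, slope 1 LOD/cM, 0.5-cM grid
  cm <- seq(0, 100, by = 0.5)
  lod <- pmax(5 - abs(cm - 50), 0)
  prof <- structure(list(
    positions = data.frame(chrom = "chr1", posCM = cm, posMb = cm,
      binId = NA_character_),
    lod = matrix(lod, ncol = 1), n = 100, cofactors = integer(0)),
    class = "LODProfile")
  peak <- which.max(lod)
  ci <- supportInterval(prof, peak, drop = 1.5)
  ## points within the drop span 48.5-51.5; bounds extend one evaluation
  ## point beyond on each side (the usual grid convention)
  expect_equal(ci$cmLow, 48)
  expect_equal(ci$cmHigh, 52)
  expect_false(ci$clipped)
  ## drop = 0: the peak plateau plus its immediate flanks
  ci0 <- supportInterval(prof, peak, drop = 0)
  expect_equal(ci0$cmLow, 49.5)
  expect_equal(ci0$cmHigh, 50.5)
  ## flat profile to the chromosome end is clipped and flagged
  prof$lod <- matrix(pmax(5 - pmax(cm - 50, 0), 0), ncol = 1)
  ci2 <- supportInterval(prof, which.max(prof$lod[, 1]), drop = 1.5)
  expect_true(ci2$clipped)
  expect_equal(ci2$cmLow, 0)
})

test_that("effects and PVE follow their definitions", {
  ## class means 10 (A) and 9 (B) -> ADD = +0.5
  pA <- rep(c(1, 0), each = 20)
  pB <- 1 - pA
  y <- rep(c(10, 9), each = 20)
  eff <- estimateEffects(pA, pB, y, lod = 0)
  expect_equal(eff$add, 0.5)
  expect_equal(eff$pve, 0)
  ## empty class flagged
  expect_warning(e2 <- estimateEffects(rep(1, 5), rep(0, 5), rnorm(5)),
    "empty")
  expect_true(is.na(e2$add))
  ## perfect signal: PVE -> 100
  x <- rep(c(1, -1), 30)
  n <- length(x)
  rss0 <- sum((x - mean(x))^2)
  lod <- n / 2 * log10(rss0 / 1e-12)
  expect_gt(estimateEffects(as.numeric(x == 1), as.numeric(x == -1), x,
    lod)$pve, 99.9)
})

test_that("joint multi-QTL fit splits PVE between unlinked equal QTLs", {
  set.seed(33)
  x1 <- sample(c(1, -1), 200, replace = TRUE)
  x2 <- sample(c(1, -1), 200, replace = TRUE)
  y <- x1 + x2
  peaks <- data.frame(chrom = c("chr1", "chr2"), posCM = c(10, 10),
    lod = c(5, 5))
  mq <- fitMultiQTL(peaks, cbind(x1, x2), y)
  expect_equal(length(mq$pve), 2)
  expect_equal(mq$pve[1], mq$pve[2], tolerance = 10)
  expect_equal(sum(mq$pve), 100, tolerance = 2)
  ## single QTL: drop-one PVE equals the model R2
  mq1 <- fitMultiQTL(peaks[1, ], cbind(x1), y)
  expect_equal(mq1$pve, 100 * mq1$r2)
  ## collinear peaks are merged
  peaks2 <- data.frame(chrom = "chr1", posCM = c(10, 10.5), lod = c(5, 4))
  mq2 <- suppressMessages(fitMultiQTL(peaks2, cbind(x1, x1), y))
  expect_length(mq2$kept, 1)
  ## zero QTLs: empty report
  mq0 <- fitMultiQTL(peaks[0, ], matrix(0, 200, 0), y)
  expect_length(mq0$pve, 0)
})

test_that("an end-to-end scan localizes a planted QTL", {
  fx <- scanFixture()
  lab <- truthGenotypeAt(fx$pop$truth, "chr1", 30e6)[, 1]
  x <- binQTL:::codeToNumeric(lab)
  y <- 0.6 * x + withr::with_seed(55, rnorm(length(x), sd = 1))
  names(y) <- names(lab)
  sc <- scanQTL(fx$map, fx$binMap, y, env = "test", nPerm = 150, seed = 2)
  expect_gte(nrow(sc$qtl), 1)
  best <- sc$qtl[which.max(sc$qtl$lod), ]
  expect_equal(best$chrom, "chr1")
  expect_lt(abs(best$peakMb - 30), 15)
  expect_true(best$mbLow <= best$peakMb && best$mbHigh >= best$peakMb)
  expect_true(best$pve > 0 && best$pve <= 100)
  expect_gt(best$add, 0)
})
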