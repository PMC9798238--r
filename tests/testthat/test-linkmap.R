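test_that("Kosambi map function matches the closed form", {
  expect_equal(kosambi(0), 0)
  expect_equal(kosambi(0.1), 25 * log(1.2 / 0.8), tolerance = 1e-12)
  expect_equal(kosambi(0.1), 10.13662770, tolerance = 1e-7)
  expect_equal(kosambi(0.25), 25 * log(1.5 / 0.5), tolerance = 1e-12)
  expect_equal(kosambi(0.25), 27.46530722, tolerance = 1e-7)
  expect_error(kosambi(0.5), "0.5")
  expect_error(kosambi(-0.01), "0.5")
  ## inverse round-trips
  r <- c(0, 0.05, 0.2, 0.45)
  expect_equal(kosambiInverse(kosambi(r)), r, tolerance = 1e-12)
})

test_that("Kosambi is the identity near zero (100 cM per unit r)", {
  r <- 10^seq(-6, -3)
  expect_equal(kosambi(r) / r, rep(100, length(r)), tolerance = 1e-5)
})

test_that("selfed-RIL correction and its inverse agree", {
  expect_equal(rilMeioticToObserved(0.25), 1 / 3)
  expect_equal(rilObservedToMeiotic(1 / 3), 0.25)
  r <- seq(0, 0.45, by = 0.05)
  expect_equal(rilObservedToMeiotic(rilMeioticToObserved(r)), r,
    tolerance = 1e-12)
})

test_that("recombination fraction estimation from genotype vectors", {
  a <- rep("A", 10)
  expect_equal(estimateRF(a, a)$r, 0)
  ## 10 informative pairs, 2 discordant: R = 0.2, r = 0.125
  b <- a; b[1:2] <- "B"
  rf <- estimateRF(a, b)
  expect_equal(rf$R, 0.2)
  expect_equal(rf$r, 0.125)
  ## H and N pairs are excluded
  c <- a; c[1] <- "B"; c[2] <- "H"; c[3] <- "N"
  rf2 <- estimateRF(a, c)
  expect_equal(rf2$nPairs, 8)
  expect_equal(rf2$R, 1 / 8)
  ## no informative pairs -> undefined
  expect_true(is.na(estimateRF(rep("H", 5), rep("A", 5))$r))
})

test_that("map construction: single interval, zero map, cumulative positions", {
  set.seed(5)
  base <- sample(c("A", "B"), 200, replace = TRUE)
  swap <- function(g, k) { i <- sample(200, k); g[i] <- ifelse(g[i] == "A", "B", "A"); g }
  g2 <- swap(base, 33)    # R ~ 1/6
  bm <- mkBinMap(cbind(base, g2))
  gm <- buildGeneticMap(bm, generations = Inf)
  tb <- mapTable(gm)
  R <- 33 / 200
  expect_equal(tb$rAdj[2], R / (2 * (1 - R)), tolerance = 1e-12)
  expect_equal(tb$cumCM[2], kosambi(R / (2 * (1 - R))), tolerance = 1e-12)
  ## identical bins: zero-length map
  bm0 <- mkBinMap(cbind(base, base, base))
  expect_equal(mapSummary(buildGeneticMap(bm0, generations = Inf))[1, "geneticCM"], 0)
})

test_that("uninformative adjacencies are merged, not assigned a distance", {
  g <- cbind(rep(c("A", "B"), each = 10),
    rep("H", 20),                       # no homozygous pair with neighbours
    rep(c("A", "B"), each = 10))
  bm <- mkBinMap(g)
  gm <- buildGeneticMap(bm)
  expect_equal(attr(gm, "nMerged"), 1)
  expect_equal(nrow(mapTable(gm)), 2)
  merged <- attr(gm, "binMap")
  ## the merged bin spans the union interval
  expect_equal(GenomicRanges::end(binRanges(merged))[1], 2e5)
})

test_that("map length is invariant under chromosome reversal", {
  gt <- tinyTemplate(bp = 2e7, cm = 90, nSnps = 400)
  pop <- simulateRILPopulation(gt, 80, seed = 23)
  res <- callBinMap(pop$calls, c(chr1 = 2e7))
  gm <- buildGeneticMap(res$binMap)
  bm <- res$binMap
  m <- ncol(bm@genotypes)
  rev <- new("BinMap", bins = GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = rev(2e7 - GenomicRanges::end(bm@bins) + 1),
      end = rev(2e7 - GenomicRanges::start(bm@bins) + 1)),
    binId = sprintf("mk%d", seq_len(m))),
    genotypes = bm@genotypes[, m:1], grid = bm@grid)
  colnames(rev@genotypes) <- sprintf("mk%d", seq_len(m))
  gmRev <- buildGeneticMap(rev)
  expect_equal(mapSummary(gmRev)[1, "geneticCM"],
    mapSummary(gm)[1, "geneticCM"], tolerance = 1e-9)
})

test_that("genotyping error in bin calls inflates the estimated map length", {
  ## error inflates apparent recombination: flipping 1% of bin genotypes
  ## must lengthen the estimated map on every matched replicate
  gt <- tinyTemplate(bp = 2e7, cm = 90, nSnps = 400)
  pop <- simulateRILPopulation(gt, 60, seed = 301)
  clean <- callBinMap(pop$calls, c(chr1 = 2e7))$binMap
  lenClean <- mapSummary(buildGeneticMap(clean))[1, "geneticCM"]
  for (s in 1:20) {
    noisy <- clean
    g <- noisy@genotypes
    flip <- withr::with_seed(400 + s,
      sample(which(g %in% c("A", "B")), round(0.01 * length(g))))
    g[flip] <- ifelse(g[flip] == "A", "B", "A")
    noisy@genotypes <- g
    lenNoisy <- mapSummary(buildGeneticMap(noisy))[1, "geneticCM"]
    expect_gt(lenNoisy, lenClean)
  }
})

test_that("error-free simulation recovers the simulated map length", {
  ## two chromosomes at the SNP-per-cM density of a GBS maize map
  ## (~1.06 cM/Mb, 12 SNPs/Mb)
  gt <- buildGenomeTemplate(2, c(1e8, 1e8), c(106, 106), 1200, seed = 11)
  pop <- simulateRILPopulation(gt, 150, seed = 41)
  res <- callBinMap(pop$calls, setNames(gt@chromosomes$bpLength,
    gt@chromosomes$name))
  gm <- buildGeneticMap(res$binMap)
  tot <- mapSummary(gm)
  expect_equal(tot[tot$chrom == "Total", "geneticCM"], 212, tolerance = 0.10)
})

test_that("finite-generation selfing correction matches its limits", {
  ## at fixation the two-locus chain reproduces 2r / (1 + 2r)
  r <- c(0.01, 0.1, 0.3)
  R50 <- vapply(r, binQTL:::twoLocusSelfingR, numeric(1), generations = 50)
  expect_equal(R50, rilMeioticToObserved(r), tolerance = 1e-8)
  ## one generation (F2 scored with half-weight heterozygotes): the
  ## hand-enumerated expectation is r(1-r) + r^2/2 = r - r^2/2
  R1 <- vapply(r, binQTL:::twoLocusSelfingR, numeric(1), generations = 1)
  expect_equal(R1, r - r^2 / 2, tolerance = 1e-12)
  ## inverse round-trips at the default generation count
  R6 <- vapply(r, binQTL:::twoLocusSelfingR, numeric(1), generations = 6)
  expect_equal(rilFiniteInverse(R6, 6), r, tolerance = 1e-3)
})
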