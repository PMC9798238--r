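test_that("heterozygous genome fraction follows the selfing recursion", {
  gt <- tinyTemplate(nChrom = 2, bp = 5e7, cm = 120, nSnps = 300)
  ## one selfing generation = F2: half the genome heterozygous
  f2 <- simulateRILPopulation(gt, 120, selfingGenerations = 1, seed = 5)
  hf2 <- mean(genotypeCalls(f2$calls) == "H")
  expect_equal(hf2, 0.5, tolerance = 0.08)
  ## five generations: (1/2)^5 ~ 3.1%
  f6 <- simulateRILPopulation(gt, 220, selfingGenerations = 5, seed = 6)
  hf6 <- mean(genotypeCalls(f6$calls) == "H")
  expect_lt(abs(hf6 - 2^-5), 0.012)
})

test_that("zero genetic length gives zero breakpoints", {
  gt <- buildGenomeTemplate(1, 1e6, 0, 20, seed = 2)
  pop <- simulateRILPopulation(gt, 30, seed = 3)
  expect_equal(nrow(trueBreakpoints(pop$truth)), 0)
  ## every line is a single parental segment
  for (ln in lineIds(pop$truth))
    expect_equal(nrow(trueSegments(pop$truth)[[ln]]$chr1), 1)
})

test_that("breakpoint count per line matches the RIL map-expansion factor", {
  ## selfed RILs accumulate junctions at ~2x the meiotic map length
  gt <- tinyTemplate(bp = 3e7, cm = 150, nSnps = 100)
  pop <- simulateRILPopulation(gt, 250, selfingGenerations = 6, seed = 9)
  nbp <- table(factor(trueBreakpoints(pop$truth)$line,
    levels = lineIds(pop$truth)))
  expect_equal(mean(nbp), 2 * 150 / 100, tolerance = 0.10)
})

test_that("SNP calls and truth segments are mutually consistent", {
  gt <- tinyTemplate(nChrom = 2, bp = 2e7, cm = 100, nSnps = 250)
  pop <- simulateRILPopulation(gt, 40, seed = 13)
  for (cc in c("chr1", "chr2")) {
    sel <- markerInfo(pop$calls)$chrom == cc
    rederived <- truthGenotypeAt(pop$truth, cc, markerInfo(pop$calls)$pos[sel])
    expect_identical(unname(genotypeCalls(pop$calls)[, sel]),
      unname(rederived))
  }
})

test_that("the population is reproducible from the seed alone", {
  gt <- tinyTemplate(nSnps = 60)
  a <- simulateRILPopulation(gt, 15, seed = 42)
  b <- simulateRILPopulation(gt, 15, seed = 42)
  expect_identical(genotypeCalls(a$calls), genotypeCalls(b$calls))
  expect_identical(trueSegments(a$truth), trueSegments(b$truth))
  c <- simulateRILPopulation(gt, 15, seed = 43)
  expect_false(identical(genotypeCalls(a$calls), genotypeCalls(c$calls)))
})

test_that("forceHomozygous removes residual heterozygosity", {
  gt <- tinyTemplate(nSnps = 150)
  pop <- simulateRILPopulation(gt, 50, selfingGenerations = 3, seed = 4,
    forceHomozygous = TRUE)
  expect_false(any(genotypeCalls(pop$calls) == "H"))
})

test_that("corruption: identity at zero rates, all-N at missingRate 1", {
  gt <- tinyTemplate(nSnps = 80)
  pop <- simulateRILPopulation(gt, 10, seed = 1)
  same <- corruptGenotypes(pop$calls, 0, 0, seed = 2)
  expect_identical(genotypeCalls(same), genotypeCalls(pop$calls))
  gone <- corruptGenotypes(pop$calls, 0, 1, seed = 2)
  expect_true(all(genotypeCalls(gone) == "N"))
  expect_error(corruptGenotypes(pop$calls, -0.1, 0), "\\[0, 1\\]")
  expect_error(corruptGenotypes(pop$calls, 0, 1.1), "\\[0, 1\\]")
})

test_that("observed flip fraction matches the binomial expectation", {
  gt <- tinyTemplate(nChrom = 4, bp = 1e7, cm = 50, nSnps = 2500)
  pop <- simulateRILPopulation(gt, 100, seed = 21)   # 1e6 calls
  err <- corruptGenotypes(pop$calls, errorRate = 0.01, missingRate = 0,
    seed = 22)
  nCalls <- length(genotypeCalls(pop$calls))
  flipped <- mean(genotypeCalls(err) != genotypeCalls(pop$calls))
  expect_equal(flipped, 0.01, tolerance = 3 * sqrt(0.01 * 0.99 / nCalls) / 0.01)
})

test_that("phenotype simulation honors the additive QTL model", {
  gt <- tinyTemplate(nSnps = 50)
  pop <- simulateRILPopulation(gt, 30, seed = 8, forceHomozygous = TRUE)
  ## all effects and variances zero: every record equals the intercept
  arch0 <- traitArchitecture(sigmaEnv2 = 0, sigmaRep2 = 0, intercept = 7)
  ph0 <- simulatePhenotypes(pop$truth, arch0, seed = 1)
  expect_true(all(ph0$value == 7))
  expect_equal(nrow(ph0), 30 * 4 * 3)  # lines x (2y x 2l) x 3 reps
  ## single QTL a=1, no noise: A vs B lines differ by exactly 2
  arch1 <- traitArchitecture(qtl = data.frame(chrom = "chr1", posBp = 5e6,
    effect = 1), sigmaEnv2 = 0, sigmaRep2 = 0)
  ph1 <- simulatePhenotypes(pop$truth, arch1, seed = 2)
  lab <- truthGenotypeAt(pop$truth, "chr1", 5e6)[, 1]
  perLine <- tapply(ph1$value, ph1$line, unique)[names(lab)]
  if (any(lab == "A") && any(lab == "B"))
    expect_equal(as.numeric(unique(perLine[lab == "A"])) -
      as.numeric(unique(perLine[lab == "B"])), 2)
  ## off-chromosome QTL is a configuration error
  archBad <- traitArchitecture(qtl = data.frame(chrom = "chrX", posBp = 1,
    effect = 1))
  expect_error(simulatePhenotypes(pop$truth, archBad, seed = 1), "off the")
})

test_that("architecture preset hits the target heritability analytically", {
  arch <- paperTraitArchitecture(targetH2 = 0.81)
  expect_equal(expectedArchitectureH2(arch), 0.81, tolerance = 1e-10)
})
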