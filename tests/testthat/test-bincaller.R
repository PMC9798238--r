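test_that("window rule: the published 11/15 examples hold exactly", {
  w15 <- function(codes) callWindows(codes, 15, 1, 11)$windows$call
  expect_equal(w15(rep("A", 15)), "A")
  expect_equal(w15(c(rep("A", 11), rep("B", 4))), "A")
  expect_equal(w15(c(rep("A", 8), rep("B", 7))), "H")
  expect_equal(w15(c(rep("B", 11), rep("A", 4))), "B")
  expect_equal(w15(c(rep("A", 10), rep("B", 5))), "H")  # 10 < 11 majority
})

test_that("window rule matches the brute-force oracle on all 136 compositions", {
  ## every (nA, nB, nH) with nA + nB + nH = 15
  comps <- expand.grid(nA = 0:15, nB = 0:15)
  comps <- comps[comps$nA + comps$nB <= 15, ]
  expect_equal(nrow(comps), 136)
  for (i in seq_len(nrow(comps))) {
    codes <- c(rep("A", comps$nA[i]), rep("B", comps$nB[i]),
      rep("H", 15 - comps$nA[i] - comps$nB[i]))
    codes <- sample(codes)   # order must not matter
    expect_equal(callWindows(codes, 15, 1, 11)$windows$call,
      windowRuleOracle(codes), info = paste(comps$nA[i], comps$nB[i]))
  }
})

test_that("missing calls are skipped so windows hold 15 informative sites", {
  codes <- c(rep("A", 10), rep("N", 5), rep("A", 4), "B")
  tr <- callWindows(codes, 15, 1, 11)
  expect_equal(nrow(tr$windows), 1)
  expect_equal(tr$windows$call, "A")
  expect_equal(tr$windows$firstSnp, 1)
  expect_equal(tr$windows$lastSnp, 20)   # spans the N gap
  ## fewer than 15 non-missing codes: zero windows
  expect_equal(nrow(callWindows(rep(c("A", "N"), 7), 15)$windows), 0)
})

test_that("window precondition guards the majority rule", {
  expect_error(callWindows(rep("A", 20), window = 15, majority = 7),
    "majority")
})

test_that("block merging collapses runs and locates breakpoints between them", {
  ## 30 A then 30 B, evenly spaced: one A block, one B block, one breakpoint
  codes <- c(rep("A", 30), rep("B", 30))
  pos <- seq_len(60) * 1000
  tr <- callWindows(codes, 15, 1, 11)
  mb <- mergeBlocks(tr, codes, pos)
  expect_equal(mb$blocks$call, c("A", "B"))
  expect_equal(nrow(mb$breakpoints), 1)
  ## interval spans the last A to the first B
  expect_equal(mb$breakpoints$bpLow, 30000)
  expect_equal(mb$breakpoints$bpHigh, 31000)
  expect_equal(mb$breakpoints$mid, 30500)

  ## all-A input: a single block, no breakpoints
  mbA <- mergeBlocks(callWindows(rep("A", 40)), rep("A", 40),
    seq_len(40) * 100)
  expect_equal(nrow(mbA$blocks), 1)
  expect_equal(nrow(mbA$breakpoints), 0)

  ## A -> H -> B gives three blocks and two breakpoints
  codes3 <- c(rep("A", 20), rep(c("A", "B"), 15), rep("B", 20))
  tr3 <- callWindows(codes3, 15, 1, 11)
  mb3 <- mergeBlocks(tr3, codes3, seq_along(codes3) * 10)
  expect_equal(mb3$blocks$call, c("A", "H", "B"))
  expect_equal(nrow(mb3$breakpoints), 2)
  expect_true(all(mb3$breakpoints$bpLow < mb3$breakpoints$bpHigh))
  expect_true(all(mb3$breakpoints$leftCall != mb3$breakpoints$rightCall))
})

test_that("population bins follow the 100-kb grid convention", {
  ## no breakpoints: one bin per chromosome
  bp0 <- data.frame(chrom = character(0), mid = numeric(0))
  bins0 <- detectPopulationBins(bp0, c(chr1 = 1e6, chr2 = 5e5))
  expect_equal(length(bins0), 2)
  expect_equal(GenomicRanges::width(bins0), c(1e6, 5e5))
  ## single midpoint at 450 kb on a 1-Mb chromosome: bins [0,400k) [400k,1M)
  bp1 <- data.frame(chrom = "chr1", mid = 450e3)
  bins1 <- detectPopulationBins(bp1, c(chr1 = 1e6))
  expect_equal(GenomicRanges::start(bins1), c(1, 400001))
  expect_equal(GenomicRanges::end(bins1), c(400000, 1000000))
  ## a midpoint in the first grid cell does not create an empty leading bin
  bp2 <- data.frame(chrom = "chr1", mid = 50e3)
  expect_equal(length(detectPopulationBins(bp2, c(chr1 = 1e6))), 1)
})

test_that("bin genotyping: block call, breakpoint-bin majority, flanking fill", {
  ## one line, chromosome of 1 Mb, A block then B block
  codes <- c(rep("A", 30), rep("B", 30))
  pos <- c(seq(5000, 295000, by = 10000), seq(705000, 995000, by = 10000))
  calls <- matrix(codes, 1, dimnames = list("L1", NULL))
  scm <- mkSCM(calls)
  scm@markers$pos <- pos
  colnames(scm@calls) <- sprintf("chr1_%d", pos)
  sm <- smoothPopulation(scm)
  bins <- detectPopulationBins(sm$breakpoints, c(chr1 = 1e6))
  bm <- genotypeBins(sm, scm, bins)
  g <- genotypeCalls(bm)[1, ]
  st <- GenomicRanges::start(binRanges(bm))
  en <- GenomicRanges::end(binRanges(bm))
  ## bins fully left of the breakpoint interval are A, right are B
  expect_true(all(g[en <= 295000] == "A"))
  expect_true(all(g[st >= 705000] == "B"))
  ## the SNP-free gap sits inside the breakpoint interval; bins there have
  ## no raw calls and disagreeing flanks -> N
  expect_true(all(g[st >= 300001 & en <= 700000] == "N"))
})

test_that("bin genotyping uses raw-call majority inside breakpoint bins", {
  ## hand-built smoothing result: one wide breakpoint interval covering
  ## the middle bin, whose raw calls are 7 A vs 2 B
  pos <- c(50000, seq(110000, 190000, by = 10000), 250000)
  codes <- c("A", "A", "A", "A", "B", "A", "A", "B", "A", "A", "B")
  calls <- matrix(codes, 1, dimnames = list("L1", NULL))
  scm <- new("SNPCallMatrix", calls = calls,
    markers = data.frame(chrom = "chr1", pos = pos))
  colnames(scm@calls) <- sprintf("chr1_%d", pos)
  bins <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = c(1, 100001, 200001),
      end = c(100000, 200000, 300000)), binId = c("mk1", "mk2", "mk3"))
  smoothed <- list(
    blocks = list(chr1 = list(L1 = data.frame(call = c("A", "B"),
      firstSnp = c(1L, 11L), lastSnp = c(10L, 11L)))),
    lineBreakpoints = list(chr1 = list(L1 = data.frame(
      bpLow = 95000, bpHigh = 205000, leftCall = "A", rightCall = "B",
      mid = 150000))),
    breakpoints = data.frame(line = "L1", chrom = "chr1", bpLow = 95000,
      bpHigh = 205000, leftCall = "A", rightCall = "B", mid = 150000))
  bm <- genotypeBins(smoothed, scm, bins)
  g <- unname(genotypeCalls(bm)[1, ])
  expect_equal(g[2], "A")   # 7 A vs 2 B majority inside the interval
  expect_equal(g[1], "A")   # block call left of the interval... via majority
  expect_equal(g[3], "B")
})

test_that("bins with no raw calls take the flanking-agreement fill", {
  ## breakpoint interval spans an empty middle bin; flanking blocks agree
  pos <- c(50000, 250000)
  calls <- matrix(c("A", "A"), 1, dimnames = list("L1", NULL))
  scm <- new("SNPCallMatrix", calls = calls,
    markers = data.frame(chrom = "chr1", pos = pos))
  colnames(scm@calls) <- sprintf("chr1_%d", pos)
  bins <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = c(1, 100001, 200001),
      end = c(100000, 200000, 300000)), binId = c("mk1", "mk2", "mk3"))
  mkSmooth <- function(leftCall, rightCall) list(
    blocks = list(chr1 = list(L1 = data.frame(
      call = c(leftCall, rightCall), firstSnp = c(1L, 2L),
      lastSnp = c(1L, 2L)))),
    lineBreakpoints = list(chr1 = list(L1 = data.frame(
      bpLow = 110000, bpHigh = 190000, leftCall = leftCall,
      rightCall = rightCall, mid = 150000))),
    breakpoints = data.frame(line = "L1", chrom = "chr1", bpLow = 110000,
      bpHigh = 190000, leftCall = leftCall, rightCall = rightCall,
      mid = 150000))
  gAgree <- unname(genotypeCalls(genotypeBins(mkSmooth("A", "A"), scm,
    bins))[1, ])
  expect_equal(gAgree[2], "A")
  gDisagree <- unname(genotypeCalls(genotypeBins(mkSmooth("A", "B"), scm,
    bins))[1, ])
  expect_equal(gDisagree[2], "N")
})

test_that("single-block line genotypes every bin with the block call", {
  calls <- matrix("A", 2, 40, dimnames = list(c("L1", "L2"), NULL))
  calls[2, ] <- "B"
  scm <- mkSCM(calls, spacing = 20000)
  res <- callBinMap(scm, c(chr1 = 1e6))
  expect_true(all(genotypeCalls(res$binMap)["L1", ] == "A"))
  expect_true(all(genotypeCalls(res$binMap)["L2", ] == "B"))
  expect_equal(res$summary$total, 0)
})

test_that("breakpoint summary counts per line and population totals", {
  bp <- data.frame(line = c("a", "a", "b", "c", "c", "c", "b", "b", "b"))
  s <- breakpointSummary(bp, lines = c("a", "b", "c", "d"))
  expect_equal(s$total, 9)
  expect_equal(as.numeric(s$perLine), c(2, 4, 3, 0))
  expect_equal(s$meanPerLine, 2.25)
  s0 <- breakpointSummary(bp[0, , drop = FALSE], lines = "a")
  expect_equal(s0$total, 0)
  expect_equal(s0$meanPerLine, 0)
})

test_that("bin construction is deterministic and interiors are breakpoint-free", {
  gt <- tinyTemplate(nChrom = 2, bp = 2e7, cm = 80, nSnps = 500)
  pop <- simulateRILPopulation(gt, 60, seed = 17)
  obs <- corruptGenotypes(pop$calls, 0.01, 0.05, seed = 18)
  lens <- setNames(gt@chromosomes$bpLength, gt@chromosomes$name)
  r1 <- callBinMap(obs, lens)
  r2 <- callBinMap(obs, lens)
  expect_identical(genotypeCalls(r1$binMap), genotypeCalls(r2$binMap))
  expect_identical(binRanges(r1$binMap), binRanges(r2$binMap))
  ## no interior 100-kb cell of any bin contains a breakpoint midpoint
  grid <- r1$binMap@grid
  for (cc in unique(r1$smoothed$breakpoints$chrom)) {
    mids <- r1$smoothed$breakpoints$mid[r1$smoothed$breakpoints$chrom == cc]
    midCells <- unique(floor(mids / grid) * grid)
    sel <- as.character(GenomicRanges::seqnames(binRanges(r1$binMap))) == cc
    st <- GenomicRanges::start(binRanges(r1$binMap))[sel] - 1
    en <- GenomicRanges::end(binRanges(r1$binMap))[sel]
    for (k in seq_along(st)) {
      interior <- midCells[midCells > st[k] & midCells < en[k]]
      expect_length(interior, 0)
    }
  }
})
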