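# Fixture builders shared across the suite. Everything is generated in
# code; no data files.

# A small uniform-rate template: one or more chromosomes of equal size.
tinyTemplate <- function(nChrom = 1, bp = 1e7, cm = 100, nSnps = 200,
                         seed = 11) {
  buildGenomeTemplate(nChrom, rep(bp, nChrom), rep(cm, nChrom), nSnps,
    seed = seed)
}

# Construct a BinMap directly from a genotype matrix: bins laid out as
# consecutive `width`-bp intervals on one chromosome per supplied name.
mkBinMap <- function(geno, chrom = "chr1", width = 1e5) {
  m <- ncol(geno)
  gr <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(start = (seq_len(m) - 1) * width + 1,
      end = seq_len(m) * width),
    binId = sprintf("mk%d", seq_len(m)))
  if (is.null(rownames(geno))) rownames(geno) <- sprintf("L%02d", seq_len(nrow(geno)))
  colnames(geno) <- sprintf("mk%d", seq_len(m))
  new("BinMap", bins = gr, genotypes = geno, grid = width)
}

# A SNPCallMatrix from a code matrix with evenly spaced positions.
mkSCM <- function(calls, chrom = "chr1", spacing = 1000) {
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("L%02d", seq_len(nrow(calls)))
  mk <- data.frame(chrom = chrom, pos = seq_len(ncol(calls)) * spacing,
    stringsAsFactors = FALSE)
  colnames(calls) <- sprintf("%s_%d", mk$chrom, mk$pos)
  new("SNPCallMatrix", calls = calls, markers = mk)
}

# Brute-force oracle for the 15-SNP window rule: explicit counting,
# independent of the cumulative-sum implementation.
windowRuleOracle <- function(codes, majority = 11) {
  nA <- sum(codes == "A")
  nB <- sum(codes == "B")
  if (nA >= majority) "A" else if (nB >= majority) "B" else "H"
}

# Balanced-design closed-form REML (= ANOVA expected-mean-squares) oracle
# for the model value ~ mu + line + env + line:env + error with r reps.
balancedAnovaVC <- function(d) {
  g <- length(unique(d$line)); e <- length(unique(d$env))
  r <- nrow(d) / (g * e)
  cellMeans <- tapply(d$value, list(d$line, d$env), mean)
  lineMeans <- rowMeans(cellMeans); envMeans <- colMeans(cellMeans)
  grand <- mean(d$value)
  ssG <- e * r * sum((lineMeans - grand)^2)
  ssE <- g * r * sum((envMeans - grand)^2)
  ssGE <- r * sum((sweep(sweep(cellMeans, 1, lineMeans), 2, envMeans) + grand)^2)
  ssErr <- sum((d$value - cellMeans[cbind(d$line, d$env)])^2)
  msG <- ssG / (g - 1); msE <- ssE / (e - 1)
  msGE <- ssGE / ((g - 1) * (e - 1)); msErr <- ssErr / (g * e * (r - 1))
  list(sigmaG2 = (msG - msGE) / (e * r), sigmaEnv2 = (msE - msGE) / (g * r),
    sigmaGE2 = (msGE - msErr) / r, sigmaE2 = msErr)
}
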