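#' Select parental-informative SNPs
#'
#' Keeps SNPs where both parents are homozygous for different alleles (the
#' aa x bb segregation pattern); heterozygous, missing or monomorphic
#' parental calls are dropped.
#'
#' @param parent1Calls,parent2Calls character vectors of per-SNP diploid
#'   base calls, e.g. `"AA"`, `"AG"`, `"TT"`; `NA` = missing. Both vectors
#'   must align to the same SNPs.
#' @return data.frame with columns `index` (position in the input),
#'   `allele1`, `allele2` (the parent-1 and parent-2 alleles).
#' @export
selectParentalInformative <- function(parent1Calls, parent2Calls) {
  stopIfNot(length(parent1Calls) == length(parent2Calls),
    "parental call vectors must have equal length")
  splitAlleles <- function(x) {
    a <- matrix(NA_character_, length(x), 2)
    ok <- !is.na(x) & nchar(x) == 2
    a[ok, 1] <- substr(x[ok], 1, 1)
    a[ok, 2] <- substr(x[ok], 2, 2)
    a
  }
  a1 <- splitAlleles(parent1Calls)
  a2 <- splitAlleles(parent2Calls)
  hom1 <- !is.na(a1[, 1]) & a1[, 1] == a1[, 2]
  hom2 <- !is.na(a2[, 1]) & a2[, 1] == a2[, 2]
  keep <- hom1 & hom2 & a1[, 1] != a2[, 1]
  if (!any(keep))
    stop("no informative markers: no SNP has both parents homozygous for different alleles",
      call. = FALSE)
  data.frame(index = which(keep), allele1 = a1[keep, 1], allele2 = a2[keep, 1],
    stringsAsFactors = FALSE)
}

#' Encode progeny base calls by parental origin
#'
#' At each parental-informative SNP, progeny genotypes are recoded `A`
#' (parent-1 homozygote), `B` (parent-2 homozygote) or `H` (heterozygote).
#' Any allele carried by neither parent is an abnormal base and the call is
#' masked to `N`, as are missing calls.
#'
#' @param progenyCalls character matrix lines x SNPs of diploid base calls
#'   (same SNP order as the vectors given to [selectParentalInformative()]).
#' @param informative data.frame from [selectParentalInformative()].
#' @param markers optional data.frame (`chrom`, `pos`) aligned to the input
#'   SNP columns; subset to the informative set in the output.
#' @return a [SNPCallMatrix-class] restricted to the informative SNPs.
#' @export
encodeByParent <- function(progenyCalls, informative, markers = NULL) {
  sub <- progenyCalls[, informative$index, drop = FALSE]
  n <- nrow(sub); m <- ncol(sub)
  a1 <- matrix(informative$allele1, n, m, byrow = TRUE)
  a2 <- matrix(informative$allele2, n, m, byrow = TRUE)
  b1 <- substr(sub, 1, 1); b2 <- substr(sub, 2, 2)
  out <- matrix("N", n, m, dimnames = dimnames(sub))
  valid <- !is.na(sub) & nchar(sub) == 2 &
    (b1 == a1 | b1 == a2) & (b2 == a1 | b2 == a2)
  out[valid & b1 == a1 & b2 == a1] <- "A"
  out[valid & b1 == a2 & b2 == a2] <- "B"
  out[valid & ((b1 == a1 & b2 == a2) | (b1 == a2 & b2 == a1))] <- "H"
  if (is.null(markers))
    markers <- data.frame(chrom = "chr1", pos = informative$index)
  else
    markers <- markers[informative$index, , drop = FALSE]
  rownames(markers) <- NULL
  if (is.null(rownames(out))) rownames(out) <- paste0("line", seq_len(n))
  colnames(out) <- sprintf("%s_%d", markers$chrom, markers$pos)
  new("SNPCallMatrix", calls = out, markers = markers)
}

## chi-square goodness of fit of A:B counts against 1:1 (1 df), with an
## optional Yates continuity correction.
segregationChisq <- function(nA, nB, continuity = FALSE) {
  tot <- nA + nB
  e <- tot / 2
  dev <- abs(nA - e)
  if (continuity) dev <- pmax(dev - 0.5, 0)
  chi <- ifelse(tot > 0, 2 * dev^2 / e, NA_real_)
  p <- pchisq(chi, df = 1, lower.tail = FALSE)
  list(chisq = chi, p = p)
}

#' Filter SNPs with segregation distortion
#'
#' Per SNP, a chi-square goodness-of-fit test of the A:B counts against the
#' 1:1 RIL expectation (heterozygous and missing calls excluded); SNPs with
#' p below `alpha` are removed, as are SNPs with zero informative calls.
#'
#' @param scm a [SNPCallMatrix-class].
#' @param alpha significance level (default 0.001).
#' @param continuity apply the Yates continuity correction (default FALSE;
#'   call counts in a mapping population are large).
#' @return the filtered [SNPCallMatrix-class]; attribute `removed` holds
#'   the dropped marker indices.
#' @export
filterSegregation <- function(scm, alpha = 0.001, continuity = FALSE) {
  calls <- scm@calls
  nA <- colSums(calls == "A")
  nB <- colSums(calls == "B")
  ts <- segregationChisq(nA, nB, continuity)
  drop <- is.na(ts$p) | ts$p < alpha
  if (any(drop))
    message(sum(drop), " SNP(s) removed by the segregation-distortion filter")
  out <- scm[, !drop]
  attr(out, "removed") <- unname(which(drop))
  out
}

#' Filter SNPs and lines by call rate
#'
#' Drops SNPs whose non-missing fraction is below `minSnpRate`, then lines
#' whose non-missing fraction (over the retained SNPs) is below
#' `minLineRate`, iterating this fixed SNPs-then-lines order until no
#' further removal occurs, so the filter is idempotent.
#'
#' @param scm a [SNPCallMatrix-class].
#' @param minSnpRate,minLineRate call-rate thresholds in `[0, 1]`
#'   (default 0.2 for both).
#' @return the filtered [SNPCallMatrix-class].
#' @export
filterCallRate <- function(scm, minSnpRate = 0.2, minLineRate = 0.2) {
  stopIfNot(minSnpRate >= 0 && minSnpRate <= 1 &&
    minLineRate >= 0 && minLineRate <= 1, "call-rate thresholds must be in [0, 1]")
  out <- scm
  repeat {
    keepSnp <- colMeans(out@calls != "N") >= minSnpRate
    if (!any(keepSnp)) stop("call-rate filter removed all SNPs", call. = FALSE)
    out <- out[, keepSnp]
    keepLine <- rowMeans(out@calls != "N") >= minLineRate
    if (!any(keepLine)) stop("call-rate filter removed all lines", call. = FALSE)
    out <- out[keepLine, ]
    if (all(keepSnp) && all(keepLine)) break
  }
  out
}

#' Drop SNPs on unanchored sequences
#'
#' Retains only SNPs whose chromosome name is in the allow-list (scaffold
#' placed markers cannot be ordered on the physical map).
#'
#' @param scm a [SNPCallMatrix-class].
#' @param allowed character vector of chromosome names to keep (default
#'   `chr1`-`chr10`).
#' @return the filtered [SNPCallMatrix-class].
#' @export
filterScaffolds <- function(scm, allowed = paste0("chr", 1:10)) {
  keep <- scm@markers$chrom %in% allowed
  if (!any(keep)) stop("no SNPs on allowed chromosomes", call. = FALSE)
  scm[, keep]
}

#' Run the full post-calling QC chain
#'
#' Scaffold screen, segregation-distortion filter, then call-rate filters,
#' with a per-step removal report.
#'
#' @param scm a [SNPCallMatrix-class] (already ABH-encoded).
#' @param alpha segregation-distortion significance level.
#' @param minSnpRate,minLineRate call-rate thresholds.
#' @param allowed chromosome allow-list (default: all chromosomes present).
#' @return list with `calls` (filtered [SNPCallMatrix-class]) and `report`
#'   (data.frame of SNP/line counts after each step).
#' @export
runGenotypeQC <- function(scm, alpha = 0.001, minSnpRate = 0.2,
                          minLineRate = 0.2, allowed = NULL) {
  if (is.null(allowed)) allowed <- unique(scm@markers$chrom)
  steps <- list(input = scm)
  steps$scaffold <- filterScaffolds(steps$input, allowed)
  steps$segregation <- suppressMessages(filterSegregation(steps$scaffold, alpha))
  steps$callRate <- filterCallRate(steps$segregation, minSnpRate, minLineRate)
  report <- data.frame(
    step = names(steps),
    nSnps = vapply(steps, function(s) ncol(s@calls), 1L),
    nLines = vapply(steps, function(s) nrow(s@calls), 1L),
    row.names = NULL)
  list(calls = steps$callRate, report = report)
}
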