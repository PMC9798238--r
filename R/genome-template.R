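#' Build a genome template for RIL simulation
#'
#' Defines chromosome physical/genetic lengths and places SNPs uniformly at
#' random (without replacement) along each chromosome. Genetic coordinates
#' are assigned by monotone linear interpolation between bp/cM anchors; by
#' default the recombination rate is uniform per chromosome (two anchors).
#'
#' @param nChrom number of chromosomes.
#' @param bpLengths numeric vector of physical lengths (bp), length `nChrom`.
#' @param cmLengths numeric vector of genetic lengths (cM), length `nChrom`.
#' @param nSnpsPerChrom integer (recycled): SNPs per chromosome, >= 2.
#' @param seed integer seed for SNP placement.
#' @param chromNames optional chromosome names (default `chr1..chrN`).
#' @param mapAnchors optional named list of data.frames (`bp`, `cm`) giving
#'   a piecewise-linear recombination-rate map per chromosome; must start at
#'   (1, 0) and end at (`bpLength`, `cmLength`).
#' @return a [GenomeTemplate-class] object.
#' @examples
#' gt <- buildGenomeTemplate(2, c(2e6, 1e6), c(100, 50), 50, seed = 1)
#' gt
#' @export
buildGenomeTemplate <- function(nChrom, bpLengths, cmLengths, nSnpsPerChrom,
                                seed = 1L, chromNames = NULL,
                                mapAnchors = NULL) {
  stopIfNot(length(bpLengths) == nChrom && length(cmLengths) == nChrom,
    "bpLengths and cmLengths must have length nChrom")
  stopIfNot(all(bpLengths > 0), "chromosome physical lengths must be positive")
  stopIfNot(all(cmLengths >= 0), "chromosome genetic lengths must be >= 0")
  nSnps <- rep_len(as.integer(nSnpsPerChrom), nChrom)
  stopIfNot(all(nSnps >= 2), "need at least 2 SNPs per chromosome")
  if (is.null(chromNames)) chromNames <- paste0("chr", seq_len(nChrom))

  snps <- withSeed(seed, {
    lapply(seq_len(nChrom), function(i)
      sort(sample.int(as.integer(bpLengths[i]), nSnps[i])))
  })
  names(snps) <- chromNames

  if (is.null(mapAnchors)) {
    mapAnchors <- lapply(seq_len(nChrom), function(i)
      data.frame(bp = c(1, bpLengths[i]), cm = c(0, cmLengths[i])))
  } else {
    for (i in seq_len(nChrom)) {
      a <- mapAnchors[[i]]
      stopIfNot(a$bp[1] == 1 && a$cm[1] == 0 &&
        abs(a$bp[nrow(a)] - bpLengths[i]) < 1 &&
        abs(a$cm[nrow(a)] - cmLengths[i]) < 1e-9,
        "mapAnchors for chromosome %d must span (1,0) to (bpLength,cmLength)", i)
      stopIfNot(!is.unsorted(a$bp, strictly = TRUE) && !is.unsorted(a$cm),
        "mapAnchors for chromosome %d must be monotone", i)
    }
  }
  names(mapAnchors) <- chromNames

  new("GenomeTemplate",
    chromosomes = data.frame(name = chromNames, bpLength = as.numeric(bpLengths),
      cmLength = as.numeric(cmLengths), stringsAsFactors = FALSE),
    snpPositions = snps, mapAnchors = mapAnchors)
}

#' Genetic coordinates of the template's SNPs
#'
#' @param template a [GenomeTemplate-class].
#' @return named list of numeric cM positions per chromosome.
#' @export
snpGeneticPositions <- function(template) {
  ch <- template@chromosomes
  out <- lapply(ch$name, function(nm)
    cmAtBp(template@mapAnchors[[nm]], template@snpPositions[[nm]]))
  names(out) <- ch$name
  out
}

## Published dimensions of the maize Ji846 x Ye3189 bin map (10 chromosomes;
## per-chromosome physical lengths in bp and genetic lengths in cM).
MAIZE_BP_LENGTHS <- c(301476924, 237917468, 232245527, 242062272, 217959525,
  169407836, 176826311, 175377492, 157038028, 149632204)
MAIZE_CM_LENGTHS <- c(360.88, 258.14, 233.27, 247.66, 204.27,
  183.40, 197.27, 192.74, 171.88, 131.41)
MAIZE_SNP_COUNTS <- c(10773, 9213, 10214, 8665, 6335,
  7218, 6923, 7949, 5402, 4988)

#' Maize-scale genome template preset
#'
#' Ten chromosomes with the physical and genetic lengths of the published
#' maize RIL bin map (total ~2.06 Gb, ~2,181 cM).
#'
#' @param nSnpsPerChrom SNPs per chromosome (default 300; the map this
#'   preset mirrors carried the per-chromosome GBS SNP counts in
#'   `MAIZE_SNP_COUNTS`, but downstream bin construction only needs enough
#'   SNP support per window).
#' @param seed integer seed for SNP placement.
#' @return a [GenomeTemplate-class].
#' @export
maizeGenomeTemplate <- function(nSnpsPerChrom = 300L, seed = 1L) {
  buildGenomeTemplate(10L, MAIZE_BP_LENGTHS, MAIZE_CM_LENGTHS,
    nSnpsPerChrom, seed = seed)
}
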