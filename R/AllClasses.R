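## Central S4 containers. Genotype codes throughout: "A" = parent-1 (female)
## homozygote, "B" = parent-2 (male) homozygote, "H" = heterozygote,
## "N" = missing/abnormal.

GENO_CODES <- c("A", "B", "H", "N")

#' GenomeTemplate: chromosome dimensions and SNP scaffold for simulation
#'
#' Holds physical and genetic chromosome lengths, per-chromosome SNP
#' positions, and the monotone bp <-> cM interpolation anchors (piecewise
#' linear; default two anchors per chromosome, i.e. a uniform recombination
#' rate).
#'
#' @slot chromosomes data.frame with columns `name`, `bpLength`, `cmLength`.
#' @slot snpPositions named list (per chromosome) of strictly increasing
#'   1-based integer positions.
#' @slot mapAnchors named list of data.frames with columns `bp`, `cm`
#'   giving the monotone interpolation anchors per chromosome.
#' @exportClass GenomeTemplate
setClass("GenomeTemplate",
  representation(
    chromosomes = "data.frame",
    snpPositions = "list",
    mapAnchors = "list"
  )
)

setValidity("GenomeTemplate", function(object) {
  ch <- object@chromosomes
  msg <- character()
  if (!all(c("name", "bpLength", "cmLength") %in% names(ch)))
    msg <- c(msg, "chromosomes needs columns name, bpLength, cmLength")
  else {
    if (any(ch$bpLength <= 0)) msg <- c(msg, "bpLength must be positive")
    if (any(ch$cmLength < 0)) msg <- c(msg, "cmLength must be >= 0")
    if (anyDuplicated(ch$name)) msg <- c(msg, "duplicated chromosome names")
    if (!setequal(names(object@snpPositions), ch$name))
      msg <- c(msg, "snpPositions names must match chromosome names")
    for (nm in names(object@snpPositions)) {
      p <- object@snpPositions[[nm]]
      if (length(p) && (is.unsorted(p, strictly = TRUE) || p[1] < 1))
        msg <- c(msg, sprintf("SNP positions on %s not strictly increasing 1-based", nm))
    }
  }
  if (length(msg)) msg else TRUE
})

#' SNPCallMatrix: lines x SNPs parental-origin genotype calls
#'
#' @slot calls character matrix, rows = lines, columns = SNPs, entries in
#'   `{A, B, H, N}`; column names are marker ids.
#' @slot markers data.frame with one row per SNP column: `chrom`, `pos`
#'   (1-based bp), positions strictly increasing within chromosome.
#' @exportClass SNPCallMatrix
setClass("SNPCallMatrix",
  representation(calls = "matrix", markers = "data.frame")
)

setValidity("SNPCallMatrix", function(object) {
  msg <- character()
  if (!is.character(object@calls)) msg <- c(msg, "calls must be a character matrix")
  else if (!all(object@calls %in% GENO_CODES))
    msg <- c(msg, "calls restricted to codes A, B, H, N")
  mk <- object@markers
  if (!all(c("chrom", "pos") %in% names(mk)))
    msg <- c(msg, "markers needs columns chrom, pos")
  else {
    if (nrow(mk) != ncol(object@calls))
      msg <- c(msg, "one marker row per calls column required")
    for (cc in unique(mk$chrom)) {
      p <- mk$pos[mk$chrom == cc]
      if (is.unsorted(p, strictly = TRUE))
        msg <- c(msg, sprintf("positions on %s not strictly increasing", cc))
    }
  }
  if (is.null(rownames(object@calls)))
    msg <- c(msg, "calls must carry line ids as rownames")
  if (length(msg)) msg else TRUE
})

#' TrueGenomeSet: simulated parental-origin mosaics (ground truth)
#'
#' One element per line; each element is a named list over chromosomes of
#' data.frames with columns `startBp`, `endBp` (1-based inclusive), `label`
#' (A/B/H). Segments tile the chromosome; adjacent labels differ.
#'
#' @slot segments list as described above.
#' @slot chromLengths named numeric vector of chromosome bp lengths.
#' @exportClass TrueGenomeSet
setClass("TrueGenomeSet",
  representation(segments = "list", chromLengths = "numeric")
)

setValidity("TrueGenomeSet", function(object) {
  for (ln in names(object@segments)) {
    for (cc in names(object@segments[[ln]])) {
      seg <- object@segments[[ln]][[cc]]
      if (nrow(seg) == 0) next
      if (seg$startBp[1] != 1 || seg$endBp[nrow(seg)] != object@chromLengths[[cc]])
        return(sprintf("segments of %s/%s do not tile the chromosome", ln, cc))
      if (nrow(seg) > 1) {
        if (any(seg$startBp[-1] != seg$endBp[-nrow(seg)] + 1))
          return(sprintf("segments of %s/%s overlap or leave gaps", ln, cc))
        if (any(seg$label[-1] == seg$label[-nrow(seg)]))
          return(sprintf("adjacent equal labels in %s/%s", ln, cc))
      }
    }
  }
  TRUE
})

#' BinMap: population-wide recombination bins and bin genotypes
#'
#' Bins are maximal runs of 100-kb grid intervals free of recombination
#' breakpoints across the whole population; each bin is inherited as a unit
#' and serves as one mapping marker.
#'
#' @slot bins GRanges of bin intervals (1-based closed, as GRanges
#'   convention) with mcols `binId`; internally bins are built on a 0-based
#'   half-open 100-kb grid.
#' @slot genotypes character matrix lines x bins in `{A, B, H, N}`,
#'   colnames = binId.
#' @slot grid numeric grid size in bp used for bin boundaries.
#' @exportClass BinMap
setClass("BinMap",
  representation(bins = "GRanges", genotypes = "matrix", grid = "numeric")
)

setValidity("BinMap", function(object) {
  msg <- character()
  if (length(object@bins) != ncol(object@genotypes))
    msg <- c(msg, "one genotype column per bin required")
  if (!all(object@genotypes %in% GENO_CODES))
    msg <- c(msg, "bin genotypes restricted to codes A, B, H, N")
  if (is.null(mcols(object@bins)$binId))
    msg <- c(msg, "bins need a binId metadata column")
  if (length(msg)) msg else TRUE
})

#' GeneticMap: Kosambi genetic map over ordered bin markers
#'
#' @slot table data.frame with one row per bin marker: `chrom`, `binId`,
#'   `bpStart`, `bpEnd` (1-based inclusive), `rAdj` (meiotic recombination
#'   fraction to the previous bin, NA for the first bin of a chromosome),
#'   `dcM` (adjacent Kosambi distance), `cumCM` (cumulative position from 0).
#' @slot summary data.frame with per-chromosome rows plus a `Total` row:
#'   `chrom`, `nMarkers`, `physicalMb`, `geneticCM`, `avgDistCM`, `maxGapCM`.
#' @exportClass GeneticMap
setClass("GeneticMap",
  representation(table = "data.frame", summary = "data.frame")
)

setValidity("GeneticMap", function(object) {
  tb <- object@table
  need <- c("chrom", "binId", "bpStart", "bpEnd", "rAdj", "dcM", "cumCM")
  if (!all(need %in% names(tb)))
    return(paste("table needs columns", paste(need, collapse = ", ")))
  r <- tb$rAdj[!is.na(tb$rAdj)]
  if (any(r < 0 | r >= 0.5)) return("rAdj must lie in [0, 0.5)")
  for (cc in unique(tb$chrom)) {
    if (is.unsorted(tb$cumCM[tb$chrom == cc]))
      return(sprintf("cumCM not non-decreasing on %s", cc))
  }
  TRUE
})
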