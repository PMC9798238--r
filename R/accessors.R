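## Accessors and show() methods for the S4 containers.

#' @rdname SNPCallMatrix-class
#' @param object,x a `SNPCallMatrix`
#' @export
setGeneric("genotypeCalls", function(object) standardGeneric("genotypeCalls"))

#' @rdname SNPCallMatrix-class
#' @export
setMethod("genotypeCalls", "SNPCallMatrix", function(object) object@calls)

#' @rdname BinMap-class
#' @export
setMethod("genotypeCalls", "BinMap", function(object) object@genotypes)

#' @rdname SNPCallMatrix-class
#' @export
setGeneric("markerInfo", function(object) standardGeneric("markerInfo"))

#' @rdname SNPCallMatrix-class
#' @export
setMethod("markerInfo", "SNPCallMatrix", function(object) object@markers)

#' @rdname SNPCallMatrix-class
#' @export
setGeneric("lineIds", function(object) standardGeneric("lineIds"))

#' @rdname SNPCallMatrix-class
#' @export
setMethod("lineIds", "SNPCallMatrix", function(object) rownames(object@calls))

#' @rdname BinMap-class
#' @export
setMethod("lineIds", "BinMap", function(object) rownames(object@genotypes))

#' @rdname TrueGenomeSet-class
#' @param object a `TrueGenomeSet`
#' @export
setMethod("lineIds", "TrueGenomeSet", function(object) names(object@segments))

#' @rdname BinMap-class
#' @param object,x a `BinMap`
#' @export
setGeneric("binRanges", function(object) standardGeneric("binRanges"))

#' @rdname BinMap-class
#' @export
setMethod("binRanges", "BinMap", function(object) object@bins)

#' @rdname GeneticMap-class
#' @param object a `GeneticMap`
#' @export
setGeneric("mapTable", function(object) standardGeneric("mapTable"))

#' @rdname GeneticMap-class
#' @export
setMethod("mapTable", "GeneticMap", function(object) object@table)

#' @rdname GeneticMap-class
#' @export
setGeneric("mapSummary", function(object) standardGeneric("mapSummary"))

#' @rdname GeneticMap-class
#' @export
setMethod("mapSummary", "GeneticMap", function(object) object@summary)

#' @rdname TrueGenomeSet-class
#' @export
setGeneric("trueSegments", function(object) standardGeneric("trueSegments"))

#' @rdname TrueGenomeSet-class
#' @export
setMethod("trueSegments", "TrueGenomeSet", function(object) object@segments)

#' Subset a SNPCallMatrix by lines (i) and/or markers (j)
#'
#' @param x a `SNPCallMatrix`
#' @param i line index (integer, logical or character)
#' @param j marker index (integer or logical)
#' @param ... ignored
#' @param drop ignored; result is always a `SNPCallMatrix`
#' @export
setMethod("[", "SNPCallMatrix", function(x, i, j, ..., drop = FALSE) {
  calls <- x@calls
  mk <- x@markers
  if (!missing(i)) calls <- calls[i, , drop = FALSE]
  if (!missing(j)) {
    calls <- calls[, j, drop = FALSE]
    mk <- mk[j, , drop = FALSE]
    rownames(mk) <- NULL
  }
  new("SNPCallMatrix", calls = calls, markers = mk)
})

setMethod("show", "GenomeTemplate", function(object) {
  ch <- object@chromosomes
  cat("GenomeTemplate with", nrow(ch), "chromosome(s)\n")
  cat(sprintf("  physical: %.1f Mb   genetic: %.2f cM   SNPs: %d\n",
    sum(ch$bpLength) / 1e6, sum(ch$cmLength),
    sum(lengths(object@snpPositions))))
})

setMethod("show", "SNPCallMatrix", function(object) {
  cat("SNPCallMatrix:", nrow(object@calls), "lines x",
    ncol(object@calls), "SNPs on",
    length(unique(object@markers$chrom)), "chromosome(s)\n")
  tb <- table(factor(object@calls, levels = GENO_CODES))
  frac <- round(100 * tb / sum(tb), 2)
  cat("  code frequencies (%):",
    paste(names(frac), frac, sep = "=", collapse = "  "), "\n")
})

setMethod("show", "TrueGenomeSet", function(object) {
  nbp <- vapply(object@segments, function(ln)
    sum(vapply(ln, nrow, 1L) - 1L), 1L)
  cat("TrueGenomeSet:", length(object@segments), "lines,",
    length(object@chromLengths), "chromosome(s)\n")
  cat(sprintf("  breakpoints per line: mean %.1f (range %d-%d)\n",
    mean(nbp), min(nbp), max(nbp)))
})

setMethod("show", "BinMap", function(object) {
  cat("BinMap:", nrow(object@genotypes), "lines x",
    ncol(object@genotypes), "bins (grid", object@grid / 1e3, "kb)\n")
  cat(sprintf("  median bin width: %.0f kb\n",
    stats::median(width(object@bins)) / 1e3))
})

setMethod("show", "GeneticMap", function(object) {
  tot <- object@summary[object@summary$chrom == "Total", ]
  cat("GeneticMap:", nrow(object@table), "bin markers,",
    sprintf("%.2f cM total, mean adjacent distance %.3f cM\n",
      tot$geneticCM, tot$avgDistCM))
})
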