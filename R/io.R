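## Readers and writers for the pipeline's on-disk formats. All files are
## plain text; a comment header names the producing stage and parameters.

stageHeader <- function(stage, params = list()) {
  ph <- if (length(params))
    paste(names(params), unlist(params), sep = "=", collapse = " ")
  else "none"
  sprintf("# binQTL stage=%s params[%s]", stage, ph)
}

#' Write parental-origin SNP calls as VCF
#'
#' Lines become samples; codes map to GT as `A -> 0/0`, `B -> 1/1`,
#' `H -> 0/1`, `N -> ./.`; REF/ALT are placeholders `A`/`B` (parental
#' origin, not nucleotides).
#'
#' @param scm a [SNPCallMatrix-class].
#' @param file output path.
#' @export
writeSNPVcf <- function(scm, file) {
  mk <- scm@markers
  calls <- scm@calls
  gt <- matrix(".(/.)", nrow(calls), ncol(calls))
  gt[] <- c(A = "0/0", B = "1/1", H = "0/1", N = "./.")[calls]
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
    "##source=binQTL parental-origin encoding (REF=parent1 allele class, ALT=parent2)",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", rownames(calls)), collapse = "\t")), con)
  body <- cbind(mk$chrom, mk$pos, colnames(calls), "A", "B", ".", ".", ".",
    "GT", t(gt))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(file)
}

#' Read a GT-based VCF into a SNPCallMatrix
#'
#' Homozygous-reference genotypes become `A`, homozygous-alternate `B`,
#' heterozygous `H`, anything else `N`. Requires the vcfR package.
#'
#' @param file VCF path.
#' @return a [SNPCallMatrix-class].
#' @export
readSNPVcf <- function(file) {
  stopIfNot(requireNamespace("vcfR", quietly = TRUE),
    "reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- matrix("N", nrow(gt), ncol(gt), dimnames = dimnames(gt))
  code[gt %in% c("0/0")] <- "A"
  code[gt %in% c("1/1")] <- "B"
  code[gt %in% c("0/1", "1/0")] <- "H"
  mk <- data.frame(chrom = as.character(v@fix[, "CHROM"]),
    pos = as.numeric(v@fix[, "POS"]), stringsAsFactors = FALSE)
  ord <- order(naturalChromOrder(mk$chrom), mk$pos)
  calls <- t(code)[, ord, drop = FALSE]
  mk <- mk[ord, , drop = FALSE]
  rownames(mk) <- NULL
  colnames(calls) <- sprintf("%s_%d", mk$chrom, mk$pos)
  new("SNPCallMatrix", calls = calls, markers = mk)
}

#' Write/read the tab-separated genotype matrix
#'
#' Columns `chrom`, `pos`, then one column of `A/B/H/N` codes per line.
#'
#' @param scm a [SNPCallMatrix-class].
#' @param file path.
#' @param stage stage label for the header comment.
#' @export
writeSNPTable <- function(scm, file, stage = "genotypes") {
  df <- data.frame(scm@markers, t(scm@calls), check.names = FALSE)
  writeLines(stageHeader(stage), file)
  suppressWarnings(data.table::fwrite(df, file, sep = "\t", append = TRUE,
    col.names = TRUE))
  invisible(file)
}

#' @rdname writeSNPTable
#' @export
readSNPTable <- function(file) {
  df <- data.table::fread(file, sep = "\t", skip = "chrom")
  mk <- data.frame(chrom = as.character(df$chrom), pos = as.numeric(df$pos),
    stringsAsFactors = FALSE)
  calls <- t(as.matrix(df[, -(1:2)]))
  colnames(calls) <- sprintf("%s_%d", mk$chrom, mk$pos)
  new("SNPCallMatrix", calls = calls, markers = mk)
}

#' Write bins as BED and the bin genotype matrix as CSV
#'
#' BED uses the 0-based half-open convention of the internal grid.
#'
#' @param binMap a [BinMap-class].
#' @param bedFile,genoFile output paths (either may be NULL to skip).
#' @export
writeBinMap <- function(binMap, bedFile = NULL, genoFile = NULL) {
  gr <- binMap@bins
  if (!is.null(bedFile)) {
    bed <- data.frame(chrom = as.character(seqnames(gr)),
      start = start(gr) - 1L, end = end(gr), name = mcols(gr)$binId)
    writeLines(stageHeader("binmap", list(grid = binMap@grid)), bedFile)
    suppressWarnings(data.table::fwrite(bed, bedFile, sep = "\t",
      append = TRUE, col.names = FALSE))
  }
  if (!is.null(genoFile)) {
    df <- data.frame(line = rownames(binMap@genotypes), binMap@genotypes,
      check.names = FALSE)
    writeLines(stageHeader("binmap", list(grid = binMap@grid)), genoFile)
    suppressWarnings(data.table::fwrite(df, genoFile, append = TRUE,
      col.names = TRUE))
  }
  invisible(binMap)
}

#' Write a data.frame stage artifact as CSV with a stage header
#'
#' @param df data.frame.
#' @param file path.
#' @param stage stage name.
#' @param params named list recorded in the header.
#' @export
writeStageCsv <- function(df, file, stage, params = list()) {
  writeLines(stageHeader(stage, params), file)
  suppressWarnings(data.table::fwrite(df, file, append = TRUE,
    col.names = TRUE))
  invisible(file)
}

#' Read a stage CSV written by [writeStageCsv()]
#'
#' @param file path.
#' @return data.frame.
#' @export
readStageCsv <- function(file) {
  as.data.frame(data.table::fread(file, skip = 1L))
}
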