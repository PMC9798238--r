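#' Default pipeline configuration
#'
#' Nested list of stage parameters with the workflow defaults: a
#' maize-scale genome, 275 RILs, six selfing generations, 1% genotype
#' error and 5% missingness, 15/11 window smoothing on a 100-kb grid, the
#' heritability-0.81 trait preset over three environments, and a
#' 1000-permutation CIM scan at alpha 0.05 merged across environments at
#' 20 Mb.
#'
#' @param seed global seed; per-stage substreams are derived from it.
#' @return named list of class `PipelineConfig`.
#' @export
defaultPipelineConfig <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    traitPrefix = "PC",
    simulate = list(nChrom = 10L, nSnpsPerChrom = 300L, nLines = 275L,
      selfingGenerations = 6L, errorRate = 0.01, missingRate = 0.05,
      envPreset = "paper", targetH2 = 0.81),
    qc = list(alpha = 0.001, minSnpRate = 0.2, minLineRate = 0.2),
    binmap = list(window = 15L, step = 1L, majority = 11L, grid = 1e5),
    scan = list(nCofactors = 5L, exclusionWindow = 10, nPerm = 1000L,
      alpha = 0.05, drop = 1.5, gridStep = 1),
    merge = list(maxPeakGapMb = 20)),
    class = "PipelineConfig")
}

#' Validate, read and write pipeline configurations
#'
#' Configurations round-trip through YAML; unknown keys are rejected.
#'
#' @param config a configuration list.
#' @param file YAML path.
#' @return `validatePipelineConfig()` returns the completed configuration
#'   (defaults filled in); the IO helpers return the config/file.
#' @export
validatePipelineConfig <- function(config) {
  ref <- unclass(defaultPipelineConfig())
  checkKeys <- function(x, refx, path = "") {
    extra <- setdiff(names(x), names(refx))
    stopIfNot(length(extra) == 0, "unknown configuration key(s): %s",
      paste0(path, extra, collapse = ", "))
    for (nm in names(x)) {
      if (is.list(refx[[nm]]))
        checkKeys(x[[nm]], refx[[nm]], paste0(path, nm, "."))
    }
  }
  checkKeys(unclass(config), ref)
  out <- modifyList(ref, unclass(config))
  structure(out, class = "PipelineConfig")
}

#' @rdname validatePipelineConfig
#' @export
readPipelineConfig <- function(file) {
  validatePipelineConfig(yaml::read_yaml(file))
}

#' @rdname validatePipelineConfig
#' @export
writePipelineConfig <- function(config, file) {
  yaml::write_yaml(unclass(validatePipelineConfig(config)), file)
  invisible(file)
}

#' Run the full pipeline: simulate, qc, binmap, map, blue, scan, merge
#'
#' Executes the stage sequence with per-stage artifacts written under
#' `outDir` and returns a manifest of parameters, seeds, stage
#' input/output counts and artifact checksums. Re-running with the same
#' configuration reproduces the artifacts byte for byte.
#'
#' @param config a pipeline configuration (see
#'   [defaultPipelineConfig()]); validated before use.
#' @param outDir output directory (created if needed).
#' @param quiet suppress per-stage log lines.
#' @return invisible list with the stage objects (`template`, `pop`,
#'   `pheno`, `qc`, `binMap`, `map`, `fit`, `scans`, `consensus`,
#'   `report`) and `manifest`.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outDir = tempfile("binqtl_"),
                        quiet = FALSE) {
  config <- validatePipelineConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  log <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  manifest <- list(package = "binQTL",
    version = as.character(utils::packageVersion("binQTL")),
    config = unclass(config), stages = list())

  ## --- simulate ---
  sc <- config$simulate
  template <- maizeGenomeTemplate(sc$nSnpsPerChrom, seed = deriveSeed(seed, 1))
  if (sc$nChrom < 10) {
    keep <- paste0("chr", seq_len(sc$nChrom))
    template <- buildGenomeTemplate(sc$nChrom,
      template@chromosomes$bpLength[seq_len(sc$nChrom)],
      template@chromosomes$cmLength[seq_len(sc$nChrom)],
      sc$nSnpsPerChrom, seed = deriveSeed(seed, 1), chromNames = keep)
  }
  pop <- simulateRILPopulation(template, sc$nLines, sc$selfingGenerations,
    seed = deriveSeed(seed, 2))
  arch <- paperTraitArchitecture(sc$targetH2, sc$selfingGenerations)
  if (identical(sc$envPreset, "paper"))
    arch$envDesign <- paperEnvironments()
  arch$qtl <- arch$qtl[arch$qtl$chrom %in% template@chromosomes$name, ,
    drop = FALSE]
  pheno <- simulatePhenotypes(pop$truth, arch, seed = deriveSeed(seed, 3))
  observed <- corruptGenotypes(pop$calls, sc$errorRate, sc$missingRate,
    seed = deriveSeed(seed, 4))
  writeSNPTable(observed, file.path(outDir, "genotypes.tsv"), "simulate")
  writeStageCsv(pheno, file.path(outDir, "phenotypes.csv"), "simulate")
  writeStageCsv(trueBreakpoints(pop$truth),
    file.path(outDir, "truth_breakpoints.csv"), "simulate")
  log("simulate", "%d lines, %d SNPs, %d phenotype records",
    nrow(observed@calls), ncol(observed@calls), nrow(pheno))

  ## --- qc ---
  qc <- runGenotypeQC(observed, config$qc$alpha, config$qc$minSnpRate,
    config$qc$minLineRate)
  writeStageCsv(qc$report, file.path(outDir, "qc_report.csv"), "qc",
    config$qc)
  log("qc", "SNPs %d -> %d, lines %d -> %d", ncol(observed@calls),
    ncol(qc$calls@calls), nrow(observed@calls), nrow(qc$calls@calls))

  ## --- binmap ---
  bm <- config$binmap
  chromLengths <- setNames(template@chromosomes$bpLength,
    template@chromosomes$name)
  bc <- callBinMap(qc$calls, chromLengths, bm$window, bm$step, bm$majority,
    bm$grid)
  writeBinMap(bc$binMap, file.path(outDir, "bins.bed"),
    file.path(outDir, "bin_genotypes.csv"))
  log("binmap", "%d bins, %d breakpoints (%.1f per line)",
    ncol(bc$binMap@genotypes), bc$summary$total, bc$summary$meanPerLine)

  ## --- genetic map ---
  map <- buildGeneticMap(bc$binMap)
  writeStageCsv(map@table, file.path(outDir, "genetic_map.csv"), "geneticmap")
  writeStageCsv(map@summary, file.path(outDir, "map_summary.csv"),
    "geneticmap")
  tot <- map@summary[map@summary$chrom == "Total", ]
  log("geneticmap", "%.1f cM over %d markers", tot$geneticCM, tot$nMarkers)

  ## --- blue ---
  fit <- fitMixedModel(pheno)
  writeStageCsv(fit$blue, file.path(outDir, "blue.csv"), "blue")
  writeStageCsv(data.frame(component = names(fit$vc),
    variance = unlist(fit$vc)), file.path(outDir, "variance_components.csv"),
    "blue")
  log("blue", "%d lines, H2 = %.3f", nrow(fit$blue), fit$H2)

  ## --- scan per environment + BLUE ---
  sp <- config$scan
  binMap <- attr(map, "binMap")
  probs <- genotypeProbs(map, binMap, sp$gridStep)
  phenoSets <- c(
    setNames(lapply(unique(pheno$env), function(e) {
      v <- tapply(pheno$value[pheno$env == e], pheno$line[pheno$env == e],
        mean)
      setNames(as.numeric(v), names(v))
    }), unique(pheno$env)),
    list(BLUE = setNames(fit$blue$blue, fit$blue$line)))
  scans <- list()
  for (k in seq_along(phenoSets)) {
    env <- names(phenoSets)[k]
    scans[[env]] <- scanQTL(map, binMap, phenoSets[[k]], env = env,
      nCofactors = sp$nCofactors, exclusionWindow = sp$exclusionWindow,
      nPerm = sp$nPerm, alpha = sp$alpha, drop = sp$drop,
      seed = deriveSeed(seed, 10 + k), gridStep = sp$gridStep,
      probs = probs)
    prof <- scans[[env]]$profile
    writeStageCsv(cbind(prof$positions, lod = prof$lod[, 1]),
      file.path(outDir, sprintf("lod_%s.tsv", env)), "scan",
      list(env = env, threshold = round(scans[[env]]$threshold, 3)))
    log("scan", "%s: threshold %.2f, %d QTL(s)", env,
      scans[[env]]$threshold, nrow(scans[[env]]$qtl))
  }

  ## --- merge ---
  allQtl <- do.call(rbind, c(lapply(scans, `[[`, "qtl"),
    make.row.names = FALSE))
  consensus <- mergeAcrossEnvs(allQtl, config$merge$maxPeakGapMb,
    config$traitPrefix)
  report <- reportTable(consensus)
  writeStageCsv(consensus, file.path(outDir, "qtl_consensus.csv"), "merge",
    config$merge)
  writeStageCsv(report, file.path(outDir, "qtl_report.csv"), "merge",
    config$merge)
  log("merge", "%d records in %d consensus loci", nrow(consensus),
    length(unique(consensus$name)))

  files <- list.files(outDir, full.names = TRUE)
  manifest$stages <- list(
    simulate = list(lines = nrow(observed@calls), snps = ncol(observed@calls)),
    qc = list(snps = ncol(qc$calls@calls), lines = nrow(qc$calls@calls)),
    binmap = list(bins = ncol(bc$binMap@genotypes),
      breakpoints = bc$summary$total),
    geneticmap = list(cM = tot$geneticCM),
    blue = list(H2 = fit$H2),
    scan = lapply(scans, function(s)
      list(threshold = s$threshold, nQtl = nrow(s$qtl))),
    merge = list(nConsensus = length(unique(consensus$name))))
  manifest$checksums <- as.list(tools::md5sum(files))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(template = template, pop = pop, pheno = pheno, qc = qc,
    binMap = bc$binMap, smoothed = bc$smoothed, map = map, fit = fit,
    scans = scans, consensus = consensus, report = report,
    manifest = manifest, outDir = outDir))
}
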