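#' Define a trait architecture for phenotype simulation
#'
#' The trait is controlled by additive QTLs (genotype score +1 for the
#' parent-1 homozygote, 0 for heterozygotes, -1 for the parent-2
#' homozygote) plus independent normal deviations for polygenic background,
#' genotype-by-year, genotype-by-location, genotype-by-year-by-location and
#' residual error, in a years x locations x replicates design.
#'
#' @param qtl data.frame with columns `chrom`, `posBp`, `effect` (additive
#'   effect per substituted allele, trait units); may have zero rows.
#' @param sigmaG2 polygenic (non-QTL) genetic variance.
#' @param sigmaGY2,sigmaGL2,sigmaGLY2 interaction variances (genotype x
#'   year, x location, x year-x-location).
#' @param sigmaE2 residual (plot error) variance.
#' @param years,locations,reps design counts (all >= 1).
#' @param sigmaEnv2 environment (year-location cell) main-effect variance.
#' @param sigmaRep2 replicate-within-environment variance.
#' @param intercept trait grand mean (default 11, a typical maize kernel
#'   protein content in %).
#' @param envDesign optional data.frame (`env`, `year`, `location`, `reps`)
#'   overriding the balanced years x locations layout, e.g. the unbalanced
#'   three-environment layout of a two-year/two-location trial with one
#'   empty cell (see [paperEnvironments()]).
#' @return a list of class `TraitArchitecture`.
#' @export
traitArchitecture <- function(qtl = data.frame(chrom = character(),
                                posBp = numeric(), effect = numeric()),
                              sigmaG2 = 0, sigmaGY2 = 0, sigmaGL2 = 0,
                              sigmaGLY2 = 0, sigmaE2 = 0,
                              years = 2L, locations = 2L, reps = 3L,
                              sigmaEnv2 = 0.5, sigmaRep2 = 0.05,
                              intercept = 11, envDesign = NULL) {
  vars <- c(sigmaG2, sigmaGY2, sigmaGL2, sigmaGLY2, sigmaE2, sigmaEnv2, sigmaRep2)
  stopIfNot(all(vars >= 0), "variance components must be >= 0")
  stopIfNot(years >= 1 && locations >= 1 && reps >= 1, "design counts must be >= 1")
  if (is.null(envDesign)) {
    envDesign <- expand.grid(year = paste0("Y", seq_len(years)),
      location = paste0("L", seq_len(locations)), stringsAsFactors = FALSE)
    envDesign$env <- paste0(envDesign$location, envDesign$year)
    envDesign$reps <- reps
  } else {
    stopIfNot(all(c("env", "year", "location", "reps") %in% names(envDesign)),
      "envDesign needs columns env, year, location, reps")
  }
  structure(list(qtl = qtl, sigmaG2 = sigmaG2, sigmaGY2 = sigmaGY2,
    sigmaGL2 = sigmaGL2, sigmaGLY2 = sigmaGLY2, sigmaE2 = sigmaE2,
    years = years, locations = locations, reps = reps,
    sigmaEnv2 = sigmaEnv2, sigmaRep2 = sigmaRep2,
    intercept = intercept, envDesign = envDesign),
    class = "TraitArchitecture")
}

#' Unbalanced three-environment trial layout
#'
#' Two years at one location plus one year at a second location, three
#' replicates each — the layout of the maize RIL protein-content trial
#' (Gongzhuling 2018/2019 plus Harbin).
#'
#' @param reps replicates per environment (default 3).
#' @return data.frame usable as `envDesign` in [traitArchitecture()].
#' @export
paperEnvironments <- function(reps = 3L) {
  data.frame(
    env = c("2018GZL", "2019GZL", "2018HEB"),
    year = c("2018", "2019", "2018"),
    location = c("GZL", "GZL", "HEB"),
    reps = reps, stringsAsFactors = FALSE)
}

#' Expected broad-sense heritability implied by a trait architecture
#'
#' Uses the entry-mean formula with total genotypic variance = polygenic
#' variance + expected QTL variance. For a RIL population after `g` selfing
#' generations each biallelic QTL contributes `(1 - 2^-g) * a^2` (the
#' residual heterozygote fraction scores 0).
#'
#' @param arch a [traitArchitecture()] object.
#' @param selfingGenerations selfing generations of the target population.
#' @return expected H-squared.
#' @export
expectedArchitectureH2 <- function(arch, selfingGenerations = 6L) {
  qtlVar <- (1 - 2^-selfingGenerations) * sum(arch$qtl$effect^2)
  vc <- list(sigmaG2 = arch$sigmaG2 + qtlVar, sigmaGY2 = arch$sigmaGY2,
    sigmaGL2 = arch$sigmaGL2, sigmaGLY2 = arch$sigmaGLY2,
    sigmaE2 = arch$sigmaE2)
  heritability(vc, Y = arch$years, L = arch$locations, R = arch$reps)
}

#' Trait architecture preset tuned to a target heritability
#'
#' Five additive protein-content QTLs of moderate effect; interaction
#' variances fixed at plausible field-trial magnitudes; the residual
#' variance is solved analytically so that [expectedArchitectureH2()]
#' equals `targetH2` (default 0.81) under the balanced 2-year x 2-location
#' x 3-replicate design.
#'
#' @param targetH2 target entry-mean heritability.
#' @param selfingGenerations selfing generations of the target population.
#' @return a `TraitArchitecture`.
#' @export
paperTraitArchitecture <- function(targetH2 = 0.81, selfingGenerations = 6L) {
  qtl <- data.frame(
    chrom = c("chr2", "chr7", "chr9", "chr3", "chr5"),
    posBp = c(17e6, 130e6, 78e6, 196e6, 94e6),
    effect = c(0.40, -0.35, -0.30, 0.30, 0.25), stringsAsFactors = FALSE)
  sigmaGY2 <- 0.05; sigmaGL2 <- 0.05; sigmaGLY2 <- 0.10
  Y <- 2L; L <- 2L; R <- 3L
  sigmaG2 <- (1 - 2^-selfingGenerations) * sum(qtl$effect^2)
  denom <- sigmaG2 / targetH2
  sigmaE2 <- (denom - sigmaG2 - sigmaGY2 / Y - sigmaGL2 / L -
    sigmaGLY2 / (L * Y)) * (L * Y * R)
  stopIfNot(sigmaE2 >= 0, "targetH2 unattainable with the preset components")
  traitArchitecture(qtl = qtl, sigmaG2 = 0, sigmaGY2 = sigmaGY2,
    sigmaGL2 = sigmaGL2, sigmaGLY2 = sigmaGLY2, sigmaE2 = sigmaE2,
    years = Y, locations = L, reps = R)
}

#' Simulate multi-environment replicated phenotypes
#'
#' Genetic value of a line = sum of QTL effects times the line's genotype
#' score (+1 A / 0 H / -1 B at each QTL) plus a polygenic normal deviate.
#' Environment, replicate-within-environment, GxY, GxL, GxYxL and residual
#' deviations are independent normals with the architecture's variances.
#'
#' @param truth a [TrueGenomeSet-class] from [simulateRILPopulation()].
#' @param arch a [traitArchitecture()].
#' @param seed integer seed.
#' @return data.frame with one row per line x environment x replicate:
#'   columns `line`, `env`, `year`, `location`, `rep`, `value`.
#' @export
simulatePhenotypes <- function(truth, arch, seed = 1L) {
  lines <- names(truth@segments)
  n <- length(lines)
  ed <- arch$envDesign
  ## genotype scores at the QTLs
  gval <- numeric(n)
  if (nrow(arch$qtl)) {
    for (q in seq_len(nrow(arch$qtl))) {
      cc <- arch$qtl$chrom[q]
      stopIfNot(cc %in% names(truth@chromLengths) &&
        arch$qtl$posBp[q] >= 1 && arch$qtl$posBp[q] <= truth@chromLengths[[cc]],
        "QTL %d lies off the simulated chromosomes", q)
      lab <- truthGenotypeAt(truth, cc, arch$qtl$posBp[q])[, 1]
      gval <- gval + arch$qtl$effect[q] * codeToNumeric(lab)
    }
  }
  withSeed(seed, {
    gval <- gval + rnorm(n, 0, sqrt(arch$sigmaG2))
    years <- unique(ed$year); locs <- unique(ed$location)
    envEff <- setNames(rnorm(nrow(ed), 0, sqrt(arch$sigmaEnv2)), ed$env)
    gy <- matrix(rnorm(n * length(years), 0, sqrt(arch$sigmaGY2)), n,
      dimnames = list(lines, years))
    gl <- matrix(rnorm(n * length(locs), 0, sqrt(arch$sigmaGL2)), n,
      dimnames = list(lines, locs))
    gly <- matrix(rnorm(n * nrow(ed), 0, sqrt(arch$sigmaGLY2)), n,
      dimnames = list(lines, ed$env))
    rows <- list()
    for (e in seq_len(nrow(ed))) {
      repEff <- rnorm(ed$reps[e], 0, sqrt(arch$sigmaRep2))
      for (r in seq_len(ed$reps[e])) {
        rows[[length(rows) + 1L]] <- data.frame(
          line = lines, env = ed$env[e], year = ed$year[e],
          location = ed$location[e], rep = paste0("rep", r),
          value = arch$intercept + gval + envEff[e] + repEff[r] +
            gy[, ed$year[e]] + gl[, ed$location[e]] + gly[, ed$env[e]] +
            rnorm(n, 0, sqrt(arch$sigmaE2)),
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
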