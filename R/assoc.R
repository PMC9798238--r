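#' Marker-group phenotype difference test
#'
#' Two-sided Welch (unequal-variance) t-test of trait BLUEs between two
#' marker genotype classes (e.g. the two parental haplotypes of a
#' diagnostic indel marker scored in an inbred panel).
#'
#' @param values numeric trait values (BLUEs).
#' @param groups factor/character of genotype class labels (exactly two
#'   classes, each with >= 2 observations).
#' @return list with `difference` (mean of first class minus mean of
#'   second, classes in label sort order), `p`, `statistic`, `df`,
#'   `groupMeans`.
#' @export
markerGroupTest <- function(values, groups) {
  groups <- as.character(groups)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- groups[ok]
  lv <- sort(unique(groups))
  stopIfNot(length(lv) == 2, "exactly two genotype classes required")
  n1 <- sum(groups == lv[1]); n2 <- sum(groups == lv[2])
  stopIfNot(n1 >= 2 && n2 >= 2, "each class needs >= 2 observations")
  tt <- t.test(values[groups == lv[1]], values[groups == lv[2]],
    var.equal = FALSE)
  means <- setNames(c(mean(values[groups == lv[1]]),
    mean(values[groups == lv[2]])), lv)
  list(difference = unname(means[1] - means[2]), p = tt$p.value,
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    groupMeans = means)
}

#' Expression-trait correlation
#'
#' Pearson correlation between per-line normalized expression and trait
#' BLUEs (pairwise complete), with the two-sided p-value from the t
#' transform. For an expression matrix, one test per gene with
#' Benjamini-Hochberg adjusted p-values alongside the raw ones.
#'
#' @param expression numeric vector (one gene) or matrix genes x lines.
#' @param trait numeric vector of per-line BLUEs, aligned by name when
#'   both carry names.
#' @return for a vector: list with `r`, `p`, `n`; for a matrix: data.frame
#'   with `gene`, `r`, `p`, `padj`.
#' @export
exprTraitCorrelation <- function(expression, trait) {
  one <- function(x, y) {
    if (!is.null(names(x)) && !is.null(names(y))) {
      common <- intersect(names(x), names(y))
      x <- x[common]; y <- y[common]
    }
    ok <- complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    stopIfNot(length(x) >= 3, "need >= 3 paired observations")
    if (sd(x) == 0 || sd(y) == 0) {
      warning("zero variance; correlation undefined")
      return(list(r = NA_real_, p = NA_real_, n = length(x)))
    }
    ct <- cor.test(x, y, method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
  }
  if (is.matrix(expression)) {
    res <- lapply(rownames(expression), function(g) {
      x <- expression[g, ]
      names(x) <- colnames(expression)
      one(x, trait)
    })
    out <- data.frame(gene = rownames(expression),
      r = vapply(res, `[[`, 1, "r"), p = vapply(res, `[[`, 1, "p"),
      stringsAsFactors = FALSE)
    out$padj <- p.adjust(out$p, method = "BH")
    out
  } else one(expression, trait)
}

#' Relative expression by the 2^-ddCq method
#'
#' `fold = 2^-[(Cq_target,sample - Cq_ref,sample) -
#' (Cq_target,calibrator - Cq_ref,calibrator)]`. Replicate Cq values are
#' averaged; the fold-change standard error is propagated from the
#' replicate standard errors by the delta method.
#'
#' @param cqTargetSample,cqRefSample,cqTargetCalibrator,cqRefCalibrator
#'   numeric vectors of replicate Cq values (target/reference gene in the
#'   sample/calibrator condition).
#' @return list with `fold`, `ddCq`, `se` (fold-change scale; NA with
#'   single replicates).
#' @examples
#' ddcqRelativeExpression(20, 18, 22, 18)   # ddCq = -2, fold = 4
#' @export
ddcqRelativeExpression <- function(cqTargetSample, cqRefSample,
                                   cqTargetCalibrator, cqRefCalibrator) {
  vals <- list(cqTargetSample, cqRefSample, cqTargetCalibrator,
    cqRefCalibrator)
  stopIfNot(all(vapply(vals, function(v) all(is.finite(v)), TRUE)),
    "Cq values must be finite")
  m <- vapply(vals, mean, 1)
  ddCq <- (m[1] - m[2]) - (m[3] - m[4])
  fold <- 2^(-ddCq)
  sem2 <- vapply(vals, function(v)
    if (length(v) > 1) var(v) / length(v) else NA_real_, 1)
  se <- if (all(!is.na(sem2))) fold * log(2) * sqrt(sum(sem2)) else NA_real_
  list(fold = unname(fold), ddCq = unname(ddCq), se = unname(se))
}
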