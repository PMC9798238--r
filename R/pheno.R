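#' Fit the multi-environment mixed model: BLUEs and variance components
#'
#' Two REML fits of the trial data `value ~ line + env + rep`:
#'
#' 1. **BLUE fit** — line as a fixed effect (cell-means coding) with random
#'    environment, replicate-within-environment and line-by-environment
#'    terms: per-line adjusted means (best linear unbiased estimates).
#' 2. **Variance-component fit** — line as a random effect. When `year`
#'    and `location` columns are present the genotype-by-environment
#'    variance is decomposed into genotype-by-year, genotype-by-location
#'    and genotype-by-year-by-location components; otherwise a single
#'    genotype-by-environment component is estimated and reported as the
#'    GxY term (with `L = 1`).
#'
#' Random terms with fewer than two levels are dropped (with a message);
#' with no random term left the BLUE fit degenerates to ordinary least
#' squares. Replicates are treated as nested within environment.
#'
#' @param records data.frame with columns `line`, `env`, `rep`, `value` and
#'   optionally `year`, `location`. No duplicate (line, env, rep) keys.
#' @param fitBlues fit the fixed-line BLUE model (default TRUE). FALSE
#'   skips it — with hundreds of lines the fixed-effect fit dominates the
#'   runtime — and returns `blue = NULL` (variance components only).
#' @param polish re-optimize the variance-component REML criterion with a
#'   stringent Nelder-Mead pass (default TRUE; ~1e-8 agreement with the
#'   balanced-design ANOVA identity). FALSE keeps lme4's optimum (~1e-5
#'   relative), which is ample for simulation studies and much faster.
#' @return list with `blue` (data.frame `line`, `blue`, `se`), `vc` (list
#'   `sigmaG2`, `sigmaGY2`, `sigmaGL2`, `sigmaGLY2`, `sigmaE2`), `design`
#'   (list `Y`, `L`, `R`), `H2` (plug-in broad-sense heritability) and the
#'   two fitted model objects.
#' @export
fitMixedModel <- function(records, fitBlues = TRUE, polish = TRUE) {
  need <- c("line", "env", "rep", "value")
  stopIfNot(all(need %in% names(records)), "records need columns line, env, rep, value")
  stopIfNot(!anyDuplicated(records[, c("line", "env", "rep")]),
    "duplicate (line, env, rep) keys")
  stopIfNot(all(is.finite(records$value)), "trait values must be finite")
  stopIfNot(length(unique(records$line)) >= 2, "need at least 2 lines")
  d <- records
  d$line <- factor(d$line)
  d$env <- factor(d$env)
  d$repIn <- factor(paste(d$env, d$rep, sep = ":"))  # rep nested in env
  hasYL <- all(c("year", "location") %in% names(d))
  nEnv <- nlevels(d$env)

  ## ---- BLUE fit: line fixed ----
  blue <- NULL; blueFit <- NULL
  if (fitBlues) {
  ranTerms <- c(
    if (nEnv >= 2) "(1 | env)",
    if (nlevels(d$repIn) > nEnv) "(1 | repIn)",
    if (nEnv >= 2 && any(table(d$line, d$env) > 1)) "(1 | line:env)")
  if (length(ranTerms)) {
    fml <- as.formula(paste("value ~ 0 + line +", paste(ranTerms, collapse = " + ")))
    blueFit <- lme4::lmer(fml, data = d, REML = TRUE,
      control = lme4::lmerControl(calc.derivs = FALSE,
        check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4)))
    est <- lme4::fixef(blueFit)
    se <- sqrt(diag(as.matrix(stats::vcov(blueFit))))
  } else {
    message("no random term with >= 2 levels; BLUEs from ordinary least squares")
    blueFit <- lm(value ~ 0 + line, data = d)
    est <- coef(blueFit)
    se <- sqrt(diag(stats::vcov(blueFit)))
  }
  blue <- data.frame(line = sub("^line", "", names(est)), blue = unname(est),
    se = unname(se), stringsAsFactors = FALSE)
  }

  ## ---- variance-component fit: line random ----
  if (hasYL) {
    d$year <- factor(d$year); d$location <- factor(d$location)
    Y <- nlevels(d$year); L <- nlevels(d$location)
  } else {
    Y <- nEnv; L <- 1L
  }
  R <- max(table(d$line, d$env))
  vcTerms <- c("(1 | line)",
    if (nEnv >= 2) "(1 | env)",
    if (nlevels(d$repIn) > nEnv) "(1 | repIn)")
  gxe <- character(0)
  if (hasYL && Y >= 2 && L >= 2) {
    gxe <- c("(1 | line:year)", "(1 | line:location)", "(1 | line:year:location)")
  } else if (nEnv >= 2) {
    gxe <- "(1 | line:env)"
  } else {
    message("single environment: genotype-by-environment components fixed at 0")
  }
  if (nrow(d) <= nlevels(d$line)) {
    message("no replication: variance components not estimable")
    vc <- list(sigmaG2 = NA_real_, sigmaGY2 = NA_real_, sigmaGL2 = NA_real_,
      sigmaGLY2 = NA_real_, sigmaE2 = NA_real_)
    return(list(blue = blue, vc = vc, design = list(Y = Y, L = L, R = R),
      H2 = NA_real_, blueFit = blueFit, vcFit = NULL))
  }
  fmlVc <- as.formula(paste("value ~ 1 +", paste(c(vcTerms, gxe), collapse = " + ")))
  vcFit <- lme4::lmer(fmlVc, data = d, REML = TRUE,
    control = lme4::lmerControl(calc.derivs = FALSE,
      check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4)))
  ## lme4's default stopping rule leaves ~1e-5 relative error in the
  ## components; the tight Nelder-Mead pass brings the balanced-design
  ## ANOVA identity to ~1e-8
  if (polish) vcFit <- polishREML(vcFit, fmlVc, d)
  vcdf <- as.data.frame(lme4::VarCorr(vcFit))
  getVar <- function(grp) {
    v <- vcdf$vcov[vcdf$grp == grp]
    if (length(v)) v[1] else 0
  }
  vc <- list(
    sigmaG2 = getVar("line"),
    sigmaGY2 = if (hasYL && Y >= 2 && L >= 2) getVar("line:year") else getVar("line:env"),
    sigmaGL2 = getVar("line:location"),
    sigmaGLY2 = getVar("line:year:location"),
    sigmaE2 = vcdf$vcov[vcdf$grp == "Residual"][1])
  design <- list(Y = Y, L = L, R = R)
  H2 <- if (sum(unlist(vc)) > 0)
    heritability(vc, Y = Y, L = L, R = R) else NA_real_
  list(blue = blue, vc = vc, design = design, H2 = H2,
    blueFit = blueFit, vcFit = vcFit)
}

## Re-optimize a fitted lmer model's REML criterion from its own optimum
## with a stringent Nelder-Mead, via lme4's modular interface.
polishREML <- function(fit, fml, data) {
  parsed <- lme4::lFormula(fml, data = data, REML = TRUE,
    control = lme4::lmerControl(calc.derivs = FALSE,
      check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4)))
  devf <- do.call(lme4::mkLmerDevfun, parsed)
  start <- lme4::getME(fit, "theta")
  opt <- stats::optim(start, devf, method = "Nelder-Mead",
    control = list(reltol = 1e-15, maxit = 5e4, warn.1d.NelderMead = FALSE))
  opt$fval <- opt$value
  opt$conv <- opt$convergence
  lme4::mkMerMod(environment(devf), opt, parsed$reTrms, fr = parsed$fr)
}

#' Broad-sense heritability on an entry-mean basis
#'
#' `H2 = sigmaG2 / (sigmaG2 + sigmaGY2/Y + sigmaGL2/L + sigmaGLY2/(L*Y) +
#' sigmaE2/(L*Y*R))` for a trial with `Y` years, `L` locations and `R`
#' replicates per location.
#'
#' @param vc list (or [fitMixedModel()] `vc` element) with `sigmaG2`,
#'   `sigmaGY2`, `sigmaGL2`, `sigmaGLY2`, `sigmaE2` (missing elements
#'   count as 0).
#' @param Y,L,R design counts (all >= 1).
#' @return numeric H-squared in `[0, 1]`.
#' @examples
#' heritability(list(sigmaG2 = 0.5, sigmaGY2 = 0.1, sigmaGL2 = 0.1,
#'   sigmaGLY2 = 0.2, sigmaE2 = 0.15), Y = 2, L = 2, R = 3)  # 0.7547
#' @export
heritability <- function(vc, Y, L, R) {
  stopIfNot(Y >= 1 && L >= 1 && R >= 1, "design counts must be >= 1")
  g <- function(nm) if (!is.null(vc[[nm]])) vc[[nm]] else 0
  num <- g("sigmaG2")
  den <- num + g("sigmaGY2") / Y + g("sigmaGL2") / L +
    g("sigmaGLY2") / (L * Y) + g("sigmaE2") / (L * Y * R)
  stopIfNot(den > 0, "all variance components are zero; heritability undefined")
  num / den
}

#' Pairwise Pearson correlations of line means across environments
#'
#' @param records data.frame with `line`, `env`, `value`.
#' @param minShared minimum number of shared lines per pair (default 3);
#'   pairs below it are reported as `NA`.
#' @return symmetric correlation matrix (environments x environments).
#' @export
envCorrelations <- function(records, minShared = 3L) {
  envs <- unique(records$env)
  stopIfNot(length(envs) >= 2, "need at least 2 environments")
  means <- tapply(records$value, list(records$line, records$env), mean)
  out <- matrix(NA_real_, length(envs), length(envs),
    dimnames = list(envs, envs))
  diag(out) <- 1
  for (i in seq_along(envs)[-1]) for (j in seq_len(i - 1)) {
    ok <- complete.cases(means[, c(envs[i], envs[j])])
    if (sum(ok) >= minShared)
      out[envs[i], envs[j]] <- out[envs[j], envs[i]] <-
        cor(means[ok, envs[i]], means[ok, envs[j]])
  }
  out
}
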