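## Small internal helpers shared across modules.

## Derive a reproducible substream seed from a master seed and a counter.
## Kept below 2^31 so it is always a valid integer seed.
deriveSeed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483587)
}

## Evaluate an expression with a local RNG state (does not disturb the
## caller's stream).
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

stopIfNot <- function(cond, msg, ...) {
  if (!cond) stop(sprintf(msg, ...), call. = FALSE)
}

## bp -> cM and cM -> bp by monotone piecewise-linear interpolation over the
## template's anchors.
cmAtBp <- function(anchors, bp) {
  stats::approx(anchors$bp, anchors$cm, xout = bp, rule = 2)$y
}

bpAtCm <- function(anchors, cm) {
  ## anchors$cm may be constant (zero genetic length); fall back to midpoint
  if (max(anchors$cm) == min(anchors$cm))
    return(rep(mean(range(anchors$bp)), length(cm)))
  stats::approx(anchors$cm, anchors$bp, xout = cm, rule = 2, ties = "ordered")$y
}

codeToNumeric <- function(codes) {
  ## A -> +1, B -> -1, H -> 0, N -> NA (additive genotype score)
  x <- rep(NA_real_, length(codes))
  x[codes == "A"] <- 1
  x[codes == "B"] <- -1
  x[codes == "H"] <- 0
  if (is.matrix(codes)) dim(x) <- dim(codes)
  x
}
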