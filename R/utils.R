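# Wald 95% multiplier: fixed normal quantile, used for every reported CI
# (MR-Egger p-values use the t distribution but keep the 1.96 interval so
# intervals are comparable across methods).
.CI_Z <- 1.96

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
# A NULL seed uses (and advances) the current stream.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  expr
}

.newEstimate <- function(method, beta, se, pvalue, nSnp, extras = list()) {
  new("MREstimate", method = method, beta = beta, se = se,
      ciLow = beta - .CI_Z * se, ciHigh = beta + .CI_Z * se,
      pvalue = max(pvalue, .Machine$double.xmin), nSnp = as.integer(nSnp),
      extras = extras)
}

.assertHarmonized <- function(x, minSnp, what) {
  if (!is(x, "HarmonizedSet"))
    stop(what, " expects a HarmonizedSet (see harmonizedSet())", call. = FALSE)
  if (length(x) < minSnp)
    stop(what, " needs at least ", minSnp, " instrument(s), got ", length(x),
         call. = FALSE)
  invisible(x)
}

# Ratio-based estimators require a nonzero variant-exposure effect.
.assertNonzeroBetaX <- function(x, what) {
  if (any(x@betaX == 0))
    stop(what, ": beta_x is zero for ",
         paste(x@snp[x@betaX == 0], collapse = ", "), call. = FALSE)
  invisible(x)
}
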