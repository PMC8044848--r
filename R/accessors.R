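#' @describeIn MREstimate-class causal log-OR estimate.
#' @export
setMethod("mrBeta", "MREstimate", function(x) x@beta)

#' @describeIn MREstimate-class standard error of the estimate.
#' @export
setMethod("mrSE", "MREstimate", function(x) x@se)

#' @describeIn MREstimate-class two-sided p-value.
#' @export
setMethod("pValue", "MREstimate", function(x) x@pvalue)

#' @describeIn MREstimate-class odds ratio `exp(beta)` (derived view).
#' @export
setMethod("oddsRatio", "MREstimate", function(x) exp(x@beta))

#' @describeIn MREstimate-class number of instruments used.
#' @export
setMethod("nSnp", "MREstimate", function(x) x@nSnp)

#' @describeIn MREstimate-class method tag.
#' @export
setMethod("mrMethod", "MREstimate", function(x) x@method)

#' @describeIn MREstimate-class 95% Wald confidence interval, log-OR scale.
#' @param object an `MREstimate`.
#' @param parm,level ignored (fixed 95% Wald interval).
#' @param ... ignored.
#' @export
setMethod("confint", "MREstimate", function(object, parm, level = 0.95, ...)
  c(object@ciLow, object@ciHigh))

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("MR estimate [%s], %d instrument(s)\n", object@method, object@nSnp))
  cat(sprintf("  beta = %.4f (se %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
              object@beta, object@se, object@ciLow, object@ciHigh, object@pvalue))
  cat(sprintf("  OR   = %.3f, 95%% CI [%.3f, %.3f]\n",
              exp(object@beta), exp(object@ciLow), exp(object@ciHigh)))
  if (object@method == "egger" && !is.null(object@extras$intercept))
    cat(sprintf("  intercept = %.4f (se %.4f), p = %.3g\n",
                object@extras$intercept, object@extras$interceptSE,
                object@extras$interceptP))
  invisible(object)
})

#' @describeIn HarmonizedSet-class variant identifiers.
#' @export
setMethod("snpIds", "HarmonizedSet", function(x) x@snp)

#' @describeIn HarmonizedSet-class variant-exposure effects.
#' @export
setMethod("betaX", "HarmonizedSet", function(x) x@betaX)

#' @describeIn HarmonizedSet-class their standard errors.
#' @export
setMethod("seX", "HarmonizedSet", function(x) x@seX)

#' @describeIn HarmonizedSet-class variant-outcome effects.
#' @export
setMethod("betaY", "HarmonizedSet", function(x) x@betaY)

#' @describeIn HarmonizedSet-class their standard errors.
#' @export
setMethod("seY", "HarmonizedSet", function(x) x@seY)

#' @describeIn HarmonizedSet-class variants dropped during harmonization,
#'   with reasons.
#' @export
setMethod("droppedVariants", "HarmonizedSet", function(x) x@dropped)

#' @describeIn HarmonizedSet-class number of harmonized instruments.
#' @export
setMethod("length", "HarmonizedSet", function(x) length(x@snp))

#' @describeIn HarmonizedSet-class subset instruments (dropped table is kept).
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "HarmonizedSet", function(x, i, j, ..., drop = FALSE) {
  new("HarmonizedSet",
      snp = x@snp[i], betaX = x@betaX[i], seX = x@seX[i],
      betaY = x@betaY[i], seY = x@seY[i], action = x@action[i],
      dropped = x@dropped,
      exposureLabel = x@exposureLabel, outcomeLabel = x@outcomeLabel)
})

#' @describeIn HarmonizedSet-class instruments as a data.frame.
#' @param row.names,optional,... passed over (unused).
#' @export
setMethod("as.data.frame", "HarmonizedSet",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(snp = x@snp, beta_x = x@betaX, se_x = x@seX,
               beta_y = x@betaY, se_y = x@seY, action = x@action,
               stringsAsFactors = FALSE)
  })

setMethod("show", "HarmonizedSet", function(object) {
  cat(sprintf("HarmonizedSet: %s -> %s\n", object@exposureLabel, object@outcomeLabel))
  cat(sprintf("  %d harmonized instrument(s), %d dropped\n",
              length(object@snp), nrow(object@dropped)))
  if (length(object@snp)) {
    df <- as.data.frame(object)
    print(utils::head(df, 6), row.names = FALSE)
    if (nrow(df) > 6) cat(sprintf("  ... %d more\n", nrow(df) - 6L))
  }
  if (nrow(object@dropped)) {
    cat("  dropped:\n")
    print(utils::head(object@dropped, 6), row.names = FALSE)
  }
  invisible(object)
})

setMethod("show", "HeterogeneityResult", function(object) {
  cat(sprintf("Cochran's Q = %.3f, df = %d, p = %.3g\n",
              object@q, object@df, object@pvalue))
  invisible(object)
})

setMethod("show", "PressoResult", function(object) {
  cat(sprintf("MR-PRESSO: RSS_obs = %.3f, global p = %.4g (%d simulations)\n",
              object@rssObs, object@globalP, object@nSim))
  if (length(object@outliers)) {
    cat(sprintf("  outliers: %s\n", paste(object@outliers, collapse = ", ")))
    cat(sprintf("  distortion p = %.3g\n", object@distortionP))
  } else cat("  no outliers detected\n")
  invisible(object)
})

#' @describeIn DirectionReport-class named list of `MREstimate`s.
#' @export
setMethod("estimates", "DirectionReport", function(x) x@estimates)

#' @describeIn DirectionReport-class the `SensitivityReport`.
#' @export
setMethod("sensitivity", "DirectionReport", function(x) x@sensitivity)

#' @describeIn DirectionReport-class the per-stage audit log.
#' @export
setMethod("stageLog", "DirectionReport", function(x) x@log)

#' @describeIn DirectionReport-class the Bonferroni significance flag.
#' @export
setMethod("isSignificant", "DirectionReport", function(x) x@significant)

#' @describeIn DirectionReport-class the harmonized instruments used.
#' @export
setMethod("droppedVariants", "DirectionReport",
          function(x) droppedVariants(x@harmonized))

setMethod("estimateTable", "MREstimate", function(x) estimateTable(list(x)))

setMethod("estimateTable", "list", function(x) {
  stopifnot(length(x) > 0L, all(vapply(x, is, logical(1), "MREstimate")))
  data.frame(
    method  = vapply(x, function(e) e@method, character(1)),
    n_snp   = vapply(x, function(e) e@nSnp, integer(1)),
    beta    = vapply(x, function(e) e@beta, numeric(1)),
    se      = vapply(x, function(e) e@se, numeric(1)),
    ci_low  = vapply(x, function(e) e@ciLow, numeric(1)),
    ci_high = vapply(x, function(e) e@ciHigh, numeric(1)),
    pvalue  = vapply(x, function(e) e@pvalue, numeric(1)),
    or      = vapply(x, function(e) exp(e@beta), numeric(1)),
    stringsAsFactors = FALSE)
})

setMethod("estimateTable", "DirectionReport",
          function(x) estimateTable(unname(x@estimates)))

setMethod("show", "DirectionReport", function(object) {
  cat(sprintf("Direction: %s -> %s (%d instruments)\n",
              object@exposureLabel, object@outcomeLabel,
              length(object@harmonized)))
  print(estimateTable(object), row.names = FALSE, digits = 4)
  if (!is.null(object@sensitivity@heterogeneity))
    show(object@sensitivity@heterogeneity)
  if (!is.null(object@sensitivity@presso)) show(object@sensitivity@presso)
  if (length(object@power))
    cat(sprintf("  80%%-power detectable OR interval: (%.2f, %.2f)\n",
                object@power$orLow, object@power$orHigh))
  cat(sprintf("  significant at Bonferroni threshold %.3g: %s\n",
              object@config$bonferroni, object@significant))
  invisible(object)
})

setMethod("show", "StudyReport", function(object) {
  cat("Bidirectional Mendelian randomization study\n")
  cat(sprintf("Bonferroni threshold: %.4g\n\n", object@bonferroni))
  show(object@forward); cat("\n"); show(object@reverse)
  invisible(object)
})
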