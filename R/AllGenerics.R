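#' @rdname MREstimate-class
#' @param x an object.
#' @export
setGeneric("mrBeta", function(x) standardGeneric("mrBeta"))

#' @rdname MREstimate-class
#' @export
setGeneric("mrSE", function(x) standardGeneric("mrSE"))

#' @rdname MREstimate-class
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname MREstimate-class
#' @export
setGeneric("oddsRatio", function(x) standardGeneric("oddsRatio"))

#' @rdname MREstimate-class
#' @export
setGeneric("nSnp", function(x) standardGeneric("nSnp"))

#' @rdname MREstimate-class
#' @export
setGeneric("mrMethod", function(x) standardGeneric("mrMethod"))

#' @rdname HarmonizedSet-class
#' @param x an object.
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' @rdname HarmonizedSet-class
#' @export
setGeneric("betaX", function(x) standardGeneric("betaX"))

#' @rdname HarmonizedSet-class
#' @export
setGeneric("seX", function(x) standardGeneric("seX"))

#' @rdname HarmonizedSet-class
#' @export
setGeneric("betaY", function(x) standardGeneric("betaY"))

#' @rdname HarmonizedSet-class
#' @export
setGeneric("seY", function(x) standardGeneric("seY"))

#' @rdname HarmonizedSet-class
#' @export
setGeneric("droppedVariants", function(x) standardGeneric("droppedVariants"))

#' @rdname DirectionReport-class
#' @param x an object.
#' @export
setGeneric("estimates", function(x) standardGeneric("estimates"))

#' @rdname DirectionReport-class
#' @export
setGeneric("sensitivity", function(x) standardGeneric("sensitivity"))

#' @rdname DirectionReport-class
#' @export
setGeneric("stageLog", function(x) standardGeneric("stageLog"))

#' @rdname DirectionReport-class
#' @export
setGeneric("isSignificant", function(x) standardGeneric("isSignificant"))

#' Tabulate causal estimates
#'
#' Flattens one or more [MREstimate-class] objects (or the estimates in a
#' [DirectionReport-class]) into a data.frame with one row per method:
#' `method, n_snp, beta, se, ci_low, ci_high, pvalue, or` (log-OR scale for
#' `beta`..`ci_high`; `or = exp(beta)`).
#'
#' @param x an `MREstimate`, a list of them, or a `DirectionReport`.
#' @return a data.frame, deterministic column order.
#' @export
setGeneric("estimateTable", function(x) standardGeneric("estimateTable"))
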