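#' @import methods
NULL

#' Pairwise linkage-disequilibrium table
#'
#' Symmetric lookup of squared correlation (r-squared) between variant pairs.
#' Pairs absent from the table are treated as unlinked (r-squared 0); a
#' variant is always in complete LD with itself (r-squared 1).
#'
#' @slot snpA,snpB character vectors of variant identifiers (one pair per
#'   entry, stored in canonical order).
#' @slot r2 numeric vector of squared correlations in `[0, 1]`.
#'
#' @seealso [ldTable()], [readLdTable()], [ldR2()]
#' @export
setClass("LdTable",
  representation(snpA = "character", snpB = "character", r2 = "numeric"))

setValidity("LdTable", function(object) {
  msg <- character()
  n <- length(object@snpA)
  if (length(object@snpB) != n || length(object@r2) != n)
    msg <- c(msg, "snpA, snpB and r2 must have equal length")
  if (any(!is.finite(object@r2)) || any(object@r2 < 0 | object@r2 > 1))
    msg <- c(msg, "r2 values must lie in [0, 1]")
  key <- paste(pmin(object@snpA, object@snpB), pmax(object@snpA, object@snpB))
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    conflict <- vapply(unique(dup), function(k) {
      r <- object@r2[key == k]
      diff(range(r)) > 1e-12
    }, logical(1))
    if (any(conflict))
      msg <- c(msg, paste0("conflicting r2 for duplicated pair(s): ",
                           paste(unique(dup)[conflict], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Harmonized exposure/outcome instrument set
#'
#' The central input object for all causal estimators: per variant, the
#' genetic effect on the exposure and on the outcome expressed on a common
#' effect-allele orientation, with standard errors. Variants that could not
#' be harmonized are recorded in `dropped` with a reason.
#'
#' @slot snp character, variant identifiers.
#' @slot betaX,seX numeric, variant-exposure effect (log-odds per effect
#'   allele) and its standard error (> 0).
#' @slot betaY,seY numeric, variant-outcome effect on the same effect allele
#'   and its standard error (> 0).
#' @slot action character, harmonization provenance per variant (one of
#'   `unchanged`, `sign_flipped`, `strand_flipped`,
#'   `strand_flipped_and_signed`, `proxy_substituted:<id>`, or `constructed`
#'   when built directly).
#' @slot dropped data.frame with columns `snp`, `reason`.
#' @slot exposureLabel,outcomeLabel single strings naming the two traits.
#'
#' @seealso [harmonizedSet()], [harmonizeSets()]
#' @export
setClass("HarmonizedSet",
  representation(snp = "character",
                 betaX = "numeric", seX = "numeric",
                 betaY = "numeric", seY = "numeric",
                 action = "character",
                 dropped = "data.frame",
                 exposureLabel = "character", outcomeLabel = "character"),
  prototype(dropped = data.frame(snp = character(), reason = character(),
                                 stringsAsFactors = FALSE),
            exposureLabel = "exposure", outcomeLabel = "outcome"))

setValidity("HarmonizedSet", function(object) {
  msg <- character()
  n <- length(object@snp)
  for (s in c("betaX", "seX", "betaY", "seY", "action"))
    if (length(slot(object, s)) != n)
      msg <- c(msg, sprintf("slot '%s' must have length %d", s, n))
  if (length(msg) == 0L) {
    if (any(!is.finite(object@seX)) || any(object@seX <= 0))
      msg <- c(msg, "seX must be finite and > 0")
    if (any(!is.finite(object@seY)) || any(object@seY <= 0))
      msg <- c(msg, "seY must be finite and > 0")
    if (anyDuplicated(object@snp))
      msg <- c(msg, "duplicated snp identifiers")
    if (!all(c("snp", "reason") %in% names(object@dropped)))
      msg <- c(msg, "dropped must have columns snp, reason")
    else if (any(object@snp %in% object@dropped$snp))
      msg <- c(msg, "a snp cannot be both harmonized and dropped")
  }
  if (length(msg)) msg else TRUE
})

#' A causal estimate from one Mendelian randomization method
#'
#' Effects are held on the log odds-ratio scale; the odds ratio is a derived
#' view available through [oddsRatio()]. The 95% interval is the Wald
#' interval `beta +/- 1.96 * se`.
#'
#' @slot method single string tagging the estimator (`wald`, `ivw_fixed`,
#'   `ivw_mre`, `egger`, `weighted_median`, `presso_raw`, `presso_corrected`).
#' @slot beta,se numeric, causal log-OR per unit exposure log-OR and its SE.
#' @slot ciLow,ciHigh numeric, 95% Wald bounds on the log-OR scale.
#' @slot pvalue numeric, two-sided p-value.
#' @slot nSnp integer, number of instruments used.
#' @slot extras named list of method-specific fields (e.g. the MR-Egger
#'   intercept, its SE and p-value; bootstrap settings).
#' @export
setClass("MREstimate",
  representation(method = "character", beta = "numeric", se = "numeric",
                 ciLow = "numeric", ciHigh = "numeric", pvalue = "numeric",
                 nSnp = "integer", extras = "list"),
  prototype(extras = list()))

setValidity("MREstimate", function(object) {
  msg <- character()
  if (length(object@method) != 1L) msg <- c(msg, "method must be a single string")
  if (!is.finite(object@se) || object@se < 0) msg <- c(msg, "se must be >= 0")
  if (!is.finite(object@pvalue) || object@pvalue <= 0 || object@pvalue > 1)
    msg <- c(msg, "pvalue must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Cochran's Q heterogeneity test result
#'
#' @slot q Q statistic (>= 0), computed with first-order inverse-variance
#'   weights so that `q / df` is the multiplicative random-effects inflation.
#' @slot df integer degrees of freedom, `n_snp - 1`.
#' @slot pvalue chi-square upper-tail p-value.
#' @export
setClass("HeterogeneityResult",
  representation(q = "numeric", df = "integer", pvalue = "numeric"))

#' MR-PRESSO result
#'
#' Global pleiotropy test, per-variant outlier flags, and (when outliers are
#' found) the outlier-corrected estimate with a distortion test.
#'
#' @slot rssObs observed residual sum of squares (leave-one-out weighted).
#' @slot globalP empirical global-test p-value (add-one estimator, so never 0).
#' @slot nSim number of parametric simulations used.
#' @slot outliers character vector of flagged variant ids (possibly empty).
#' @slot outlierP named numeric vector of per-variant empirical p-values.
#' @slot raw,corrected the uncorrected IVW estimate and, when outliers were
#'   removed, the re-estimated one (`NULL` otherwise).
#' @slot distortionP bootstrap p-value for the raw-vs-corrected difference
#'   (`NA` when no outliers).
#' @export
setClass("PressoResult",
  representation(rssObs = "numeric", globalP = "numeric", nSim = "integer",
                 outliers = "character", outlierP = "numeric",
                 raw = "ANY", corrected = "ANY", distortionP = "numeric"))

setValidity("PressoResult", function(object) {
  msg <- character()
  if (object@globalP < 1 / (1 + object@nSim) - 1e-15 || object@globalP > 1)
    msg <- c(msg, "globalP must lie in [1/(1+nSim), 1]")
  if (length(object@outliers) == 0L && !is.null(object@corrected))
    msg <- c(msg, "corrected estimate present without outliers")
  if (length(msg)) msg else TRUE
})

#' Heterogeneity / pleiotropy diagnostics bundle
#'
#' @slot heterogeneity a [HeterogeneityResult-class] (or `NULL` when fewer
#'   than 2 instruments).
#' @slot presso a [PressoResult-class] (or `NULL` when fewer than 4
#'   instruments).
#' @slot leaveOneOut data.frame of leave-one-out IVW estimates.
#' @slot funnel data.frame of per-variant ratio and precision.
#' @export
setClass("SensitivityReport",
  representation(heterogeneity = "ANY", presso = "ANY",
                 leaveOneOut = "data.frame", funnel = "data.frame"))

#' One direction of a bidirectional MR study
#'
#' @slot exposureLabel,outcomeLabel trait names.
#' @slot harmonized the [HarmonizedSet-class] the estimates are based on.
#' @slot estimates named list of [MREstimate-class] objects.
#' @slot sensitivity a [SensitivityReport-class].
#' @slot power named list with the detectable-OR interval and its inputs
#'   (empty when the outcome case fraction was not supplied).
#' @slot log data.frame auditing each pipeline stage (counts in/out, detail).
#' @slot significant logical flag: primary (fixed-effect IVW) p-value below
#'   the family-wise Bonferroni threshold.
#' @slot config named list echoing the effective settings (incl. seed).
#' @export
setClass("DirectionReport",
  representation(exposureLabel = "character", outcomeLabel = "character",
                 harmonized = "HarmonizedSet", estimates = "list",
                 sensitivity = "SensitivityReport", power = "list",
                 log = "data.frame", significant = "logical",
                 config = "list"))

#' Consolidated bidirectional study report
#'
#' @slot forward,reverse the two [DirectionReport-class] objects.
#' @slot bonferroni the family-wise significance threshold
#'   (`alphaFamily / nTests`).
#' @slot config run metadata (seed, thresholds, labels).
#' @export
setClass("StudyReport",
  representation(forward = "DirectionReport", reverse = "DirectionReport",
                 bonferroni = "numeric", config = "list"))
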