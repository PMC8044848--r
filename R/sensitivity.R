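.cochranQCore <- function(x) {
  theta <- x@betaY / x@betaX
  w <- x@betaX^2 / x@seY^2
  thIVW <- sum(w * theta) / sum(w)   # identical to the fixed-effect IVW beta
  list(q = sum(w * (theta - thIVW)^2), thIVW = thIVW)
}

#' Cochran's Q heterogeneity test
#'
#' Q = sum over variants of `w_k (theta_k - theta_IVW)^2` with per-variant
#' ratios `theta_k = beta_y / beta_x` and first-order weights
#' `w_k = beta_x^2 / se_y^2` — the same weights as the fixed-effect IVW, so
#' `Q / (k - 1)` is exactly the multiplicative random-effects inflation
#' factor. p-value from the chi-square upper tail at `k - 1` df.
#'
#' @param x a [HarmonizedSet-class] with at least 2 instruments, nonzero
#'   exposure effects.
#' @return a [HeterogeneityResult-class].
#' @export
cochranQ <- function(x) {
  .assertHarmonized(x, 2L, "cochranQ")
  .assertNonzeroBetaX(x, "cochranQ")
  k <- length(x)
  q <- .cochranQCore(x)$q
  new("HeterogeneityResult", q = q, df = k - 1L,
      pvalue = stats::pchisq(q, df = k - 1, lower.tail = FALSE))
}

# Leave-one-out IVW slopes via sum subtraction (O(k) for all k slopes).
.looSlopes <- function(bx, by, wy) {
  a <- bx * by * wy; b <- bx^2 * wy
  (sum(a) - a) / (sum(b) - b)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Simulation-based global pleiotropy test, per-variant outlier detection and
#' outlier-corrected re-estimation.
#'
#' The observed statistic is `RSS_obs = sum_j w_j (beta_y_j -
#' theta_(-j) * beta_x_j)^2`, `w_j = 1 / se_y_j^2`, where `theta_(-j)` is the
#' fixed-effect IVW slope with variant j left out. The null distribution is
#' built from `nSim` parametric replicates with `beta_x* ~ Normal(beta_x,
#' se_x)` and `beta_y* ~ Normal(theta_(-j) * beta_x_j, se_y_j)`; the global
#' p-value is the add-one empirical tail `(1 + #\{RSS* >= RSS_obs\}) /
#' (1 + nSim)`, so it is never zero and is exactly reproducible given
#' `(seed, nSim)`. Each variant's weighted residual is compared to its own
#' simulated distribution and flagged as an outlier when its empirical
#' p-value falls below `outlierAlpha / k` (Bonferroni). When outliers are
#' found, the corrected estimate is the IVW fit on the remaining variants,
#' and a distortion p-value is obtained by bootstrapping the corrected-raw
#' difference: `nSim` resamples of `k - #outliers` instruments drawn with
#' replacement from the full set.
#'
#' @param x a [HarmonizedSet-class] with at least 4 instruments, nonzero
#'   exposure effects.
#' @param nSim simulation replicates, default 1000 (10000 recommended for
#'   reporting).
#' @param outlierAlpha family-wise outlier level, default 0.05.
#' @param seed integer seed (required for reproducibility of the empirical
#'   p-values).
#' @return a [PressoResult-class].
#' @export
mrPresso <- function(x, nSim = 1000, outlierAlpha = 0.05, seed = NULL) {
  .assertHarmonized(x, 4L, "mrPresso")
  .assertNonzeroBetaX(x, "mrPresso")
  k <- length(x)
  bx <- x@betaX; by <- x@betaY; sx <- x@seX; sy <- x@seY
  wy <- 1 / sy^2
  thLoo <- .looSlopes(bx, by, wy)
  resObs <- wy * (by - thLoo * bx)^2
  rssObs <- sum(resObs)

  sim <- withSeed(seed, {
    BX <- matrix(stats::rnorm(nSim * k, mean = rep(bx, each = nSim),
                              sd = rep(sx, each = nSim)), nSim, k)
    BY <- matrix(stats::rnorm(nSim * k, mean = rep(thLoo * bx, each = nSim),
                              sd = rep(sy, each = nSim)), nSim, k)
    A <- (BX * BY) %*% wy
    B <- (BX * BX) %*% wy
    ThLoo <- (drop(A) - t(t(BX * BY) * wy)) / (drop(B) - t(t(BX * BX) * wy))
    Res <- t(t((BY - ThLoo * BX)^2) * wy)
    list(rss = rowSums(Res), res = Res)
  })
  globalP <- (1 + sum(sim$rss >= rssObs)) / (1 + nSim)
  outlierP <- vapply(seq_len(k), function(j)
    (1 + sum(sim$res[, j] >= resObs[j])) / (1 + nSim), numeric(1))
  names(outlierP) <- x@snp
  isOut <- outlierP < outlierAlpha / k

  raw <- mrIVW(x)
  raw@method <- "presso_raw"
  corrected <- NULL
  distortionP <- NA_real_
  if (any(isOut) && sum(!isOut) >= 1L) {
    corrected <- mrIVW(x[!isOut])
    corrected@method <- "presso_corrected"
    obsDiff <- corrected@beta - raw@beta
    nKeep <- sum(!isOut)
    bootDiff <- withSeed(if (is.null(seed)) NULL else seed + 1L, {
      vapply(seq_len(nSim), function(b) {
        idx <- sample.int(k, nKeep, replace = TRUE)
        .ivwCore(bx[idx], by[idx], sy[idx])$beta - raw@beta
      }, numeric(1))
    })
    distortionP <- (1 + sum(abs(bootDiff) >= abs(obsDiff))) / (1 + nSim)
  }
  new("PressoResult", rssObs = rssObs, globalP = globalP,
      nSim = as.integer(nSim), outliers = x@snp[isOut], outlierP = outlierP,
      raw = raw, corrected = corrected, distortionP = distortionP)
}

#' Leave-one-out IVW estimates
#'
#' Re-estimates the fixed-effect IVW causal effect with each instrument
#' excluded in turn, to show whether any single variant drives the pooled
#' estimate.
#'
#' @param x a [HarmonizedSet-class] with at least 3 instruments.
#' @param model IVW variance model, as in [mrIVW()].
#' @return data.frame with one row per excluded variant: `excluded, n_snp,
#'   beta, se, ci_low, ci_high, pvalue, or`.
#' @export
leaveOneOut <- function(x, model = "fixed") {
  .assertHarmonized(x, 3L, "leaveOneOut")
  rows <- lapply(seq_len(length(x)), function(j) {
    e <- mrIVW(x[-j], model = model)
    cbind(excluded = x@snp[j], estimateTable(e)[, -1])
  })
  do.call(rbind, rows)
}

#' Funnel-plot data
#'
#' Per-variant Wald ratio against its precision (`1 / se(theta_k) =
#' |beta_x| / se_y`). Asymmetry of the funnel suggests directional
#' pleiotropy. No rendering is done; plot with any graphics layer.
#'
#' @param x a [HarmonizedSet-class] with at least 1 instrument, nonzero
#'   exposure effects.
#' @return data.frame `snp, ratio, precision`.
#' @export
funnelData <- function(x) {
  .assertHarmonized(x, 1L, "funnelData")
  .assertNonzeroBetaX(x, "funnelData")
  data.frame(snp = x@snp, ratio = x@betaY / x@betaX,
             precision = abs(x@betaX) / x@seY, stringsAsFactors = FALSE)
}

#' Bundle sensitivity diagnostics
#'
#' Runs Cochran's Q, MR-PRESSO, leave-one-out and funnel data, skipping any
#' diagnostic whose minimum instrument count is not met.
#'
#' @param x a [HarmonizedSet-class].
#' @param nSim MR-PRESSO simulations.
#' @param seed seed forwarded to MR-PRESSO.
#' @return a [SensitivityReport-class].
#' @export
sensitivityReport <- function(x, nSim = 1000, seed = NULL) {
  emptyLoo <- data.frame()
  new("SensitivityReport",
      heterogeneity = if (length(x) >= 2L) cochranQ(x) else NULL,
      presso = if (length(x) >= 4L) mrPresso(x, nSim = nSim, seed = seed)
               else NULL,
      leaveOneOut = if (length(x) >= 3L) leaveOneOut(x) else emptyLoo,
      funnel = if (length(x) >= 1L) funnelData(x) else emptyLoo)
}
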