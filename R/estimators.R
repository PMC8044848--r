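# Fixed-effect IVW core, shared by the estimator, Cochran's Q and MR-PRESSO:
#   beta = sum(bx * by * wy) / sum(bx^2 * wy),  wy = 1 / se_y^2
#   se   = sqrt(1 / sum(bx^2 * wy))
# Equivalent to weighted least squares of by on bx through the origin.
.ivwCore <- function(bx, by, sy) {
  if (length(bx) == 1L)  # reduces exactly to the Wald ratio
    return(list(beta = by / bx, se = sy / abs(bx)))
  wy <- 1 / sy^2
  denom <- sum(bx^2 * wy)
  beta <- sum(bx * by * wy) / denom
  list(beta = beta, se = sqrt(1 / denom))
}

#' Wald ratio estimate from a single instrument
#'
#' `beta = beta_y / beta_x` with first-order standard error
#' `se_y / |beta_x|`; two-sided normal p-value.
#'
#' @param x a one-instrument [HarmonizedSet-class].
#' @return an [MREstimate-class] with method `"wald"`.
#' @export
waldRatio <- function(x) {
  .assertHarmonized(x, 1L, "waldRatio")
  if (length(x) != 1L)
    stop("waldRatio takes exactly one instrument; use mrIVW to pool",
         call. = FALSE)
  .assertNonzeroBetaX(x, "waldRatio")
  beta <- x@betaY / x@betaX
  se <- x@seY / abs(x@betaX)
  .newEstimate("wald", beta, se, 2 * stats::pnorm(-abs(beta / se)), 1L)
}

#' Inverse-variance weighted causal estimate
#'
#' Pools per-variant Wald ratios with first-order inverse-variance weights.
#' The fixed-effect model (default) uses exactly
#' `beta = sum(bX bY / sY^2) / sum(bX^2 / sY^2)` and
#' `se = sqrt(1 / sum(bX^2 / sY^2))`; the multiplicative random-effects model
#' keeps the same point estimate and inflates the standard error by
#' `sqrt(max(1, Q / (k - 1)))`, Q being Cochran's statistic.
#'
#' @param x a [HarmonizedSet-class] with at least one instrument, all with
#'   nonzero exposure effects.
#' @param model `"fixed"` (default) or `"multiplicative_random"`.
#' @return an [MREstimate-class] (`ivw_fixed` or `ivw_mre`).
#' @export
mrIVW <- function(x, model = c("fixed", "multiplicative_random")) {
  model <- match.arg(model)
  .assertHarmonized(x, 1L, "mrIVW")
  .assertNonzeroBetaX(x, "mrIVW")
  k <- length(x)
  core <- .ivwCore(x@betaX, x@betaY, x@seY)
  se <- core$se
  extras <- list()
  if (model == "multiplicative_random") {
    infl <- 1
    if (k >= 2L) {
      q <- .cochranQCore(x)$q
      infl <- sqrt(max(1, q / (k - 1)))
    }
    se <- se * infl
    extras$inflation <- infl
  }
  .newEstimate(if (model == "fixed") "ivw_fixed" else "ivw_mre",
               core$beta, se, 2 * stats::pnorm(-abs(core$beta / se)), k,
               extras)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome on exposure effects with a free
#' intercept (weights `1 / se_y^2`). Instruments are first oriented so every
#' exposure effect is positive (both betas flipped together), which makes the
#' fit invariant to arbitrary allele orientation. Both coefficient standard
#' errors carry the residual inflation factor `sqrt(max(1, RSS / (k - 2)))`;
#' p-values use the t distribution with `k - 2` df while the reported 95%
#' interval keeps the 1.96 multiplier for comparability across methods. A
#' nonzero intercept indicates directional (unbalanced) horizontal
#' pleiotropy; the slope is the pleiotropy-adjusted causal estimate under the
#' InSIDE assumption.
#'
#' @param x a [HarmonizedSet-class] with at least 3 instruments.
#' @return an [MREstimate-class] with method `"egger"`; `extras` holds
#'   `intercept`, `interceptSE`, `interceptP`, `inflation`, `df`.
#' @export
mrEgger <- function(x) {
  .assertHarmonized(x, 3L, "mrEgger")
  k <- length(x)
  s <- ifelse(x@betaX < 0, -1, 1)
  bx <- s * x@betaX; by <- s * x@betaY
  w <- 1 / x@seY^2
  X <- cbind(1, bx)
  xtwx <- crossprod(X, w * X)
  coefs <- unname(drop(solve(xtwx, crossprod(X, w * by))))
  resid <- by - drop(X %*% coefs)
  rss <- sum(w * resid^2)
  infl <- sqrt(max(1, rss / (k - 2)))
  seUnit <- unname(sqrt(diag(solve(xtwx))))
  ses <- seUnit * infl
  pvals <- 2 * stats::pt(-abs(coefs / ses), df = k - 2)
  .newEstimate("egger", coefs[2], ses[2], pvals[2], k,
               extras = list(intercept = coefs[1], interceptSE = ses[1],
                             interceptP = pvals[1], inflation = infl,
                             df = k - 2L))
}

# Interpolated weighted median of ratios `theta` with weights `w`.
.weightedMedianPoint <- function(theta, w) {
  o <- order(theta)
  th <- theta[o]; w <- w[o] / sum(w)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(th[1])
  n <- length(th)
  if (0.5 >= p[n]) return(th[n])
  stats::approx(p, th, xout = 0.5, ties = "ordered")$y
}

#' Weighted median causal estimate
#'
#' Consistent when instruments carrying more than half of the weight are
#' valid. Per-variant ratios `beta_y / beta_x` are weighted by the
#' first-order inverse ratio variance `beta_x^2 / se_y^2` (normalized); the
#' estimate interpolates the ratio at cumulative weight percentile 0.5 using
#' `p_j = (S_j - w_j / 2) / S_total`. The standard error comes from a
#' parametric bootstrap: effects are resampled from
#' `Normal(observed, se)` on both sides `nBoot` times and the weighted median
#' recomputed.
#'
#' @param x a [HarmonizedSet-class] with at least 3 instruments, nonzero
#'   exposure effects.
#' @param nBoot bootstrap replicates, default 1000.
#' @param seed integer seed for the bootstrap (recorded in `extras`).
#' @return an [MREstimate-class] with method `"weighted_median"`.
#' @export
weightedMedian <- function(x, nBoot = 1000, seed = NULL) {
  .assertHarmonized(x, 3L, "weightedMedian")
  .assertNonzeroBetaX(x, "weightedMedian")
  k <- length(x)
  theta <- x@betaY / x@betaX
  w <- x@betaX^2 / x@seY^2
  est <- .weightedMedianPoint(theta, w)
  boot <- withSeed(seed, {
    vapply(seq_len(nBoot), function(b) {
      bx <- stats::rnorm(k, x@betaX, x@seX)
      by <- stats::rnorm(k, x@betaY, x@seY)
      ok <- bx != 0
      .weightedMedianPoint(by[ok] / bx[ok], bx[ok]^2 / x@seY[ok]^2)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  .newEstimate("weighted_median", est, se,
               2 * stats::pnorm(-abs(est / se)), k,
               extras = list(nBoot = nBoot, seed = seed))
}
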