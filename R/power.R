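#' Power of a two-sample MR test with a binary outcome
#'
#' Normal-approximation power in the style of the mRnd calculator: with
#' causal odds ratio `or`, the IVW test's non-centrality is
#' `z = |ln or| * sqrt(n * r2 * k * (1 - k))`, where `n` is the outcome-study
#' sample size, `k` its case fraction and `r2` the variance in the exposure
#' explained by the instruments; two-sided power is
#' `Phi(z - z_{1-alpha/2}) + Phi(-z - z_{1-alpha/2})`.
#'
#' @param n outcome-study sample size (> 0).
#' @param kCases proportion of cases, in (0, 1).
#' @param r2 instrument variance explained, in (0, 1).
#' @param or hypothesized causal odds ratio (> 0; vectorized).
#' @param alpha two-sided type-I error, default 0.05.
#' @return power in (0, 1); equals `alpha` at `or = 1` and is symmetric in
#'   `or` vs `1 / or`.
#' @export
mrPowerBinary <- function(n, kCases, r2, or, alpha = 0.05) {
  stopifnot(n > 0, kCases > 0, kCases < 1, r2 > 0, r2 < 1,
            alpha > 0, alpha < 1)
  if (any(or <= 0)) stop("odds ratio must be positive", call. = FALSE)
  z <- abs(log(or)) * sqrt(n * r2 * kCases * (1 - kCases))
  crit <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(z - crit) + stats::pnorm(-z - crit)
}

#' Detectable odds-ratio interval at a target power
#'
#' Solves, on each side of the null OR = 1, for the odds ratio at which
#' [mrPowerBinary()] reaches `targetPower`; effects inside the interval are
#' underpowered at the given design. Roots are found by bisection on the
#' log-OR scale to machine tolerance.
#'
#' @inheritParams mrPowerBinary
#' @param targetPower default 0.80.
#' @return named numeric `c(orLow, orHigh)` with `orLow < 1 < orHigh`.
#' @export
detectableORInterval <- function(n, kCases, r2, alpha = 0.05,
                                 targetPower = 0.80) {
  stopifnot(targetPower > alpha, targetPower < 1)
  f <- function(b) mrPowerBinary(n, kCases, r2, exp(b), alpha) - targetPower
  upper <- 1
  while (f(upper) < 0) upper <- upper * 2
  bHigh <- stats::uniroot(f, c(0, upper), tol = 1e-12)$root
  bLow <- stats::uniroot(function(b) f(-b), c(0, upper), tol = 1e-12)$root
  c(orLow = exp(-bLow), orHigh = exp(bHigh))
}
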