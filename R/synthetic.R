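# Non-palindromic allele pairs assigned to simulated variants, so default
# fixtures survive the palindrome filter unless one is injected on purpose.
.SAFE_ALLELES <- rbind(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"),
                       c("A", "C"), c("G", "T"))

.pvalFromZ <- function(beta, se)
  pmax(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin)

.gwasFrame <- function(snp, chrom, pos, ea, oa, eaf, beta, se, n) {
  data.frame(snp = snp, chrom = as.character(chrom), pos = pos,
             effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta, se = se, pval = .pvalFromZ(beta, se),
             n = n, hwe_p = NA_real_, stringsAsFactors = FALSE)
}

#' Simulate two-sample GWAS summary statistics with known truth
#'
#' Generates matched exposure and outcome summary-statistic tables linked by
#' a linear causal effect with optional (possibly directional, possibly
#' InSIDE-violating) horizontal pleiotropy, directly at the summary level:
#' per variant k, a true exposure effect `gamma_k ~ Normal(gammaMean,
#' gammaSd^2)`, a direct outcome effect
#' `alpha_k = pleiotropyMean + pleiotropySd * (rho * z_gamma_k +
#' sqrt(1 - rho^2) * eps_k)` (so `alpha` has the requested mean/sd and
#' correlation `rho = insideViolation` with instrument strength), a total
#' outcome effect `Gamma_k = theta * gamma_k + alpha_k`, and observed effects
#' `beta_x ~ Normal(gamma_k, se_x^2)`, `beta_y ~ Normal(Gamma_k, se_y^2)`
#' with SEs drawn uniformly from the given ranges. p-values are computed from
#' beta/se so records are internally consistent for the selection filters.
#'
#' Defaults emulate the forward study design that motivated the package:
#' 13 already-selected instruments with exposure F-statistics around 30-60
#' (genome-wide significant), suggestive-level outcome standard errors, and
#' no causal effect.
#'
#' @param nSnp number of instruments, default 13.
#' @param theta true causal effect on the log-OR scale, default 0.
#' @param gammaMean,gammaSd distribution of true variant-exposure effects,
#'   defaults 0.12 and 0.03 (log-odds). A vector `gammaFixed` overrides the
#'   draw.
#' @param gammaFixed optional fixed vector of true exposure effects.
#' @param pleiotropyMean,pleiotropySd mean and sd of direct effects
#'   `alpha_k`, defaults 0 (no pleiotropy).
#' @param insideViolation correlation in `[-1, 1]` between `alpha_k` and
#'   `gamma_k`; nonzero values break the InSIDE assumption that MR-Egger
#'   relies on. Requires `gammaSd > 0` when nonzero.
#' @param seXRange,seYRange uniform sampling ranges for the exposure and
#'   outcome standard errors, defaults `c(0.016, 0.022)` and
#'   `c(0.025, 0.045)`.
#' @param eafRange uniform range of effect-allele frequencies, default
#'   `c(0.10, 0.90)`.
#' @param nExposure,nOutcome sample sizes written into the tables, defaults
#'   25295 and 34615.
#' @param outcomeEaf whether outcome records carry allele frequencies
#'   (default TRUE; set FALSE to emulate a frequency-stripped outcome
#'   deposit).
#' @param seed integer seed; identical seeds give identical output.
#' @return list with `exposure` and `outcome` (validated GWAS data.frames)
#'   and `truth` (list: `gamma`, `alpha`, `Gamma`, `theta`, config echo).
#' @export
simulateTwoSample <- function(nSnp = 13, theta = 0,
                              gammaMean = 0.12, gammaSd = 0.03,
                              gammaFixed = NULL,
                              pleiotropyMean = 0, pleiotropySd = 0,
                              insideViolation = 0,
                              seXRange = c(0.016, 0.022),
                              seYRange = c(0.025, 0.045),
                              eafRange = c(0.10, 0.90),
                              nExposure = 25295, nOutcome = 34615,
                              outcomeEaf = TRUE, seed = NULL) {
  stopifnot(nSnp >= 1, gammaSd >= 0, pleiotropySd >= 0,
            abs(insideViolation) <= 1,
            length(seXRange) == 2, length(seYRange) == 2)
  if (insideViolation != 0 && is.null(gammaFixed) && gammaSd == 0)
    stop("insideViolation requires variation in gamma (gammaSd > 0)",
         call. = FALSE)
  withSeed(seed, {
    gamma <- if (!is.null(gammaFixed)) {
      stopifnot(length(gammaFixed) == nSnp)
      as.numeric(gammaFixed)
    } else stats::rnorm(nSnp, gammaMean, gammaSd)
    zg <- if (is.null(gammaFixed)) {
      if (gammaSd > 0) (gamma - gammaMean) / gammaSd else rep(0, nSnp)
    } else if (stats::sd(gamma) > 0) {
      (gamma - mean(gamma)) / stats::sd(gamma)
    } else rep(0, nSnp)
    rho <- insideViolation
    alpha <- pleiotropyMean +
      pleiotropySd * (rho * zg + sqrt(1 - rho^2) * stats::rnorm(nSnp))
    Gamma <- theta * gamma + alpha
    sx <- stats::runif(nSnp, seXRange[1], seXRange[2])
    sy <- stats::runif(nSnp, seYRange[1], seYRange[2])
    bx <- stats::rnorm(nSnp, gamma, sx)
    by <- stats::rnorm(nSnp, Gamma, sy)
    eaf <- stats::runif(nSnp, eafRange[1], eafRange[2])
    alle <- .SAFE_ALLELES[((seq_len(nSnp) - 1L) %% nrow(.SAFE_ALLELES)) + 1L,
                          , drop = FALSE]
    # one locus per variant: chromosomes cycle 1..22, positions > 1 Mb apart
    chrom <- ((seq_len(nSnp) - 1L) %% 22L) + 1L
    pos <- 1e6 + 3e6 * ((seq_len(nSnp) - 1L) %/% 22L + 1L) +
      17L * seq_len(nSnp)
    snp <- sprintf("rs%06d", seq_len(nSnp))
    exposure <- .gwasFrame(snp, chrom, pos, alle[, 1], alle[, 2], eaf,
                           bx, sx, nExposure)
    outcome <- .gwasFrame(snp, chrom, pos, alle[, 1], alle[, 2],
                          if (outcomeEaf) eaf else NA_real_,
                          by, sy, nOutcome)
    list(exposure = .validateGwasTable(exposure),
         outcome = .validateGwasTable(outcome),
         truth = list(gamma = gamma, alpha = alpha, Gamma = Gamma,
                      theta = theta, pleiotropyMean = pleiotropyMean,
                      pleiotropySd = pleiotropySd,
                      insideViolation = insideViolation, seed = seed))
  })
}

#' Simulate a single LD-structured locus
#'
#' A toy locus for exercising the clumping rules: `nSnp` variants on one
#' chromosome spread evenly over `spanBp`, with pairwise r-squared decaying
#' exponentially in distance, `r2 = exp(-decay * distance_kb)`, and distinct
#' p-values so greedy clumping has a unique answer.
#'
#' @param nSnp number of variants (>= 1).
#' @param decay r-squared decay rate per kb (0 = complete LD everywhere;
#'   large = independence).
#' @param spanBp locus width in base pairs, default 500000.
#' @param chrom chromosome label, default "1".
#' @param seed seed controlling the p-value assignment.
#' @return list with `records` (GWAS data.frame) and `ld` ([LdTable-class]).
#' @export
simulateLdLocus <- function(nSnp, decay, spanBp = 5e5, chrom = "1",
                            seed = NULL) {
  stopifnot(nSnp >= 1, decay >= 0, spanBp > 0)
  pos <- round(seq(1e6, 1e6 + spanBp, length.out = nSnp))
  pairs <- which(upper.tri(matrix(0, nSnp, nSnp)), arr.ind = TRUE)
  distKb <- abs(pos[pairs[, 1]] - pos[pairs[, 2]]) / 1000
  snp <- sprintf("loc%03d", seq_len(nSnp))
  ld <- ldTable(snp[pairs[, 1]], snp[pairs[, 2]], exp(-decay * distKb))
  withSeed(seed, {
    # distinct, shuffled significance so the greedy winner is unambiguous
    z <- sample(seq(6, 6 + nSnp - 1))
    se <- rep(0.02, nSnp)
    beta <- z * se
    records <- .gwasFrame(snp, chrom, pos, "A", "G",
                          stats::runif(nSnp, 0.1, 0.9), beta, se, 25000)
    list(records = .validateGwasTable(records), ld = ld)
  })
}
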