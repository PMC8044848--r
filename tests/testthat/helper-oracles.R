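# Independent oracles used across test files. These deliberately take a
# different computational route from the package (lm fits, explicit loops)
# so they can catch algebra mistakes in the implementation.

# IVW slope as weighted least squares through the origin, via lm().
oracleIVWBeta <- function(bx, by, sy) {
  unname(coef(lm(by ~ bx - 1, weights = 1 / sy^2)))
}

# Egger slope/intercept and their unit-variance SEs via lm(); lm scales SEs
# by the residual sigma, so divide it out to recover the unit SEs.
oracleEgger <- function(bx, by, sy) {
  s <- ifelse(bx < 0, -1, 1)
  fit <- lm((s * by) ~ I(s * bx), weights = 1 / sy^2)
  sm <- summary(fit)
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       seUnit = unname(sm$coefficients[, "Std. Error"]) / sm$sigma,
       sigma = sm$sigma)
}

# Brute-force interpolated weighted median: explicit loop over the sorted
# ratios, linear interpolation between bracketing cumulative percentiles.
oracleWeightedMedian <- function(theta, w) {
  o <- order(theta)
  theta <- theta[o]; w <- w[o] / sum(w)
  p <- numeric(length(w))
  run <- 0
  for (i in seq_along(w)) {
    p[i] <- run + w[i] / 2
    run <- run + w[i]
  }
  if (p[1] >= 0.5) return(theta[1])
  if (p[length(p)] <= 0.5) return(theta[length(theta)])
  i <- max(which(p < 0.5))
  theta[i] + (theta[i + 1] - theta[i]) * (0.5 - p[i]) / (p[i + 1] - p[i])
}

# Cochran's Q by direct summation.
oracleQ <- function(bx, by, sy) {
  theta <- by / bx
  w <- bx^2 / sy^2
  thIVW <- sum(w * theta) / sum(w)
  sum(w * (theta - thIVW)^2)
}

# Brute-force greedy clumping over explicit pair checks.
oracleClumpIds <- function(records, ld, r2Max = 0.01, windowBp = 1e6) {
  o <- order(records$pval, records$chrom, records$pos)
  kept <- integer()
  for (i in o) {
    ok <- TRUE
    for (j in kept) {
      same <- identical(records$chrom[i], records$chrom[j])
      near <- same && abs(records$pos[i] - records$pos[j]) <= windowBp
      if (near && ldR2(ld, records$snp[i], records$snp[j]) > r2Max)
        ok <- FALSE
    }
    if (ok) kept <- c(kept, i)
  }
  sort(records$snp[kept])
}

# The standard 3-instrument fixture used in several files.
fixture3 <- function() {
  harmonizedSet(betaX = c(0.2, 0.4, 0.5), seX = c(0.01, 0.01, 0.01),
                betaY = c(0.10, 0.18, 0.25), seY = c(0.05, 0.10, 0.20))
}

# A small GWAS data.frame builder with sensible defaults.
gwasRows <- function(snp, ..., eaf = 0.3, beta = 0.1, se = 0.02,
                     pval = 1e-9, chrom = "1", pos = NA, ea = "A", oa = "G",
                     n = 25000, hwe_p = NA) {
  k <- length(snp)
  if (all(is.na(pos))) pos <- seq(1e6, by = 5e6, length.out = k)
  data.frame(snp = snp, chrom = rep_len(chrom, k), pos = rep_len(pos, k),
             effect_allele = rep_len(ea, k), other_allele = rep_len(oa, k),
             eaf = rep_len(eaf, k), beta = rep_len(beta, k),
             se = rep_len(se, k), pval = rep_len(pval, k),
             n = rep_len(n, k), hwe_p = rep_len(hwe_p, k),
             stringsAsFactors = FALSE)
}
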