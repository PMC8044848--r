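test_that("Wald ratio follows the first-order formulas", {
  w <- waldRatio(harmonizedSet(0.5, 0.01, 0.25, 0.1))
  expect_equal(mrBeta(w), 0.5)
  expect_equal(mrSE(w), 0.2)

  neg <- waldRatio(harmonizedSet(-0.5, 0.01, 0.25, 0.1))
  expect_equal(mrBeta(neg), -0.5)
  expect_equal(mrSE(neg), 0.2)   # SE uses |beta_x|

  null <- waldRatio(harmonizedSet(0.5, 0.01, 0, 0.1))
  expect_equal(mrBeta(null), 0)
  expect_equal(pValue(null), 1)

  expect_error(waldRatio(harmonizedSet(0, 0.01, 0.1, 0.1)), "zero")
})

test_that("IVW reproduces direct summation and the WLS-through-origin fit", {
  hs <- fixture3()
  est <- mrIVW(hs)
  # direct summation oracle
  wy <- 1 / seY(hs)^2
  expect_equal(mrBeta(est),
               sum(betaX(hs) * betaY(hs) * wy) / sum(betaX(hs)^2 * wy),
               tolerance = 1e-12)
  expect_equal(mrSE(est), sqrt(1 / sum(betaX(hs)^2 * wy)), tolerance = 1e-12)
  # frozen values computed from the summation oracle
  expect_equal(mrBeta(est), 0.4790849673202614, tolerance = 1e-10)
  expect_equal(mrSE(est), 0.1616904166908887, tolerance = 1e-10)
  # equivalent to weighted least squares through the origin
  expect_equal(mrBeta(est), oracleIVWBeta(betaX(hs), betaY(hs), seY(hs)),
               tolerance = 1e-10)
  # CI and OR are consistent views
  expect_equal(confint(est), mrBeta(est) + c(-1, 1) * 1.96 * mrSE(est))
  expect_equal(oddsRatio(est), exp(mrBeta(est)))

  # single instrument reduces exactly to the Wald ratio
  one <- mrIVW(hs[2])
  wr <- waldRatio(hs[2])
  expect_identical(mrBeta(one), mrBeta(wr))
  expect_identical(mrSE(one), mrSE(wr))

  expect_error(mrIVW(harmonizedSet(numeric(), numeric(), numeric(),
                                   numeric())), "at least 1")
})

test_that("IVW beta is scale-free in the outcome SEs; fixed SE scales", {
  hs <- fixture3()
  for (c0 in c(0.5, 2, 7)) {
    scaled <- harmonizedSet(betaX(hs), seX(hs), betaY(hs), c0 * seY(hs))
    expect_equal(mrBeta(mrIVW(scaled)), mrBeta(mrIVW(hs)), tolerance = 1e-12)
    expect_equal(mrSE(mrIVW(scaled)), c0 * mrSE(mrIVW(hs)), tolerance = 1e-12)
  }
})

test_that("random-effects IVW inflates the SE by sqrt(max(1, Q/df))", {
  hs <- fixture3()
  fx <- mrIVW(hs); re <- mrIVW(hs, model = "multiplicative_random")
  expect_equal(mrBeta(re), mrBeta(fx))
  q <- cochranQ(hs)@q
  expect_equal(mrSE(re), mrSE(fx) * sqrt(max(1, q / 2)), tolerance = 1e-12)
  # under-dispersed data never deflate the SE
  expect_gte(mrSE(re), mrSE(fx))
})

test_that("Egger matches the weighted normal-equations oracle", {
  # exact line: slope and intercept recovered, no residual inflation
  bx <- c(0.1, 0.2, 0.3, 0.4)
  line <- harmonizedSet(bx, rep(0.01, 4), 0.02 + 0.5 * bx, rep(0.05, 4))
  e0 <- mrEgger(line)
  expect_equal(mrBeta(e0), 0.5, tolerance = 1e-10)
  expect_equal(e0@extras$intercept, 0.02, tolerance = 1e-10)
  expect_equal(e0@extras$inflation, 1)

  # noisy fixture with residual sigma > 1: matches lm() exactly
  hs <- harmonizedSet(c(0.12, 0.21, 0.33, 0.45),
                      c(0.02, 0.02, 0.02, 0.02),
                      c(0.30, 0.01, 0.25, 0.09),
                      c(0.04, 0.05, 0.06, 0.04))
  est <- mrEgger(hs)
  orc <- oracleEgger(betaX(hs), betaY(hs), seY(hs))
  expect_gt(orc$sigma, 1)
  expect_equal(mrBeta(est), orc$slope, tolerance = 1e-10)
  expect_equal(est@extras$intercept, orc$intercept, tolerance = 1e-10)
  expect_equal(mrSE(est), orc$seUnit[2] * orc$sigma, tolerance = 1e-10)
  expect_equal(est@extras$interceptSE, orc$seUnit[1] * orc$sigma,
               tolerance = 1e-10)
  # t p-values at k - 2 df
  expect_equal(pValue(est),
               2 * pt(-abs(mrBeta(est) / mrSE(est)), df = 2),
               tolerance = 1e-12)

  expect_error(mrEgger(fixture3()[1:2]), "at least 3")
})

test_that("weighted median interpolates the 50% weight percentile", {
  # all ratios equal: estimate is that ratio, whatever the weights
  const <- harmonizedSet(c(0.2, 0.4, 0.8), rep(0.01, 3),
                         0.3 * c(0.2, 0.4, 0.8), c(0.02, 0.05, 0.11))
  expect_equal(mrBeta(weightedMedian(const, nBoot = 50, seed = 1)), 0.3,
               tolerance = 1e-12)

  # equal weights, ratios 0.1/0.2/0.3 -> 0.2
  eq <- harmonizedSet(c(1, 1, 1), rep(0.01, 3), c(0.1, 0.2, 0.3),
                      rep(0.1, 3))
  expect_equal(mrBeta(weightedMedian(eq, nBoot = 50, seed = 1)), 0.2)

  # brute-force oracle agreement on uneven weights
  hs <- harmonizedSet(c(0.2, 0.35, 0.5, 0.15, 0.4),
                      rep(0.01, 5),
                      c(0.05, 0.12, 0.2, 0.02, 0.11),
                      c(0.03, 0.08, 0.02, 0.05, 0.04))
  theta <- betaY(hs) / betaX(hs)
  w <- betaX(hs)^2 / seY(hs)^2
  est <- weightedMedian(hs, nBoot = 50, seed = 1)
  expect_equal(mrBeta(est), oracleWeightedMedian(theta, w),
               tolerance = 1e-10)
  # the estimate lies inside the ratio range
  expect_gte(mrBeta(est), min(theta))
  expect_lte(mrBeta(est), max(theta))

  # identical seed -> identical bootstrap SE; different seed differs
  expect_identical(mrSE(weightedMedian(hs, nBoot = 200, seed = 7)),
                   mrSE(weightedMedian(hs, nBoot = 200, seed = 7)))
  expect_false(identical(mrSE(weightedMedian(hs, nBoot = 200, seed = 7)),
                         mrSE(weightedMedian(hs, nBoot = 200, seed = 8))))
})

test_that("weighted median resists a minority of pleiotropic outliers", {
  bx <- rep(0.2, 9)
  by <- c(rep(0.06, 7), 0.6, 0.6)      # 7 valid (ratio 0.3), 2 at ratio 3
  hs <- harmonizedSet(bx, rep(0.01, 9), by, rep(0.05, 9))
  wm <- weightedMedian(hs, nBoot = 200, seed = 2)
  ivw <- mrIVW(hs)
  expect_lt(abs(mrBeta(wm) - 0.3), 0.05)
  expect_gt(mrBeta(ivw), 0.4)          # IVW is dragged by the outliers
})

test_that("estimates are invariant to per-variant allele reorientation", {
  sim <- simulateTwoSample(nSnp = 8, theta = 0.25, seed = 31)
  hs <- harmonizeSets(sim$exposure, sim$outcome)
  flip <- c(2, 5, 7)
  sgn <- rep(1, 8); sgn[flip] <- -1
  hsF <- harmonizedSet(sgn * betaX(hs), seX(hs), sgn * betaY(hs), seY(hs))
  expect_equal(mrBeta(mrIVW(hsF)), mrBeta(mrIVW(hs)), tolerance = 1e-12)
  expect_equal(mrSE(mrIVW(hsF)), mrSE(mrIVW(hs)), tolerance = 1e-12)
  expect_equal(mrBeta(mrEgger(hsF)), mrBeta(mrEgger(hs)), tolerance = 1e-12)
  expect_equal(mrEgger(hsF)@extras$intercept, mrEgger(hs)@extras$intercept,
               tolerance = 1e-12)
  expect_equal(mrBeta(weightedMedian(hsF, nBoot = 10, seed = 1)),
               mrBeta(weightedMedian(hs, nBoot = 10, seed = 1)),
               tolerance = 1e-12)
})

test_that("all methods recover the causal effect in the noiseless limit", {
  sim <- simulateTwoSample(nSnp = 6, theta = 0.3,
                           pleiotropyMean = 0, pleiotropySd = 0,
                           seXRange = c(1e-9, 1e-9),
                           seYRange = c(1e-9, 1e-9), seed = 12)
  expect_equal(sim$outcome$beta / sim$exposure$beta, rep(0.3, 6),
               tolerance = 1e-6)
  hs <- harmonizeSets(sim$exposure, sim$outcome)
  expect_equal(mrBeta(mrIVW(hs)), 0.3, tolerance = 1e-6)
  expect_equal(mrBeta(mrEgger(hs)), 0.3, tolerance = 1e-6)
  expect_equal(mrBeta(weightedMedian(hs, nBoot = 20, seed = 1)), 0.3,
               tolerance = 1e-6)
  expect_equal(mrBeta(waldRatio(hs[1])), 0.3, tolerance = 1e-6)
})
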