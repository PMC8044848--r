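expRec <- function(ea = "A", oa = "G", eaf = 0.2, beta = 0.1, se = 0.02,
                   snp = "rs1")
  gwasRows(snp, ea = ea, oa = oa, eaf = eaf, beta = beta, se = se)

outRec <- function(ea = "A", oa = "G", eaf = 0.2, beta = 0.05, se = 0.03,
                   snp = "rs1")
  gwasRows(snp, ea = ea, oa = oa, eaf = eaf, beta = beta, se = se)

test_that("pairwise harmonization resolves swaps and strand flips", {
  same <- harmonizePair(expRec(), outRec())
  expect_equal(betaY(same), 0.05)
  expect_equal(same@action, "unchanged")

  swapped <- harmonizePair(expRec(), outRec(ea = "G", oa = "A"))
  expect_equal(betaY(swapped), -0.05)
  expect_equal(swapped@action, "sign_flipped")

  flipped <- harmonizePair(expRec(), outRec(ea = "T", oa = "C"))
  expect_equal(betaY(flipped), 0.05)
  expect_equal(flipped@action, "strand_flipped")

  both <- harmonizePair(expRec(), outRec(ea = "C", oa = "T"))
  expect_equal(betaY(both), -0.05)
  expect_equal(both@action, "strand_flipped_and_signed")

  mismatch <- harmonizePair(expRec(), outRec(ea = "A", oa = "C"))
  expect_equal(length(mismatch), 0L)
  expect_equal(droppedVariants(mismatch)$reason, "allele mismatch")

  expect_error(harmonizePair(expRec(snp = "rs1"), outRec(snp = "rs2")),
               "different variants")
})

test_that("palindromic pairs follow the requested policy", {
  ex <- expRec(ea = "A", oa = "T", eaf = 0.20)

  dropped <- harmonizePair(ex, outRec(ea = "A", oa = "T", eaf = 0.78))
  expect_equal(length(dropped), 0L)
  expect_match(droppedVariants(dropped)$reason, "palindromic")

  # frequency inference: exposure frequency 0.20 vs outcome 0.78 means the
  # two studies report opposite orientations -> sign flip
  inferred <- harmonizePair(ex, outRec(ea = "A", oa = "T", eaf = 0.78),
                            palindromePolicy = "infer_by_frequency")
  expect_equal(betaY(inferred), -0.05)

  concordant <- harmonizePair(ex, outRec(ea = "A", oa = "T", eaf = 0.22),
                              palindromePolicy = "infer_by_frequency")
  expect_equal(betaY(concordant), 0.05)

  # both frequencies near 0.5: ambiguous, dropped
  amb <- harmonizePair(expRec(ea = "A", oa = "T", eaf = 0.48),
                       outRec(ea = "A", oa = "T", eaf = 0.52),
                       palindromePolicy = "infer_by_frequency")
  expect_equal(length(amb), 0L)

  # outcome frequency missing: cannot infer
  nofreq <- harmonizePair(ex, outRec(ea = "A", oa = "T", eaf = NA),
                          palindromePolicy = "infer_by_frequency")
  expect_equal(length(nofreq), 0L)

  fwd <- harmonizePair(ex, outRec(ea = "T", oa = "A", eaf = 0.78),
                       palindromePolicy = "assume_forward")
  expect_equal(betaY(fwd), -0.05)
})

test_that("harmonization is idempotent and never changes magnitudes", {
  cases <- list(outRec(), outRec(ea = "G", oa = "A"),
                outRec(ea = "T", oa = "C"), outRec(ea = "C", oa = "T"))
  for (out in cases) {
    h <- harmonizePair(expRec(), out)
    expect_equal(abs(betaY(h)), abs(out$beta))
    expect_equal(seY(h), out$se)
    expect_equal(abs(betaX(h)), 0.1)
    # re-harmonizing the harmonized orientation is a no-op
    out2 <- out
    out2$effect_allele <- "A"; out2$other_allele <- "G"
    out2$beta <- betaY(h)
    h2 <- harmonizePair(expRec(), out2)
    expect_equal(betaY(h2), betaY(h))
    expect_equal(h2@action, "unchanged")
  }
})

test_that("set harmonization preserves order, drops and proxies correctly", {
  sim <- simulateTwoSample(nSnp = 13, seed = 5)
  hs <- harmonizeSets(sim$exposure, sim$outcome,
                      exposureLabel = "E", outcomeLabel = "O")
  expect_equal(length(hs), 13L)
  expect_equal(nrow(droppedVariants(hs)), 0L)
  expect_equal(snpIds(hs), sim$exposure$snp)

  # two variants absent from the outcome, no LD: dropped with reason
  out2 <- sim$outcome[-c(3, 7), ]
  hs2 <- harmonizeSets(sim$exposure, out2)
  expect_equal(length(hs2), 11L)
  expect_equal(droppedVariants(hs2)$snp, sim$exposure$snp[c(3, 7)])
  expect_true(all(droppedVariants(hs2)$reason == "absent from outcome"))

  # empty outcome: everything dropped
  hs3 <- harmonizeSets(sim$exposure, sim$outcome[0, ])
  expect_equal(length(hs3), 0L)
  expect_equal(nrow(droppedVariants(hs3)), 13L)

  # a proxy in strong LD substitutes for a missing variant when the proxy
  # has its own exposure record
  expFull <- rbind(sim$exposure,
                   gwasRows("rsPROX", ea = "A", oa = "G", beta = 0.15,
                            se = 0.02, pval = 1e-9, chrom = "9", pos = 2e6))
  outP <- rbind(out2, gwasRows("rsPROX", ea = "A", oa = "G", beta = 0.04,
                               se = 0.03, pval = 0.01, chrom = "9", pos = 2e6))
  ld <- ldTable(sim$exposure$snp[3], "rsPROX", 0.95)
  hs4 <- harmonizeSets(sim$exposure, outP, ld = ld, exposureFull = expFull)
  expect_equal(length(hs4), 12L)
  i <- match(sim$exposure$snp[3], snpIds(hs4))
  expect_equal(hs4@action[i], "proxy_substituted:rsPROX")
  expect_equal(betaX(hs4)[i], 0.15)  # the proxy's own exposure effect
  expect_equal(betaY(hs4)[i], 0.04)

  # without an exposure record for the proxy, the instrument is dropped
  hs5 <- harmonizeSets(sim$exposure, outP, ld = ld)
  expect_match(droppedVariants(hs5)$reason[1], "lacks an exposure record")
})
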