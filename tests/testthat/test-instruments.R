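test_that("eligibility filters apply MAF, HWE and significance rules", {
  # 10 variants, three violating exactly one rule each
  tab <- gwasRows(sprintf("v%02d", 1:10))
  tab$eaf[2] <- 0.995                 # MAF 0.005 < 0.01
  tab$hwe_p <- 0.5
  tab$hwe_p[5] <- 1e-6                # fails HWE
  tab$pval[8] <- 1e-4                 # fails significance
  res <- filterVariants(tab, pMax = 5e-8)
  expect_setequal(res$records$snp, setdiff(tab$snp, c("v02", "v05", "v08")))
  expect_equal(sum(!res$log$pass), 3L)
  expect_equal(nrow(res$log), 30L)    # every variant logged once per rule

  # boundary p-value is retained (inclusive threshold)
  tabB <- gwasRows("b1", pval = 5e-8)
  expect_equal(filterVariants(tabB, pMax = 5e-8)$records$snp, "b1")

  # missing eaf / hwe_p: rule skipped, not failed
  tabM <- gwasRows("m1", eaf = NA)
  resM <- filterVariants(tabM, pMax = 5e-8)
  expect_equal(resM$records$snp, "m1")
  expect_match(resM$log$detail[resM$log$rule == "maf"], "skipped")
})

test_that("ambiguous palindromes are excluded, others retained", {
  tab <- gwasRows(c("rs853854", "x1", "x2", "x3"),
                  ea = c("A", "A", "C", "A"), oa = c("T", "G", "G", "T"),
                  eaf = c(0.499, 0.499, 0.10, NA))
  res <- excludePalindromes(tab)
  # rs853854 (A/T, frequency 0.499) is the canonical ambiguous case
  expect_false("rs853854" %in% res$records$snp)
  expect_true("x1" %in% res$records$snp)   # not palindromic
  expect_true("x2" %in% res$records$snp)   # palindromic but MAF <= 0.45
  expect_false("x3" %in% res$records$snp)  # palindrome without frequency
  expect_match(res$log$detail[res$log$snp == "x3"], "frequency unavailable")
})

test_that("greedy clumping keeps the most significant variant per locus", {
  two <- gwasRows(c("a", "b"), pos = c(1e6, 1e6 + 1e4),
                  pval = c(1e-10, 1e-8))
  ld <- ldTable("a", "b", 0.5)
  expect_equal(ldClump(two, ld)$snp, "a")

  # independent variants all survive
  expect_equal(nrow(ldClump(two, ldTable("a", "b", 0.001))), 2L)
  expect_equal(nrow(ldClump(two, NULL)), 2L)

  # outside the 1 Mb window, LD is ignored
  far <- gwasRows(c("a", "b"), pos = c(1e6, 1e6 + 1.5e6),
                  pval = c(1e-10, 1e-8))
  expect_equal(nrow(ldClump(far, ld)), 2L)

  # 5-variant chain with links A-B and B-C only: matches brute force
  chain <- gwasRows(c("A", "B", "C", "D", "E"),
                    pos = seq(1e6, by = 1e4, length.out = 5),
                    pval = c(1e-8, 1e-12, 1e-9, 1e-10, 1e-11))
  ldc <- ldTable(c("A", "B"), c("B", "C"), c(0.8, 0.8))
  got <- ldClump(chain, ldc)
  expect_equal(sort(got$snp), oracleClumpIds(chain, ldc))
  expect_equal(sort(got$snp), c("B", "D", "E"))  # hand enumeration
})

test_that("clumping is order-invariant and never keeps a violating pair", {
  for (seed in 1:5) {
    loc <- simulateLdLocus(12, decay = 0.02, spanBp = 4e5, seed = seed)
    base <- ldClump(loc$records, loc$ld)
    shuf <- withr::with_seed(seed + 100,
      loc$records[sample.int(nrow(loc$records)), ])
    expect_equal(ldClump(shuf, loc$ld)$snp, base$snp)
    # brute-force check of the pairwise invariant
    if (nrow(base) > 1) {
      pairs <- combn(nrow(base), 2)
      for (p in seq_len(ncol(pairs))) {
        i <- pairs[1, p]; j <- pairs[2, p]
        near <- identical(base$chrom[i], base$chrom[j]) &&
          abs(base$pos[i] - base$pos[j]) <= 1e6
        expect_false(near && ldR2(loc$ld, base$snp[i], base$snp[j]) > 0.01)
      }
    }
    expect_equal(sort(base$snp), oracleClumpIds(loc$records, loc$ld))
  }
})

test_that("proxy search returns the best available variant above 0.8", {
  ld <- ldTable(c("t", "t", "t"), c("p1", "p2", "p3"), c(0.85, 0.95, 0.80))
  expect_equal(findProxy("t", ld, c("p1", "p2", "p3")), "p2")
  expect_equal(findProxy("t", ld, c("p1", "p3")), "p1")
  # r2 of exactly 0.8 is not enough (strict inequality)
  expect_true(is.na(findProxy("t", ld, "p3")))
  expect_true(is.na(findProxy("t", ld, character())))
})

test_that("variance explained and F-statistic follow the stated formulas", {
  expect_equal(varianceExplained(0.5, 1), 0.5)
  expect_equal(varianceExplained(0.3, 0), 0)
  expect_equal(varianceExplained(0.3, 0.05), 0.00105)
  # symmetric in eaf vs 1 - eaf, maximal at 0.5
  eafs <- seq(0.05, 0.95, by = 0.05)
  expect_equal(varianceExplained(eafs, 0.2), varianceExplained(1 - eafs, 0.2))
  expect_equal(which.max(varianceExplained(eafs, 0.2)),
               which(eafs == 0.5))
  expect_error(varianceExplained(NA, 0.1), "reference")

  expect_equal(fStatistic(0.5, 4), 2)
  expect_equal(fStatistic(0, 1000), 0)
  # strictly increasing in r2 and n
  expect_true(all(diff(fStatistic(seq(0, 0.9, 0.1), 100)) > 0))
  expect_true(fStatistic(0.1, 2000) > fStatistic(0.1, 1000))
  expect_error(fStatistic(1, 100), "\\[0, 1\\)")
  expect_error(fStatistic(0.1, 2), "exceed 2")

  st <- instrumentStats(gwasRows(c("a", "b"), eaf = c(0.3, NA),
                                 beta = c(0.1, 0.2)),
                        n = 25295, refEaf = c(NA, 0.25))
  expect_equal(st$r2[2], 2 * 0.25 * 0.75 * 0.04)
  expect_true(all(st$f_stat == fStatistic(st$r2, 25295)))
})
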