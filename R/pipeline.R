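.stage <- function(log, stage, nIn, nOut, detail = "") {
  rbind(log, data.frame(stage = stage, n_in = nIn, n_out = nOut,
                        detail = detail, stringsAsFactors = FALSE))
}

#' Run one direction of an MR study
#'
#' Full pipeline for one exposure -> outcome direction: significance/MAF/HWE
#' filtering, palindrome exclusion, greedy LD clumping, harmonization against
#' the outcome dataset (with proxy search when an LD table is supplied),
#' causal estimation (fixed-effect IVW as the primary method, plus MR-Egger,
#' weighted median and MR-PRESSO where the instrument count allows),
#' heterogeneity and pleiotropy diagnostics, and — when the outcome case
#' fraction is known — the detectable-OR power interval. Every stage is
#' logged with input/output counts so instrument attrition is auditable.
#'
#' @param exposure,outcome validated GWAS data.frames.
#' @param ld optional [LdTable-class] used for clumping and proxy search.
#' @param pMax exposure significance threshold (inclusive), default 5e-8.
#' @param mafMin,hwePMin,palMafCutoff QC thresholds (see [filterVariants()],
#'   [excludePalindromes()]).
#' @param clumpR2,clumpWindowBp clumping thresholds (see [ldClump()]).
#' @param palindromePolicy,freqWindow harmonization policy (see
#'   [harmonizePair()]).
#' @param nSim MR-PRESSO simulations; `nBoot` weighted-median bootstraps.
#' @param nBoot bootstrap replicates for the weighted median.
#' @param seed integer seed governing every stochastic step.
#' @param alphaFamily,nTests family-wise alpha and number of tests; the
#'   primary IVW p-value is flagged against `alphaFamily / nTests`
#'   (Bonferroni).
#' @param kCasesOutcome outcome-study case fraction for the power analysis
#'   (`NULL` skips it).
#' @param targetPower power level for the detectable-OR interval,
#'   default 0.80.
#' @param exposureLabel,outcomeLabel trait names for reporting.
#' @return a [DirectionReport-class].
#' @export
runDirection <- function(exposure, outcome, ld = NULL,
                         pMax = 5e-8, mafMin = 0.01, hwePMin = 1e-4,
                         palMafCutoff = 0.45, clumpR2 = 0.01,
                         clumpWindowBp = 1e6, palindromePolicy = "drop",
                         freqWindow = 0.08, nSim = 1000, nBoot = 1000,
                         seed = 1, alphaFamily = 0.05, nTests = 2,
                         kCasesOutcome = NULL, targetPower = 0.80,
                         exposureLabel = "exposure",
                         outcomeLabel = "outcome") {
  log <- data.frame()
  n0 <- nrow(exposure)
  filt <- filterVariants(exposure, mafMin = mafMin, hwePMin = hwePMin,
                         pMax = pMax)
  log <- .stage(log, "filter_variants", n0, nrow(filt$records),
                sprintf("p<=%g, maf>=%g, hwe_p>=%g", pMax, mafMin, hwePMin))
  pal <- excludePalindromes(filt$records, mafCutoff = palMafCutoff)
  log <- .stage(log, "exclude_palindromes", nrow(filt$records),
                nrow(pal$records), sprintf("maf cutoff %g", palMafCutoff))
  clumped <- ldClump(pal$records, ld, r2Max = clumpR2,
                     windowBp = clumpWindowBp)
  log <- .stage(log, "ld_clump", nrow(pal$records), nrow(clumped),
                sprintf("r2>%g within %g bp", clumpR2, clumpWindowBp))
  if (nrow(clumped) == 0L) {
    empty <- log$stage[which(log$n_out == 0)[1]]
    stop("no instruments survive stage '", empty, "'", call. = FALSE)
  }
  hs <- harmonizeSets(clumped, outcome, ld = ld,
                      palindromePolicy = palindromePolicy,
                      freqWindow = freqWindow,
                      exposureLabel = exposureLabel,
                      outcomeLabel = outcomeLabel)
  log <- .stage(log, "harmonize", nrow(clumped), length(hs),
                if (nrow(hs@dropped))
                  paste(hs@dropped$snp, hs@dropped$reason, collapse = "; ")
                else "")
  if (length(hs) == 0L)
    stop("no instruments survive stage 'harmonize'", call. = FALSE)

  ests <- list(ivw_fixed = mrIVW(hs))
  if (length(hs) >= 3L) {
    ests$egger <- mrEgger(hs)
    ests$weighted_median <- weightedMedian(hs, nBoot = nBoot, seed = seed)
  } else {
    log <- .stage(log, "estimate", length(hs), length(hs),
                  "fewer than 3 instruments: Egger and weighted median skipped")
  }
  sens <- sensitivityReport(hs, nSim = nSim, seed = seed)
  if (!is.null(sens@presso)) {
    ests$presso_raw <- sens@presso@raw
    if (!is.null(sens@presso@corrected))
      ests$presso_corrected <- sens@presso@corrected
  }

  power <- list()
  if (!is.null(kCasesOutcome)) {
    eafForR2 <- clumped$eaf[clumped$snp %in% hs@snp]
    betaForR2 <- clumped$beta[clumped$snp %in% hs@snp]
    nOut <- suppressWarnings(max(outcome$n, na.rm = TRUE))
    if (!any(is.na(eafForR2)) && is.finite(nOut)) {
      r2 <- sum(varianceExplained(eafForR2, betaForR2))
      ci <- detectableORInterval(nOut, kCasesOutcome, r2,
                                 alpha = alphaFamily,
                                 targetPower = targetPower)
      power <- list(n = nOut, kCases = kCasesOutcome, r2 = r2,
                    alpha = alphaFamily, targetPower = targetPower,
                    orLow = unname(ci["orLow"]), orHigh = unname(ci["orHigh"]))
    } else {
      log <- .stage(log, "power", length(hs), length(hs),
                    "skipped: missing eaf or outcome sample size")
    }
  }

  bonf <- alphaFamily / nTests
  config <- list(pMax = pMax, mafMin = mafMin, hwePMin = hwePMin,
                 palMafCutoff = palMafCutoff, clumpR2 = clumpR2,
                 clumpWindowBp = clumpWindowBp,
                 palindromePolicy = palindromePolicy, nSim = nSim,
                 nBoot = nBoot, seed = seed, alphaFamily = alphaFamily,
                 nTests = nTests, bonferroni = bonf)
  new("DirectionReport", exposureLabel = exposureLabel,
      outcomeLabel = outcomeLabel, harmonized = hs, estimates = ests,
      sensitivity = sens, power = power, log = log,
      significant = ests$ivw_fixed@pvalue < bonf, config = config)
}

#' Run a bidirectional MR study
#'
#' Runs [runDirection()] in both directions with direction-specific
#' significance thresholds (the reverse direction typically uses a suggestive
#' threshold when the trait has no genome-wide significant loci) and applies
#' a Bonferroni correction across the two primary tests.
#'
#' @param tableA,tableB validated GWAS data.frames for the two traits.
#' @param labelA,labelB trait names.
#' @param ld optional [LdTable-class] shared by both directions.
#' @param pMaxAB threshold for selecting A-instruments (A -> B direction),
#'   default 5e-8.
#' @param pMaxBA threshold for selecting B-instruments (B -> A), default
#'   5e-6.
#' @param kCasesA,kCasesB case fractions of the two studies, enabling the
#'   power analysis of the direction in which each is the outcome.
#' @param seed integer seed; the reverse direction uses `seed + 1`.
#' @param alphaFamily,nTests Bonferroni family settings (defaults 0.05, 2).
#' @param ... further arguments passed to both [runDirection()] calls.
#' @return a [StudyReport-class].
#' @export
runBidirectional <- function(tableA, tableB, labelA = "traitA",
                             labelB = "traitB", ld = NULL,
                             pMaxAB = 5e-8, pMaxBA = 5e-6,
                             kCasesA = NULL, kCasesB = NULL, seed = 1,
                             alphaFamily = 0.05, nTests = 2, ...) {
  fwd <- runDirection(tableA, tableB, ld = ld, pMax = pMaxAB, seed = seed,
                      alphaFamily = alphaFamily, nTests = nTests,
                      kCasesOutcome = kCasesB,
                      exposureLabel = labelA, outcomeLabel = labelB, ...)
  rev <- runDirection(tableB, tableA, ld = ld, pMax = pMaxBA,
                      seed = seed + 1L,
                      alphaFamily = alphaFamily, nTests = nTests,
                      kCasesOutcome = kCasesA,
                      exposureLabel = labelB, outcomeLabel = labelA, ...)
  new("StudyReport", forward = fwd, reverse = rev,
      bonferroni = alphaFamily / nTests,
      config = list(seed = seed, pMaxAB = pMaxAB, pMaxBA = pMaxBA,
                    alphaFamily = alphaFamily, nTests = nTests,
                    labels = c(labelA, labelB)))
}
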