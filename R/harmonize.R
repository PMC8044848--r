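.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Construct a harmonized instrument set directly
#'
#' For estimator input built in code (e.g. from an already harmonized
#' table) rather than via [harmonizeSets()].
#'
#' @param snp variant ids (defaults to `snp1..snpK`).
#' @param betaX,seX variant-exposure effects (log-odds) and SEs.
#' @param betaY,seY variant-outcome effects on the same effect allele and SEs.
#' @param exposureLabel,outcomeLabel trait names.
#' @return a [HarmonizedSet-class].
#' @export
harmonizedSet <- function(betaX, seX, betaY, seY,
                          snp = paste0("snp", seq_along(betaX),
                                       recycle0 = TRUE),
                          exposureLabel = "exposure",
                          outcomeLabel = "outcome") {
  new("HarmonizedSet", snp = as.character(snp),
      betaX = as.numeric(betaX), seX = as.numeric(seX),
      betaY = as.numeric(betaY), seY = as.numeric(seY),
      action = rep("constructed", length(betaX)),
      exposureLabel = exposureLabel, outcomeLabel = outcomeLabel)
}

# Align one outcome record onto the exposure record's effect allele.
# Returns list(betaY, seY, action) or list(reason = ...).
.alignPair <- function(exposure, outcome, palindromePolicy, freqWindow) {
  eaX <- exposure$effect_allele; oaX <- exposure$other_allele
  eaY <- outcome$effect_allele;  oaY <- outcome$other_allele
  pal <- .isPalindromic(eaX, oaX)

  if (pal) {
    # For a palindrome the strand-flipped alleles coincide with the swapped
    # alleles, so orientation cannot be read off the allele labels.
    if (!setequal(c(eaX, oaX), c(eaY, oaY)))
      return(list(reason = "allele mismatch"))
    if (palindromePolicy == "drop")
      return(list(reason = "palindromic (policy drop)"))
    if (palindromePolicy == "assume_forward") {
      flip <- eaY != eaX
      return(list(betaY = if (flip) -outcome$beta else outcome$beta,
                  seY = outcome$se,
                  action = if (flip) "sign_flipped" else "unchanged"))
    }
    # infer_by_frequency
    fx <- exposure$eaf; fy <- outcome$eaf
    if (is.na(fx) || is.na(fy))
      return(list(reason = "palindromic, frequency unavailable"))
    if (abs(fx - 0.5) < freqWindow && abs(fy - 0.5) < freqWindow)
      return(list(reason = "palindromic, frequency ambiguous"))
    fySame <- if (eaY == eaX) fy else 1 - fy     # freq of the exposure EA
    if (abs(fx - fySame) <= abs(fx - (1 - fySame))) {
      flip <- eaY != eaX
    } else {
      flip <- eaY == eaX                         # opposite orientation wins
    }
    return(list(betaY = if (flip) -outcome$beta else outcome$beta,
                seY = outcome$se,
                action = if (flip) "sign_flipped" else "unchanged"))
  }

  strandFlipped <- FALSE
  if (!setequal(c(eaY, oaY), c(eaX, oaX))) {
    eaYc <- unname(.COMPLEMENT[eaY]); oaYc <- unname(.COMPLEMENT[oaY])
    if (setequal(c(eaYc, oaYc), c(eaX, oaX))) {
      eaY <- eaYc; oaY <- oaYc; strandFlipped <- TRUE
    } else {
      return(list(reason = "allele mismatch"))
    }
  }
  if (eaY == eaX && oaY == oaX) {
    list(betaY = outcome$beta, seY = outcome$se,
         action = if (strandFlipped) "strand_flipped" else "unchanged")
  } else if (eaY == oaX && oaY == eaX) {
    list(betaY = -outcome$beta, seY = outcome$se,
         action = if (strandFlipped) "strand_flipped_and_signed"
                  else "sign_flipped")
  } else {
    list(reason = "allele mismatch")
  }
}

#' Harmonize one exposure/outcome record pair
#'
#' Expresses the outcome effect on the exposure record's effect allele,
#' resolving allele swaps (sign flip), strand flips (complementary alleles),
#' and palindromic pairs according to `palindromePolicy`. Magnitudes of
#' effects and standard errors are never altered — only signs and provenance
#' labels.
#'
#' @param exposure,outcome single GWAS records (one-row data.frames or lists
#'   with the canonical fields) for the same variant.
#' @param palindromePolicy `"drop"` (default; the outcome study may carry no
#'   allele frequencies, making inference impossible), `"infer_by_frequency"`
#'   (orient by allele-frequency concordance; drop when both frequencies are
#'   within `freqWindow` of 0.5 or the outcome frequency is missing), or
#'   `"assume_forward"` (trust the reported strands).
#' @param freqWindow half-width of the ambiguity zone around 0.5 for
#'   frequency inference, default 0.08.
#' @return a one-instrument [HarmonizedSet-class]; when the pair is dropped
#'   the set has zero instruments and one `dropped` row giving the reason.
#' @export
harmonizePair <- function(exposure, outcome,
                          palindromePolicy = c("drop", "infer_by_frequency",
                                               "assume_forward"),
                          freqWindow = 0.08) {
  palindromePolicy <- match.arg(palindromePolicy)
  exposure <- as.list(exposure); outcome <- as.list(outcome)
  if (!identical(as.character(exposure$snp), as.character(outcome$snp)))
    stop("exposure and outcome records are for different variants (",
         exposure$snp, " vs ", outcome$snp, ")", call. = FALSE)
  res <- .alignPair(exposure, outcome, palindromePolicy, freqWindow)
  if (!is.null(res$reason))
    return(new("HarmonizedSet", snp = character(), betaX = numeric(),
               seX = numeric(), betaY = numeric(), seY = numeric(),
               action = character(),
               dropped = data.frame(snp = as.character(exposure$snp),
                                    reason = res$reason,
                                    stringsAsFactors = FALSE)))
  new("HarmonizedSet", snp = as.character(exposure$snp),
      betaX = exposure$beta, seX = exposure$se,
      betaY = res$betaY, seY = res$seY, action = res$action)
}

#' Harmonize selected instruments against an outcome dataset
#'
#' For each exposure instrument: a direct identifier match is harmonized with
#' [harmonizePair()]; when the variant is absent from the outcome table and
#' an LD table is supplied, a proxy with r-squared > `r2Min` is substituted
#' (the proxy's own exposure record must be available in `exposureFull`,
#' otherwise the instrument is dropped); otherwise the instrument is dropped
#' with reason `"absent from outcome"`. Output preserves exposure order.
#'
#' @param exposure data.frame of selected exposure instruments.
#' @param outcome data.frame of outcome summary statistics.
#' @param ld optional [LdTable-class] for proxy search.
#' @param palindromePolicy,freqWindow see [harmonizePair()].
#' @param r2Min minimum proxy r-squared (strict), default 0.8.
#' @param exposureFull optional wider exposure table in which proxies' own
#'   exposure records are looked up (defaults to `exposure`).
#' @param exposureLabel,outcomeLabel trait names carried into the result.
#' @return a [HarmonizedSet-class].
#' @export
harmonizeSets <- function(exposure, outcome, ld = NULL,
                          palindromePolicy = "drop", freqWindow = 0.08,
                          r2Min = 0.8, exposureFull = exposure,
                          exposureLabel = "exposure",
                          outcomeLabel = "outcome") {
  snp <- character(); bX <- sX <- bY <- sY <- numeric(); act <- character()
  dropped <- data.frame(snp = character(), reason = character(),
                        stringsAsFactors = FALSE)
  outIdx <- function(id) match(id, outcome$snp)
  for (i in seq_len(nrow(exposure))) {
    id <- exposure$snp[i]
    j <- outIdx(id)
    expRec <- exposure[i, , drop = FALSE]
    proxyNote <- NULL
    if (is.na(j) && !is.null(ld)) {
      proxy <- findProxy(id, ld, outcome$snp, r2Min = r2Min)
      if (!is.na(proxy)) {
        k <- match(proxy, exposureFull$snp)
        if (is.na(k)) {
          dropped <- rbind(dropped, data.frame(
            snp = id, reason = sprintf("proxy %s lacks an exposure record", proxy),
            stringsAsFactors = FALSE))
          next
        }
        expRec <- exposureFull[k, , drop = FALSE]
        j <- outIdx(proxy)
        proxyNote <- proxy
      }
    }
    if (is.na(j)) {
      dropped <- rbind(dropped, data.frame(snp = id,
        reason = "absent from outcome", stringsAsFactors = FALSE))
      next
    }
    one <- harmonizePair(expRec, outcome[j, , drop = FALSE],
                         palindromePolicy, freqWindow)
    if (length(one) == 0L) {
      d <- one@dropped; d$snp <- id
      dropped <- rbind(dropped, d)
    } else {
      snp <- c(snp, id)
      bX <- c(bX, one@betaX); sX <- c(sX, one@seX)
      bY <- c(bY, one@betaY); sY <- c(sY, one@seY)
      act <- c(act, if (is.null(proxyNote)) one@action
                    else paste0("proxy_substituted:", proxyNote))
    }
  }
  new("HarmonizedSet", snp = snp, betaX = bX, seX = sX, betaY = bY, seY = sY,
      action = act, dropped = dropped,
      exposureLabel = exposureLabel, outcomeLabel = outcomeLabel)
}
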