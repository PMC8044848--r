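.logRow <- function(snp, rule, pass, detail = "") {
  if (length(snp) == 0L)
    return(data.frame(snp = character(), rule = character(),
                      pass = logical(), detail = character(),
                      stringsAsFactors = FALSE))
  data.frame(snp = snp, rule = rule, pass = pass, detail = detail,
             stringsAsFactors = FALSE)
}

#' Significance / MAF / Hardy-Weinberg instrument filters
#'
#' Applies the instrument eligibility rules to a GWAS table: minor-allele
#' frequency at least `mafMin` (MAF = `min(eaf, 1 - eaf)`), Hardy-Weinberg
#' test p-value at least `hwePMin`, association p-value at most `pMax`
#' (boundary inclusive). When a record lacks `eaf` or `hwe_p` the respective
#' rule is skipped for that record and logged as such — it does not fail.
#'
#' @param records validated GWAS data.frame (see [readGwasTable()]).
#' @param mafMin minimum minor-allele frequency, default 0.01.
#' @param hwePMin minimum Hardy-Weinberg p-value, default 1e-4.
#' @param pMax significance threshold (e.g. 5e-8 genome-wide, 5e-6
#'   suggestive).
#' @return list with `records` (survivors, original order) and `log`
#'   (data.frame `snp, rule, pass, detail`; every input variant appears once
#'   per rule).
#' @export
filterVariants <- function(records, mafMin = 0.01, hwePMin = 1e-4,
                           pMax = 5e-8) {
  maf <- pmin(records$eaf, 1 - records$eaf)
  mafKnown <- !is.na(maf)
  mafPass <- !mafKnown | maf >= mafMin
  hweKnown <- !is.na(records$hwe_p)
  hwePass <- !hweKnown | records$hwe_p >= hwePMin
  pPass <- records$pval <= pMax
  log <- rbind(
    .logRow(records$snp, "maf", mafPass,
            ifelse(!mafKnown, "skipped: eaf missing",
                   sprintf("maf=%.4g (min %.4g)", maf, mafMin))),
    .logRow(records$snp, "hwe", hwePass,
            ifelse(!hweKnown, "skipped: hwe_p missing",
                   sprintf("hwe_p=%.4g (min %.4g)", records$hwe_p, hwePMin))),
    .logRow(records$snp, "pval", pPass,
            sprintf("pval=%.4g (max %.4g)", records$pval, pMax)))
  keep <- mafPass & hwePass & pPass
  list(records = records[keep, , drop = FALSE], log = log)
}

.isPalindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Exclude strand-ambiguous palindromic variants
#'
#' A/T and C/G variants cannot be strand-resolved from alleles alone; when
#' their minor-allele frequency is close to 0.5 frequency matching cannot
#' resolve them either. Palindromes with MAF above `mafCutoff` are removed
#' (e.g. rs853854, A/T with allele frequency 0.499, in the PCOS instrument
#' selection), as are palindromes with no frequency at all.
#'
#' @param records validated GWAS data.frame.
#' @param mafCutoff MAF above which a palindrome is ambiguous, default 0.45.
#' @return list with `records` (survivors) and `log`.
#' @export
excludePalindromes <- function(records, mafCutoff = 0.45) {
  pal <- .isPalindromic(records$effect_allele, records$other_allele)
  maf <- pmin(records$eaf, 1 - records$eaf)
  noFreq <- pal & is.na(maf)
  ambiguous <- pal & !is.na(maf) & maf > mafCutoff
  keep <- !(noFreq | ambiguous)
  detail <- rep("not palindromic", nrow(records))
  detail[pal] <- sprintf("palindrome, maf=%.4g (cutoff %.4g)",
                         maf[pal], mafCutoff)
  detail[noFreq] <- "frequency unavailable"
  list(records = records[keep, , drop = FALSE],
       log = .logRow(records$snp, "palindrome", keep, detail))
}

#' Greedy LD clumping
#'
#' Retains the most significant variant per locus: variants are visited in
#' ascending p-value order (ties broken by chromosome then position, so the
#' result is independent of input row order) and accepted unless an
#' already-accepted variant lies on the same chromosome within `windowBp`
#' (closed interval) with pairwise r-squared above `r2Max`.
#'
#' @param records validated GWAS data.frame with `chrom`, `pos`, `pval`.
#' @param ld an [LdTable-class] or `NULL` (no LD: everything is retained).
#' @param r2Max exclusion threshold, default 0.01 (exclude when r2 > 0.01).
#' @param windowBp window size in base pairs, default 1e6 (1 Mb).
#' @return the surviving records, sorted by (chrom, pos).
#' @export
ldClump <- function(records, ld = NULL, r2Max = 0.01, windowBp = 1e6) {
  if (nrow(records) == 0L) return(records)
  o <- order(records$pval, records$chrom, records$pos)
  accepted <- integer()
  for (i in o) {
    conflict <- FALSE
    for (j in accepted) {
      if (!identical(records$chrom[j], records$chrom[i])) next
      if (is.na(records$pos[i]) || is.na(records$pos[j])) next
      if (abs(records$pos[i] - records$pos[j]) > windowBp) next
      if (ldR2(ld, records$snp[i], records$snp[j]) > r2Max) {
        conflict <- TRUE; break
      }
    }
    if (!conflict) accepted <- c(accepted, i)
  }
  out <- records[accepted, , drop = FALSE]
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Find an LD proxy in another dataset
#'
#' Returns the identifier of the available variant in highest LD with
#' `snpId`, provided its r-squared strictly exceeds `r2Min`; `NA` otherwise
#' (the caller then drops the instrument).
#'
#' @param snpId the missing variant.
#' @param ld an [LdTable-class].
#' @param available character vector of variant ids present in the other
#'   dataset.
#' @param r2Min minimum (strict) r-squared, default 0.8.
#' @return a single variant id, or `NA_character_`.
#' @export
findProxy <- function(snpId, ld, available, r2Min = 0.8) {
  cand <- sort(setdiff(as.character(available), snpId))
  if (length(cand) == 0L || is.null(ld)) return(NA_character_)
  r2 <- ldR2(ld, snpId, cand)
  best <- which.max(r2)
  if (r2[best] > r2Min) cand[best] else NA_character_
}

#' Variance in liability explained by one variant
#'
#' `2 * MAF * (1 - MAF) * beta^2`, with MAF = `min(eaf, 1 - eaf)`.
#'
#' @param eaf effect-allele frequency (vectorized); must be present — supply
#'   a reference-panel frequency when the dataset has none.
#' @param beta per-allele effect (log-odds).
#' @return per-variant r-squared contribution.
#' @export
varianceExplained <- function(eaf, beta) {
  if (any(is.na(eaf)))
    stop("eaf is missing; supply a reference allele frequency", call. = FALSE)
  if (any(eaf < 0 | eaf > 1)) stop("eaf must lie in [0, 1]", call. = FALSE)
  maf <- pmin(eaf, 1 - eaf)
  2 * maf * (1 - maf) * beta^2
}

#' Instrument-strength F-statistic
#'
#' `F = r2 * (n - 2) / (1 - r2)`; values below 10 conventionally flag a weak
#' instrument.
#'
#' @param r2 proportion of variance explained, in `[0, 1)` (vectorized).
#' @param n total sample size of the study the variant was estimated in
#'   (> 2).
#' @return F statistic(s).
#' @export
fStatistic <- function(r2, n) {
  if (any(is.na(r2) | r2 < 0 | r2 >= 1))
    stop("r2 must lie in [0, 1)", call. = FALSE)
  if (any(is.na(n) | n <= 2)) stop("n must exceed 2", call. = FALSE)
  r2 * (n - 2) / (1 - r2)
}

#' Per-instrument strength summary
#'
#' Convenience wrapper computing, for each record, the variance explained and
#' F-statistic, with a weak-instrument flag at F < 10.
#'
#' @param records validated GWAS data.frame with `eaf` present (or `refEaf`
#'   supplied).
#' @param n sample size used in the F formula.
#' @param refEaf optional replacement frequencies (e.g. 1000 Genomes EUR)
#'   for records whose own `eaf` is missing.
#' @return data.frame `snp, r2, f_stat, weak`.
#' @export
instrumentStats <- function(records, n, refEaf = NULL) {
  eaf <- records$eaf
  if (!is.null(refEaf)) eaf[is.na(eaf)] <- refEaf[is.na(eaf)]
  r2 <- varianceExplained(eaf, records$beta)
  f <- fStatistic(r2, n)
  data.frame(snp = records$snp, r2 = r2, f_stat = f, weak = f < 10,
             stringsAsFactors = FALSE)
}
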