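#' Canonical GWAS summary-statistic columns
#'
#' Internal canonical schema: `snp`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`, `hwe_p`. `beta` is the
#' log-odds change per additional effect allele; `eaf`, `n` and `hwe_p` may be
#' absent (the shared periodontitis dataset, for instance, has allele
#' frequencies removed).
#'
#' @keywords internal
.GWAS_COLUMNS <- c("snp", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pval", "n", "hwe_p")
.GWAS_REQUIRED <- c("snp", "effect_allele", "other_allele", "beta", "se", "pval")

# Row-level validation shared by the reader and the simulator output checks.
# Returns the cleaned data.frame or stops with row-numbered diagnostics.
.validateGwasTable <- function(df) {
  problems <- character()
  bad <- function(rows, why) {
    if (any(rows, na.rm = TRUE))
      problems <<- c(problems, paste0(why, " (row ",
        paste(which(rows), collapse = ", "), ")"))
  }
  df$snp <- as.character(df$snp)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  bad(is.na(df$snp) | !nzchar(df$snp), "empty snp identifier")
  if (anyDuplicated(df$snp))
    problems <- c(problems, paste0("duplicated snp identifier(s): ",
      paste(unique(df$snp[duplicated(df$snp)]), collapse = ", ")))
  bad(!(df$effect_allele %in% c("A", "C", "G", "T")), "effect_allele not in A/C/G/T")
  bad(!(df$other_allele %in% c("A", "C", "G", "T")), "other_allele not in A/C/G/T")
  bad(df$effect_allele == df$other_allele, "effect and other allele identical")
  for (col in c("eaf", "beta", "se", "pval", "n", "hwe_p", "pos"))
    if (!col %in% names(df)) df[[col]] <- NA_real_
  df$beta <- as.numeric(df$beta); df$se <- as.numeric(df$se)
  df$pval <- as.numeric(df$pval); df$eaf <- as.numeric(df$eaf)
  df$n <- as.numeric(df$n); df$hwe_p <- as.numeric(df$hwe_p)
  df$pos <- as.numeric(df$pos)
  if (!"chrom" %in% names(df)) df$chrom <- NA_character_
  df$chrom <- as.character(df$chrom)
  bad(is.na(df$beta), "missing beta")
  bad(is.na(df$se) | df$se <= 0, "se must be > 0")
  bad(is.na(df$pval) | df$pval <= 0 | df$pval > 1, "pval must lie in (0, 1]")
  bad(!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1), "eaf must lie in [0, 1]")
  bad(!is.na(df$hwe_p) & (df$hwe_p <= 0 | df$hwe_p > 1), "hwe_p must lie in (0, 1]")
  bad(!is.na(df$pos) & (df$pos < 1 | df$pos != floor(df$pos)),
      "pos must be a positive 1-based integer")
  if (length(problems))
    stop("invalid GWAS rows:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  rownames(df) <- NULL
  df[, .GWAS_COLUMNS]
}

#' Read a GWAS summary-statistic table
#'
#' Reads a delimited text table of per-variant association summaries, maps
#' arbitrary source headers onto the canonical schema, upper-cases alleles and
#' validates every row (see Details). Row order is preserved.
#'
#' @details Canonical columns are `snp`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta` (log-odds per effect allele), `se`, `pval`,
#'   `n`, `hwe_p`. Required: snp, alleles, beta, se, pval; the rest may be
#'   missing and are filled with `NA`. Validation rejects non-ACGT alleles,
#'   identical allele pairs, `se <= 0`, `pval` outside (0, 1], `eaf` outside
#'   [0, 1] and duplicated identifiers, reporting the offending row numbers.
#'
#' @param path file path.
#' @param columnMap named character vector mapping canonical names to source
#'   column headers, e.g. `c(snp = "MarkerName", beta = "Effect", ...)`.
#'   Canonical names absent from the map are taken verbatim when present in
#'   the file.
#' @param sep field delimiter (default tab).
#' @param header logical; the file has a header line (default TRUE).
#' @return a validated data.frame in canonical column order.
#' @export
readGwasTable <- function(path, columnMap = character(), sep = "\t",
                          header = TRUE) {
  raw <- utils::read.table(path, sep = sep, header = header,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "")
  if (length(columnMap)) {
    unknown <- setdiff(names(columnMap), .GWAS_COLUMNS)
    if (length(unknown))
      stop("columnMap names not in canonical schema: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    missing <- setdiff(unname(columnMap), names(raw))
    if (length(missing))
      stop("mapped column(s) absent from file: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (canon in .GWAS_COLUMNS) {
    src <- if (canon %in% names(columnMap)) columnMap[[canon]] else canon
    if (src %in% names(raw)) out[[canon]] <- raw[[src]]
  }
  missingReq <- setdiff(.GWAS_REQUIRED, names(out))
  if (length(missingReq))
    stop("required column(s) not found (map them via columnMap): ",
         paste(missingReq, collapse = ", "), call. = FALSE)
  .validateGwasTable(out)
}

#' Construct an LD table
#'
#' @param snpA,snpB character vectors of variant ids (one pair per element).
#' @param r2 squared correlations in `[0, 1]`.
#' @return an [LdTable-class].
#' @export
ldTable <- function(snpA = character(), snpB = character(), r2 = numeric()) {
  a <- pmin(as.character(snpA), as.character(snpB))
  b <- pmax(as.character(snpA), as.character(snpB))
  key <- paste(a, b)
  keep <- !duplicated(key)
  new("LdTable", snpA = a[keep], snpB = b[keep], r2 = as.numeric(r2)[keep])
}

#' Read a pairwise LD table
#'
#' Three-column delimited text (`snp_a`, `snp_b`, `r2`). The table is
#' symmetric by construction; duplicated pairs must agree on r-squared.
#'
#' @param path file path.
#' @param sep delimiter (default tab).
#' @param header logical (default TRUE).
#' @return an [LdTable-class].
#' @export
readLdTable <- function(path, sep = "\t", header = TRUE) {
  if (file.size(path) == 0L) return(ldTable())  # every query then returns 0
  raw <- utils::read.table(path, sep = sep, header = header,
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) return(ldTable())
  if (ncol(raw) < 3L) stop("LD table needs 3 columns (snp_a, snp_b, r2)",
                           call. = FALSE)
  r2 <- as.numeric(raw[[3]])
  if (any(is.na(r2) | r2 < 0 | r2 > 1))
    stop("r2 outside [0, 1] at row(s) ",
         paste(which(is.na(r2) | r2 < 0 | r2 > 1), collapse = ", "),
         call. = FALSE)
  a <- pmin(as.character(raw[[1]]), as.character(raw[[2]]))
  b <- pmax(as.character(raw[[1]]), as.character(raw[[2]]))
  key <- paste(a, b)
  if (anyDuplicated(key)) {
    for (k in unique(key[duplicated(key)])) {
      vals <- r2[key == k]
      if (diff(range(vals)) > 1e-12)
        stop("conflicting r2 for pair ", k, ": ",
             paste(unique(vals), collapse = " vs "), call. = FALSE)
    }
    keep <- !duplicated(key)
    a <- a[keep]; b <- b[keep]; r2 <- r2[keep]
  }
  new("LdTable", snpA = a, snpB = b, r2 = r2)
}

#' Look up pairwise r-squared
#'
#' Vectorized symmetric lookup; absent pairs return 0 and `a == b` returns 1.
#'
#' @param ld an [LdTable-class] (or `NULL`, meaning no LD anywhere).
#' @param a,b variant identifiers (recycled to common length).
#' @return numeric vector of r-squared values.
#' @export
ldR2 <- function(ld, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n); b <- rep_len(as.character(b), n)
  out <- numeric(n)
  out[a == b] <- 1
  if (!is.null(ld) && length(ld@r2)) {
    key <- paste(pmin(a, b), pmax(a, b))
    hit <- match(key, paste(ld@snpA, ld@snpB))
    found <- !is.na(hit) & a != b
    out[found] <- ld@r2[hit[found]]
  }
  out
}

setMethod("show", "LdTable", function(object) {
  cat(sprintf("LdTable with %d pair(s)\n", length(object@r2)))
  invisible(object)
})

# Full-precision numeric formatting so written tables round-trip exactly.
.fmtNum <- function(x) {
  if (is.numeric(x)) vapply(x, function(v)
    if (is.na(v)) "NA" else sprintf("%.17g", v), character(1)) else x
}

.writeTsv <- function(df, path) {
  out <- as.data.frame(lapply(df, .fmtNum), stringsAsFactors = FALSE,
                       check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a per-direction analysis report
#'
#' Emits a machine-readable bundle under `dir`: `estimates.tsv` (one row per
#' method; deterministic column order `method, n_snp, beta, se, ci_low,
#' ci_high, pvalue, or`), `leave_one_out.tsv`, `funnel.tsv`, and
#' `summary.json` holding the scalar diagnostics (Cochran's Q, Egger
#' intercept, MR-PRESSO global test, power interval). Numeric fields are
#' written at full precision and round-trip exactly.
#'
#' @param estimates a non-empty list of [MREstimate-class] objects (or a
#'   [DirectionReport-class], in which case `sensitivity` is taken from it).
#' @param sensitivity a [SensitivityReport-class] or `NULL`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeDirectionReport <- function(estimates, sensitivity = NULL, dir) {
  power <- list()
  if (is(estimates, "DirectionReport")) {
    sensitivity <- estimates@sensitivity
    power <- estimates@power
    estimates <- estimates@estimates
  }
  if (!is.list(estimates) || length(estimates) == 0L)
    stop("at least one estimate is required", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory ", dir, call. = FALSE)
  paths <- file.path(dir, c("estimates.tsv", "leave_one_out.tsv",
                            "funnel.tsv", "summary.json"))
  .writeTsv(estimateTable(unname(estimates)), paths[1])
  summary <- list()
  if (!is.null(sensitivity)) {
    if (nrow(sensitivity@leaveOneOut)) .writeTsv(sensitivity@leaveOneOut, paths[2])
    if (nrow(sensitivity@funnel)) .writeTsv(sensitivity@funnel, paths[3])
    if (!is.null(sensitivity@heterogeneity)) {
      h <- sensitivity@heterogeneity
      summary$cochran_q <- list(q = h@q, df = h@df, pvalue = h@pvalue)
    }
    if (!is.null(sensitivity@presso)) {
      p <- sensitivity@presso
      summary$mr_presso <- list(rss_obs = p@rssObs, global_p = p@globalP,
                                n_sim = p@nSim, outliers = p@outliers,
                                distortion_p = p@distortionP)
    }
  }
  for (e in estimates)
    if (is(e, "MREstimate") && e@method == "egger")
      summary$egger_intercept <- e@extras[c("intercept", "interceptSE",
                                            "interceptP")]
  if (length(power)) summary$power <- power
  jsonlite::write_json(summary, paths[4], auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(paths)
}
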