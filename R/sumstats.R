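#' GWAS summary-statistic set
#'
#' One trait-by-cohort GWAS as a validated table of per-variant records.
#' Effects are per standard deviation of the (rank-normalized) trait for
#' quantitative traits and log-odds for binary traits.
#'
#' @param records Data frame with columns `variant_id`, `chrom`, `pos`
#'   (1-based), `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `pvalue`, `n` and optionally `z`.
#' @param trait_id Trait identifier (e.g. cytokine name).
#' @param cohort_id Cohort identifier.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param validate Drop rows violating the record invariants (logged via
#'   `message()`)? Default `TRUE`.
#'
#' @return Object of class `sumstats_set`: list with `trait_id`,
#'   `cohort_id`, `trait_type`, `genome_build` (fixed `"GRCh37"`) and
#'   `records`.
#' @export
sumstats_set <- function(records, trait_id, cohort_id,
                         trait_type = c("quantitative", "binary"),
                         validate = TRUE) {
  trait_type <- match.arg(trait_type)
  records <- as.data.frame(records)
  need <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
            "eaf", "beta", "se", "pvalue", "n")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing required column(s): ",
                         paste(miss, collapse = ", "))
  if (!"z" %in% names(records)) records$z <- records$beta / records$se
  records$z[is.na(records$z)] <- (records$beta / records$se)[is.na(records$z)]
  records$effect_allele <- toupper(records$effect_allele)
  records$other_allele <- toupper(records$other_allele)
  if (validate) records <- validate_records(records)
  if (anyDuplicated(records$variant_id)) stop("variant_id must be unique within a sumstats_set")
  structure(list(trait_id = trait_id, cohort_id = cohort_id,
                 trait_type = trait_type, genome_build = "GRCh37",
                 records = records),
            class = "sumstats_set")
}

#' @export
print.sumstats_set <- function(x, ...) {
  cat("<sumstats_set> ", x$trait_id, " x ", x$cohort_id, " (", x$trait_type,
      "): ", nrow(x$records), " variants\n", sep = "")
  invisible(x)
}

# Enforce per-record invariants; invalid rows are dropped with a message
# giving the count (never silently).
validate_records <- function(records) {
  ok <- rep(TRUE, nrow(records))
  ok <- ok & !is.na(records$variant_id) & nzchar(records$variant_id)
  ok <- ok & !is.na(records$pos) & records$pos >= 1
  ok <- ok & grepl("^[ACGT]+$", records$effect_allele) &
    grepl("^[ACGT]+$", records$other_allele) &
    records$effect_allele != records$other_allele
  ok <- ok & !is.na(records$eaf) & records$eaf > 0 & records$eaf < 1
  ok <- ok & !is.na(records$se) & records$se > 0
  ok <- ok & !is.na(records$pvalue) & records$pvalue > 0 & records$pvalue <= 1
  ok <- ok & !is.na(records$n) & records$n > 0
  # consistency of p with beta/se (allow modest rounding slack)
  has <- ok & !is.na(records$beta)
  zp <- suppressWarnings(z_from_p(pmin(records$pvalue[has], 1),
                                  ifelse(records$beta[has] >= 0, 1, -1)))
  dev <- abs(zp - records$beta[has] / records$se[has])
  bad <- rep(FALSE, nrow(records))
  bad[which(has)[!is.na(dev) & dev > 0.05]] <- TRUE
  ok <- ok & !bad
  n_drop <- sum(!ok)
  if (n_drop > 0) message("validate_records: dropped ", n_drop, " invalid row(s)")
  out <- records[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_drop
  out
}

#' Signed z-score from a two-sided p-value
#'
#' `z = sign * qnorm(1 - p/2)`, evaluated in log space so that p-values
#' near the double-precision underflow limit stay finite. p-values that
#' underflow to zero cannot be recovered and are rejected.
#'
#' @param pvalue Two-sided p-value(s) in `(0, 1]`.
#' @param sign Direction of effect, `+1` or `-1` (vectorized).
#'
#' @return Signed z-score(s).
#' @examples
#' z_from_p(0.05, 1)   #  1.959964
#' z_from_p(0.05, -1)  # -1.959964
#' @export
z_from_p <- function(pvalue, sign = 1) {
  if (any(is.na(pvalue)) || any(pvalue <= 0) || any(pvalue > 1)) {
    stop("pvalue must lie in (0, 1]")
  }
  if (!all(sign %in% c(-1, 1))) stop("sign must be -1 or +1")
  # log-space quantile: log(p/2) stays finite for p down to ~5e-324
  z <- stats::qnorm(log(pvalue) - log(2), lower.tail = FALSE, log.p = TRUE)
  sign * z
}

sumstats_columns <- c(SNP = "variant_id", CHR = "chrom", BP = "pos",
                      EA = "effect_allele", OA = "other_allele",
                      EAF = "eaf", BETA = "beta", SE = "se",
                      P = "pvalue", N = "n", Z = "z")

#' Read GWAS summary statistics from a TSV file
#'
#' Expects the tab-separated dialect `SNP CHR BP EA OA EAF BETA SE P N
#' [Z]` with `"."` for missing values; gzip-compressed files are read
#' transparently. Rows failing validation are dropped with a logged
#' count.
#'
#' @param path File path (optionally `.gz`).
#' @param trait_id,cohort_id,trait_type Metadata for the returned set.
#' @param column_map Optional named character vector mapping the dialect
#'   names (`SNP`, `CHR`, ...) to the actual column headers in the file.
#'
#' @return A [sumstats_set].
#' @export
read_sumstats <- function(path, trait_id = "trait", cohort_id = "cohort",
                          trait_type = "quantitative", column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  df <- utils::read.table(con, header = TRUE, sep = "\t", na.strings = ".",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0) stop("empty summary-statistics file: ", path)
  lookup <- sumstats_columns
  if (!is.null(column_map)) {
    names(lookup)[match(names(column_map), names(lookup))] <- unname(column_map)
  }
  required <- setdiff(names(lookup), "Z")
  miss <- setdiff(required, names(df))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  keep <- intersect(names(lookup), names(df))
  records <- df[keep]
  names(records) <- unname(lookup[keep])
  sumstats_set(records, trait_id, cohort_id, trait_type)
}

#' Write GWAS summary statistics to a TSV file
#'
#' Inverse of [read_sumstats()]; numeric fields are written with 10
#' significant digits so the round trip is lossless at that precision.
#'
#' @param x A [sumstats_set].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  stopifnot(inherits(x, "sumstats_set"))
  r <- x$records
  out <- data.frame(SNP = r$variant_id, CHR = r$chrom, BP = r$pos,
                    EA = r$effect_allele, OA = r$other_allele,
                    EAF = sprintf("%.10g", r$eaf),
                    BETA = sprintf("%.10g", r$beta),
                    SE = sprintf("%.10g", r$se),
                    P = sprintf("%.10g", r$pvalue),
                    N = sprintf("%.10g", r$n),
                    Z = sprintf("%.10g", r$z),
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

allele_complement <- function(a) {
  chartr("ACGT", "TGCA", a)
}

is_palindromic <- function(a1, a2) {
  allele_complement(a1) == a2
}

#' Harmonize exposure and outcome summary statistics
#'
#' Joins two summary-statistic sets on `variant_id` and aligns the
#' outcome effects to the exposure's effect allele. Swapped alleles flip
#' the outcome beta and frequency; opposite-strand records are recognized
#' by allele complement before being declared mismatches. Palindromic
#' variants (A/T or C/G) are kept only when the minor-allele frequency on
#' both sides is below `palindrome_maf_cut` and the frequencies agree in
#' orientation; otherwise their strand is undecidable and they are
#' dropped. Every drop is counted by reason in the `drops` attribute.
#'
#' @param exposure,outcome [sumstats_set] objects.
#' @param palindrome_maf_cut Palindromic variants with `min(eaf, 1-eaf) >=
#'   cut` on either side are dropped (default 0.42, the common two-sample
#'   MR default).
#'
#' @return Data frame with one row per retained variant: `variant_id`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf_x`, `beta_x`,
#'   `se_x`, `p_x`, `n_x`, `eaf_y`, `beta_y`, `se_y`, `p_y`, `n_y`.
#'   Attribute `drops` is a named integer vector of drop reasons.
#' @export
harmonize_pair <- function(exposure, outcome, palindrome_maf_cut = 0.42) {
  ex <- exposure$records
  oy <- outcome$records
  shared <- intersect(ex$variant_id, oy$variant_id)
  if (length(shared) == 0) stop("no overlapping variants between exposure and outcome")
  ex <- ex[match(shared, ex$variant_id), ]
  oy <- oy[match(shared, oy$variant_id), ]

  ea_x <- ex$effect_allele; oa_x <- ex$other_allele
  ea_y <- oy$effect_allele; oa_y <- oy$other_allele

  same <- ea_y == ea_x & oa_y == oa_x
  swap <- ea_y == oa_x & oa_y == ea_x
  # strand flips (complement); palindromic alleles are their own complement
  # pair so these masks only add non-palindromic cases
  flip_same <- !same & !swap &
    allele_complement(ea_y) == ea_x & allele_complement(oa_y) == oa_x
  flip_swap <- !same & !swap &
    allele_complement(ea_y) == oa_x & allele_complement(oa_y) == ea_x
  mismatch <- !(same | swap | flip_same | flip_swap)

  beta_y <- oy$beta
  eaf_y <- oy$eaf
  do_swap <- swap | flip_swap
  beta_y[do_swap] <- -beta_y[do_swap]
  eaf_y[do_swap] <- 1 - eaf_y[do_swap]

  pal <- is_palindromic(ea_x, oa_x)
  maf_x <- pmin(ex$eaf, 1 - ex$eaf)
  maf_y <- pmin(eaf_y, 1 - eaf_y)
  pal_ambiguous <- pal & (maf_x >= palindrome_maf_cut | maf_y >= palindrome_maf_cut)
  pal_discordant <- pal & !pal_ambiguous & ((ex$eaf < 0.5) != (eaf_y < 0.5))

  keep <- !mismatch & !pal_ambiguous & !pal_discordant
  drops <- c(allele_mismatch = sum(mismatch),
             palindromic_ambiguous = sum(pal_ambiguous & !mismatch),
             palindromic_discordant = sum(pal_discordant))
  if (sum(drops) > 0) {
    message("harmonize_pair: dropped ", sum(drops), " variant(s) (",
            paste(names(drops)[drops > 0], drops[drops > 0],
                  sep = "=", collapse = ", "), ")")
  }

  out <- data.frame(variant_id = ex$variant_id,
                    chrom = ex$chrom, pos = ex$pos,
                    effect_allele = ea_x, other_allele = oa_x,
                    eaf_x = ex$eaf, beta_x = ex$beta, se_x = ex$se,
                    p_x = ex$pvalue, n_x = ex$n,
                    eaf_y = eaf_y, beta_y = beta_y, se_y = oy$se,
                    p_y = oy$pvalue, n_y = oy$n)[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drops") <- drops
  out
}
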