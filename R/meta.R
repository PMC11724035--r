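#' Sample-size-weighted z-score meta-analysis of one variant
#'
#' Combines signed per-cohort z-statistics with weights proportional to
#' the square root of each cohort's sample size (the METAL SAMPLESIZE
#' scheme): `z_meta = sum(w_i z_i) / sqrt(sum(w_i^2))` with `w_i =
#' sqrt(n_i)`. Cohorts where the variant is missing (`NA` z) contribute a
#' `"?"` to the direction string and are excluded from the sums.
#'
#' @param z Per-cohort signed z-statistics in fixed cohort order (`NA`
#'   where the variant was not tested).
#' @param n Per-cohort sample sizes (positive where z is non-missing).
#'
#' @return List with `z_meta`, `p_meta` (two-sided), `direction`
#'   (characters `+`, `-`, `0`, `?` per cohort), `n_total` and `k` (number
#'   of contributing cohorts). `NULL` if every cohort is missing.
#' @examples
#' meta_sample_size(c(3, 2), c(1000, 4000))$z_meta  # 3.1305
#' @export
meta_sample_size <- function(z, n) {
  stopifnot(length(z) == length(n))
  use <- !is.na(z)
  if (!any(use)) return(NULL)
  if (any(n[use] <= 0)) stop("sample sizes must be positive")
  w <- sqrt(n[use])
  z_meta <- sum(w * z[use]) / sqrt(sum(w^2))
  direction <- rep("?", length(z))
  direction[use] <- ifelse(z[use] > 0, "+", ifelse(z[use] < 0, "-", "0"))
  list(z_meta = z_meta,
       p_meta = 2 * stats::pnorm(-abs(z_meta)),
       direction = paste(direction, collapse = ""),
       n_total = sum(n[use]),
       k = sum(use))
}

#' Reconstruct a standardized beta and SE from a z-score
#'
#' For a trait standardized to unit variance, the per-allele effect and
#' its standard error implied by a z-statistic, allele frequency f and
#' sample size n are `beta = z / sqrt(2 f (1-f) (n + z^2))` and `se = 1 /
#' sqrt(2 f (1-f) (n + z^2))`. This is the standard recovery of effect
#' sizes from p-value-based meta-analysis output.
#'
#' @param z Signed z-statistic(s).
#' @param eaf Effect-allele frequency in `(0, 1)`.
#' @param n Sample size.
#'
#' @return List with vectors `beta_hat` and `se_hat`.
#' @export
reconstruct_beta_se <- function(z, eaf, n) {
  if (any(eaf <= 0 | eaf >= 1)) stop("eaf must lie strictly in (0, 1)")
  if (any(n <= 0)) stop("n must be positive")
  denom <- sqrt(2 * eaf * (1 - eaf) * (n + z^2))
  list(beta_hat = z / denom, se_hat = 1 / denom)
}

#' Cochran's Q heterogeneity statistic
#'
#' Fixed-effects heterogeneity across k cohort effect estimates:
#' `Q = sum(w_i (beta_i - beta_FE)^2)` with `w_i = 1/se_i^2`, referred to
#' a chi-squared distribution on k - 1 degrees of freedom.
#'
#' @param betas Per-cohort effect estimates (reconstructed standardized
#'   betas; `NA` allowed and dropped pairwise with `ses`).
#' @param ses Matching standard errors (> 0).
#'
#' @return List with `Q`, `het_p` and `k`; `Q` and `het_p` are `NA` when
#'   fewer than two cohorts contribute.
#' @export
cochran_q <- function(betas, ses) {
  stopifnot(length(betas) == length(ses))
  use <- !is.na(betas) & !is.na(ses)
  if (any(ses[use] <= 0)) stop("all standard errors must be positive")
  k <- sum(use)
  if (k < 2) return(list(Q = NA_real_, het_p = NA_real_, k = k))
  b <- betas[use]; w <- 1 / ses[use]^2
  b_fe <- sum(w * b) / sum(w)
  Q <- sum(w * (b - b_fe)^2)
  list(Q = Q, het_p = stats::pchisq(Q, df = k - 1, lower.tail = FALSE), k = k)
}

#' Genomic inflation factor lambda
#'
#' Median of the observed one-degree-of-freedom chi-squared statistics
#' divided by the null median (0.455936...): values near 1 indicate no
#' systematic test-statistic inflation.
#'
#' @param pvalues Two-sided p-values (at least 100 recommended; fewer
#'   triggers a warning but lambda is still computed).
#'
#' @return Lambda (scalar).
#' @export
genomic_lambda <- function(pvalues) {
  if (length(pvalues) < 100) {
    warning("genomic_lambda: fewer than 100 p-values; estimate is unstable")
  }
  chisq <- stats::qchisq(pvalues, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Total phenotypic variance explained by independent lead variants
#'
#' For independent (post-clumping) variants with standardized per-allele
#' effects, each contributes `2 f (1-f) beta^2` to the variance of the
#' standardized trait.
#'
#' @param eaf Effect-allele frequencies.
#' @param beta Standardized per-allele effects.
#'
#' @return Total explained variance (0 for an empty set).
#' @export
explained_variance <- function(eaf, beta) {
  stopifnot(length(eaf) == length(beta))
  if (length(eaf) == 0) return(0)
  sum(2 * eaf * (1 - eaf) * beta^2)
}

#' Meta-analyze one trait across cohorts
#'
#' Runs the sample-size-weighted z-score meta-analysis over the union of
#' variants in the supplied cohort GWASs, reconstructs standardized
#' betas/SEs from the combined z using the sample-size-weighted mean
#' effect-allele frequency, and computes Cochran Q heterogeneity on the
#' per-cohort reconstructed standardized betas (the cohorts report
#' effects on different scales, so heterogeneity is assessed after
#' standardization).
#'
#' @param cohort_sets Named list of [sumstats_set] objects (or `NULL` for
#'   cohorts that did not measure the trait), in fixed cohort order. The
#'   names define the direction-string order.
#'
#' @return Data frame with one row per variant: `variant_id`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `eaf`, `z_meta`, `p_meta`,
#'   `beta_hat`, `se_hat`, `n_total`, `k`, `direction`, `Q`, `het_p`.
#' @export
meta_analyze <- function(cohort_sets) {
  stopifnot(length(cohort_sets) >= 1)
  n_conf <- length(cohort_sets)
  present <- !vapply(cohort_sets, is.null, logical(1))
  if (!any(present)) stop("no non-NULL cohort sets supplied")
  cohort_sets <- cohort_sets[present]
  k_coh <- length(cohort_sets)
  recs <- lapply(cohort_sets, `[[`, "records")
  ids <- unique(unlist(lapply(recs, `[[`, "variant_id"), use.names = FALSE))
  m <- length(ids)
  Zm <- Nm <- Fm <- matrix(NA_real_, m, k_coh)
  for (i in seq_len(k_coh)) {
    r <- recs[[i]]
    at <- match(r$variant_id, ids)
    Zm[at, i] <- r$z
    Nm[at, i] <- r$n
    Fm[at, i] <- r$eaf
  }
  W <- sqrt(Nm); W[is.na(Zm)] <- NA
  sum_wz <- rowSums(W * Zm, na.rm = TRUE)
  sum_w2 <- rowSums(W^2, na.rm = TRUE)
  z_meta <- sum_wz / sqrt(sum_w2)
  n_total <- rowSums(Nm * !is.na(Zm), na.rm = TRUE)
  k <- rowSums(!is.na(Zm))
  eaf <- rowSums(Fm * Nm * !is.na(Zm), na.rm = TRUE) / n_total
  # direction spans the configured cohort order: cohorts that never
  # measured the trait contribute a constant '?' column
  dir_chr <- matrix("?", m, n_conf)
  dir_sub <- matrix("?", m, k_coh)
  dir_sub[!is.na(Zm) & Zm > 0] <- "+"
  dir_sub[!is.na(Zm) & Zm < 0] <- "-"
  dir_sub[!is.na(Zm) & Zm == 0] <- "0"
  dir_chr[, which(present)] <- dir_sub
  direction <- apply(dir_chr, 1, paste, collapse = "")
  rec <- reconstruct_beta_se(z_meta, eaf, n_total)
  # per-cohort standardized betas for heterogeneity
  Bc <- Zm / sqrt(2 * Fm * (1 - Fm) * (Nm + Zm^2))
  Sc <- 1 / sqrt(2 * Fm * (1 - Fm) * (Nm + Zm^2))
  Wq <- 1 / Sc^2; Wq[is.na(Zm)] <- NA
  b_fe <- rowSums(Wq * Bc, na.rm = TRUE) / rowSums(Wq, na.rm = TRUE)
  Q <- rowSums(Wq * (Bc - b_fe)^2, na.rm = TRUE)
  Q[k < 2] <- NA_real_
  het_p <- ifelse(k >= 2, stats::pchisq(Q, df = pmax(k - 1, 1), lower.tail = FALSE),
                  NA_real_)
  # carry positional/allele info from the first cohort holding the variant
  chrom <- ea <- oa <- rep(NA_character_, m)
  pos <- rep(NA_integer_, m)
  for (i in rev(seq_len(k_coh))) {
    r <- recs[[i]]
    at <- match(r$variant_id, ids)
    chrom[at] <- r$chrom; pos[at] <- r$pos
    ea[at] <- r$effect_allele; oa[at] <- r$other_allele
  }
  out <- data.frame(variant_id = ids, chrom = chrom, pos = pos,
                    effect_allele = ea, other_allele = oa, eaf = eaf,
                    z_meta = z_meta,
                    p_meta = 2 * stats::pnorm(-abs(z_meta)),
                    beta_hat = rec$beta_hat, se_hat = rec$se_hat,
                    n_total = n_total, k = k, direction = direction,
                    Q = Q, het_p = het_p)
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  out
}
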