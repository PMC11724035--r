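# Enumeration colocalization under one causal variant per trait:
# posterior probabilities of the five causal configurations from
# per-variant Wakefield approximate Bayes factors.

#' Bayesian colocalization of two association signals
#'
#' Matches the two traits' records on `variant_id` over a region
#' (conventionally the gene window plus/minus 300 kb), computes per-SNP
#' log ABFs for each trait, and enumerates the five hypotheses: H0 no
#' association, H1/H2 only trait 1/2 associated, H3 two distinct causal
#' variants, H4 one shared causal variant. Hypothesis sums are
#'
#' \deqn{L1 = \sum_j ABF1_j,\; L2 = \sum_j ABF2_j,\;
#'       L4 = \sum_j ABF1_j ABF2_j,\; L3 = \sum_{i \ne j} ABF1_i ABF2_j,}
#'
#' evaluated entirely in log space (H3 by a direct log-sum-exp over the
#' off-diagonal pairs for regions up to 2000 SNPs, which avoids the
#' catastrophic cancellation in `L1*L2 - L4`; larger regions use the
#' guarded subtraction). Unnormalized posteriors are
#' `(1, p1 L1, p2 L2, p1 p2 L3, p12 L4)`.
#'
#' @param trait1,trait2 Data frames (or [sumstats_set]s) with
#'   `variant_id`, `beta`, `se` (meta `beta_hat`/`se_hat` accepted).
#' @param p1,p2 Prior probability a SNP is causal for trait 1/2 only
#'   (defaults 1e-4).
#' @param p12 Prior probability a SNP is causal for both (default 1e-5).
#' @param W1,W2 Prior effect variances per trait (defaults `0.15^2` for
#'   quantitative traits; use `0.2^2` for binary log-odds traits).
#' @param region_id Label copied to the result.
#'
#' @return Object of class `coloc_result`: list with `region_id`,
#'   `n_snps`, `priors`, `pp0` ... `pp4` (summing to 1).
#' @export
coloc_abf <- function(trait1, trait2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      W1 = 0.15^2, W2 = 0.15^2, region_id = "region") {
  if (min(p1, p2, p12) <= 0) stop("priors must be positive")
  d1 <- normalize_assoc(trait1)
  d2 <- normalize_assoc(trait2)
  shared <- intersect(d1$variant_id, d2$variant_id)
  if (length(shared) == 0) stop("no shared variants between the two traits")
  d1 <- d1[match(shared, d1$variant_id), ]
  d2 <- d2[match(shared, d2$variant_id), ]
  la1 <- wakefield_log_abf(d1$beta, d1$se, W1)
  la2 <- wakefield_log_abf(d2$beta, d2$se, W2)
  n <- length(shared)
  lL1 <- log_sum_exp(la1)
  lL2 <- log_sum_exp(la2)
  lL4 <- log_sum_exp(la1 + la2)
  if (n == 1) {
    lL3 <- -Inf
  } else if (n <= 2000) {
    # direct off-diagonal log-sum-exp
    M <- outer(la1, la2, "+")
    diag(M) <- -Inf
    lL3 <- log_sum_exp(as.vector(M))
  } else {
    # L3 = L1*L2 - L4, guarded in log space
    lL3 <- lL1 + lL2 + log1p(-exp(pmin(lL4 - lL1 - lL2, 0)))
  }
  lh <- c(0,
          log(p1) + lL1,
          log(p2) + lL2,
          log(p1) + log(p2) + lL3,
          log(p12) + lL4)
  pp <- exp(lh - log_sum_exp(lh))
  structure(list(region_id = region_id, n_snps = n,
                 priors = c(p1 = p1, p2 = p2, p12 = p12),
                 pp0 = pp[1], pp1 = pp[2], pp2 = pp[3], pp3 = pp[4],
                 pp4 = pp[5]),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("<coloc_result> ", x$region_id, " (", x$n_snps, " SNPs): PP0-PP4 = ",
      paste(sprintf("%.3f", c(x$pp0, x$pp1, x$pp2, x$pp3, x$pp4)),
            collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Colocalization call
#'
#' A region is called colocalized when the posterior probability of a
#' shared causal variant strictly exceeds the threshold (default 80%);
#' sub-threshold regions keep their numeric PP4 in the report.
#'
#' @param result A [coloc_abf()] result.
#' @param threshold Calling threshold on PP4 (default 0.8, strict `>`).
#'
#' @return One-row data frame: `region_id`, `n_snps`, `pp0` ... `pp4`,
#'   `colocalized`.
#' @export
coloc_call <- function(result, threshold = 0.8) {
  stopifnot(inherits(result, "coloc_result"))
  data.frame(region_id = result$region_id, n_snps = result$n_snps,
             pp0 = result$pp0, pp1 = result$pp1, pp2 = result$pp2,
             pp3 = result$pp3, pp4 = result$pp4,
             colocalized = result$pp4 > threshold)
}
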