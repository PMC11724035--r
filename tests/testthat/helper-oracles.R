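# Independent oracle implementations used to cross-check the package's
# estimators. Deliberately written as plain loops over the definitions,
# sharing no code with the implementation paths they verify.

# Exhaustive greedy clumping: at each step scan all remaining significant
# variants for the minimum p (ties by chrom then pos), promote it, then
# scan all remaining for window/r2 removal.
oracle_clump <- function(variant_id, chrom, pos, pvalue, R2,
                         p_threshold, r2_threshold, window_bp) {
  alive <- which(pvalue < p_threshold)
  leads <- character(0)
  while (length(alive) > 0) {
    ord <- alive[order(pvalue[alive], chrom[alive], pos[alive])]
    lead <- ord[1]
    leads <- c(leads, variant_id[lead])
    drop <- vapply(alive, function(j) {
      j == lead ||
        (chrom[j] == chrom[lead] && abs(pos[j] - pos[lead]) <= window_bp &&
           R2[lead, j] >= r2_threshold)
    }, logical(1))
    alive <- alive[!drop]
  }
  sort(leads)
}

# Brute-force Benjamini-Hochberg step-up: q_(i) = min_{j >= i} p_(j) m / j.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) p[ord[j]] * m / j, numeric(1))
    q_sorted[i] <- min(1, min(vals))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Exact enumeration of the five colocalization hypotheses over all
# single-SNP and SNP-pair causal configurations, in plain (non-log)
# arithmetic; valid for moderate |z|.
oracle_coloc <- function(beta1, se1, beta2, se2, p1, p2, p12, W1, W2) {
  abf <- function(beta, se, W) {
    V <- se^2
    sqrt(V / (V + W)) * exp((beta / se)^2 / 2 * W / (V + W))
  }
  a1 <- abf(beta1, se1, W1)
  a2 <- abf(beta2, se2, W2)
  n <- length(a1)
  s0 <- 1
  s1 <- sum(p1 * a1)
  s2 <- sum(p2 * a2)
  s3 <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) s3 <- s3 + p1 * p2 * a1[i] * a2[j]
  }
  s4 <- sum(p12 * a1 * a2)
  tot <- s0 + s1 + s2 + s3 + s4
  c(pp0 = s0, pp1 = s1, pp2 = s2, pp3 = s3, pp4 = s4) / tot
}

# Small random LD-correlation matrix factory for clumping sweeps: a valid
# correlation matrix from a random factor model.
random_corr <- function(n) {
  A <- matrix(stats::rnorm(n * 2), n, 2)
  S <- tcrossprod(A) + diag(stats::runif(n, 0.2, 1))
  stats::cov2cor(S)
}

# Equal-spaced AR(1) helper shared by several tests.
toy_ld <- function(n = 10, rho = 0.5, chrom = "1") {
  ar1_ld_matrix(n, rho, chrom = chrom, start_pos = 1e6, spacing = 1000)
}
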