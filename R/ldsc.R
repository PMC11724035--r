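# LD-score regression: univariate SNP-heritability and cross-trait
# genetic correlation with block-jackknife standard errors.

# Weighted least squares of y on x with free intercept; returns
# c(intercept, slope). Weights default to 1/ell heteroskedasticity
# weights (single pass, no iterative reweighting).
wls_fit <- function(y, x, w) {
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  slope <- sum(w * (x - mx) * (y - my)) / sum(w * (x - mx)^2)
  c(intercept = my - slope * mx, slope = slope)
}

# Delete-a-block jackknife over position-contiguous blocks. `stat_fn`
# maps a logical keep-mask to a numeric vector of statistics.
block_jackknife <- function(m, n_blocks, stat_fn) {
  if (n_blocks < 2) stop("jackknife needs at least 2 blocks")
  bounds <- floor(seq(0, m, length.out = n_blocks + 1))
  full <- stat_fn(rep(TRUE, m))
  reps <- matrix(NA_real_, n_blocks, length(full))
  for (b in seq_len(n_blocks)) {
    keep <- rep(TRUE, m)
    keep[(bounds[b] + 1):bounds[b + 1]] <- FALSE
    reps[b, ] <- stat_fn(keep)
  }
  # a delete-block replicate can be undefined (e.g. a heritability slope
  # crossing zero); SEs are computed over the finite replicates
  se <- vapply(seq_along(full), function(j) {
    r <- reps[is.finite(reps[, j]), j]
    nb <- length(r)
    if (nb < 2) return(NA_real_)
    sqrt((nb - 1) / nb * sum((r - mean(r))^2))
  }, numeric(1))
  list(est = full, se = se)
}

#' Univariate LD-score regression
#'
#' Regresses per-variant chi-squared statistics on LD scores under
#' `E[chi2_j] = 1 + n_j * h2 * ell_j / M` with a free intercept. The fit
#' is a single weighted least-squares pass with `1/ell` weights; the
#' slope of `chi2` on `n * ell / M` estimates the SNP-heritability `h2`.
#' Standard errors come from a delete-a-block jackknife over
#' position-contiguous blocks.
#'
#' @param z Per-variant z-statistics (>= 200 variants).
#' @param n Sample size (scalar or per-variant).
#' @param ell LD scores ([ld_scores()]).
#' @param M Number of variants the heritability is spread over (defaults
#'   to `length(z)`).
#' @param n_blocks Jackknife blocks (default 20).
#'
#' @return List with `h2`, `h2_se`, `intercept`, `intercept_se`.
#' @export
h2_regression <- function(z, n, ell, M = length(z), n_blocks = 20) {
  m <- length(z)
  if (m < 200) stop("h2_regression needs at least 200 variants")
  if (length(n) == 1) n <- rep(n, m)
  x <- n * ell / M
  if (stats::sd(x) < 1e-12) stop("degenerate design: constant n * ell")
  y <- z^2
  w <- 1 / ell
  fit_mask <- function(keep) wls_fit(y[keep], x[keep], w[keep])
  jk <- block_jackknife(m, n_blocks, fit_mask)
  list(h2 = unname(jk$est["slope"]), h2_se = jk$se[2],
       intercept = unname(jk$est["intercept"]), intercept_se = jk$se[1])
}

#' Cross-trait LD-score regression (genetic correlation)
#'
#' Fits `E[z1_j z2_j] = rho_g * sqrt(n1_j n2_j) * ell_j / M + intercept`
#' and combines the genetic-covariance slope with the two univariate
#' heritabilities into `rg = rho_g / sqrt(h2_1 * h2_2)`. When either
#' heritability estimate is non-positive the genetic correlation is
#' undefined and reported as such (status `"undefined_h2"`) instead of a
#' number — no correlation is ever emitted from missing heritability
#' evidence. With no sample overlap between the two GWASs the cross-trait
#' intercept has expectation zero.
#'
#' @param z1,z2 z-statistics on a shared variant set (same order).
#' @param n1,n2 Sample sizes (scalar or per-variant).
#' @param ell LD scores.
#' @param M Variant count for scaling (defaults to `length(z1)`).
#' @param n_blocks Jackknife blocks (default 20).
#'
#' @return Object of class `ldsc_result`: list with `h2_1`, `h2_2`,
#'   `gencov`, `rg`, `rg_se`, `intercept`, `status` (`"ok"` or
#'   `"undefined_h2"`); `rg` is `NA` unless status is `"ok"`. An `rg`
#'   beyond 1.25 in absolute value is flagged via `rg_out_of_bounds`.
#' @export
rg_regression <- function(z1, z2, n1, n2, ell, M = length(z1), n_blocks = 20) {
  if (length(z1) != length(z2)) stop("mismatched variant sets")
  m <- length(z1)
  if (length(n1) == 1) n1 <- rep(n1, m)
  if (length(n2) == 1) n2 <- rep(n2, m)
  w <- 1 / ell
  x1 <- n1 * ell / M
  x2 <- n2 * ell / M
  xc <- sqrt(n1 * n2) * ell / M
  stat_fn <- function(keep) {
    h1 <- wls_fit(z1[keep]^2, x1[keep], w[keep])["slope"]
    h2 <- wls_fit(z2[keep]^2, x2[keep], w[keep])["slope"]
    cf <- wls_fit((z1 * z2)[keep], xc[keep], w[keep])
    rg <- if (h1 > 0 && h2 > 0) cf["slope"] / sqrt(h1 * h2) else NA_real_
    c(h1 = unname(h1), h2 = unname(h2), gencov = unname(cf["slope"]),
      icpt = unname(cf["intercept"]), rg = unname(rg))
  }
  jk <- block_jackknife(m, n_blocks, stat_fn)
  est <- jk$est
  ok <- est["h1"] > 0 && est["h2"] > 0
  rg <- if (ok) unname(est["rg"]) else NA_real_
  rg_se <- if (ok) jk$se[5] else NA_real_
  structure(list(h2_1 = unname(est["h1"]), h2_2 = unname(est["h2"]),
                 gencov = unname(est["gencov"]), rg = rg, rg_se = rg_se,
                 intercept = unname(est["icpt"]),
                 status = if (ok) "ok" else "undefined_h2",
                 rg_out_of_bounds = isTRUE(ok && abs(rg) > 1.25)),
            class = "ldsc_result")
}

#' @export
print.ldsc_result <- function(x, ...) {
  cat("<ldsc_result> h2 = (", sprintf("%.3f", x$h2_1), ", ",
      sprintf("%.3f", x$h2_2), "), status = ", x$status, sep = "")
  if (x$status == "ok") cat(", rg = ", sprintf("%.3f", x$rg),
                            " (se ", sprintf("%.3f", x$rg_se), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Pairwise genetic-correlation matrix
#'
#' Runs [rg_regression()] over every unordered trait pair of a z-score
#' matrix.
#'
#' @param Z Matrix of z-statistics, variants x traits (column names =
#'   trait ids).
#' @param n Per-trait sample sizes (named vector or scalar).
#' @param ell LD scores for the rows of `Z`.
#' @param M,n_blocks See [rg_regression()].
#'
#' @return List with `rg` (symmetric matrix, `NA` where undefined, unit
#'   diagonal) and `details` (long data frame with h2s, rg, se, status).
#' @export
rg_matrix <- function(Z, n, ell, M = nrow(Z), n_blocks = 20) {
  traits <- colnames(Z)
  k <- length(traits)
  if (length(n) == 1) n <- stats::setNames(rep(n, k), traits)
  RG <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  diag(RG) <- 1
  rows <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      r <- rg_regression(Z[, i], Z[, j], n[[traits[i]]], n[[traits[j]]],
                         ell, M = M, n_blocks = n_blocks)
      RG[i, j] <- RG[j, i] <- r$rg
      rows[[length(rows) + 1]] <- data.frame(
        trait1 = traits[i], trait2 = traits[j], h2_1 = r$h2_1, h2_2 = r$h2_2,
        gencov = r$gencov, rg = r$rg, rg_se = r$rg_se,
        intercept = r$intercept, status = r$status)
    }
  }
  list(rg = RG, details = do.call(rbind, rows))
}
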