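test_that("the Wald ratio follows its definition and invariances", {
  w <- wald_ratio(0.2, 0.1, 0.05)
  expect_equal(w$beta, 0.5)
  expect_equal(w$se, 0.25)
  expect_equal(wald_ratio(0.2, 0, 0.05)$beta, 0)
  flip <- wald_ratio(-0.2, -0.1, 0.05)
  expect_equal(flip$beta, w$beta)
  expect_equal(flip$se, w$se)
  expect_error(wald_ratio(0, 0.1, 0.05), "beta_x = 0")
})

test_that("fixed-effects IVW matches the arithmetic oracle and exact fits", {
  dat <- data.frame(beta_x = c(0.2, 0.4), beta_y = c(0.1, 0.18),
                    se_y = c(0.05, 0.05))
  e <- ivw_fixed(dat)
  expect_equal(e$beta, 0.46, tolerance = 1e-4)
  expect_equal(e$se, 0.1118, tolerance = 1e-4)
  # exact proportionality recovers the constant with zero residual
  dat2 <- data.frame(beta_x = c(0.1, 0.2, 0.3), beta_y = c(0.07, 0.14, 0.21),
                     se_y = c(0.02, 0.05, 0.01))
  expect_equal(ivw_fixed(dat2)$beta, 0.7, tolerance = 1e-12)
  # single instrument falls back to the Wald ratio
  d1 <- data.frame(beta_x = 0.2, beta_y = 0.1, se_y = 0.05)
  expect_message(f <- ivw_fixed(d1), "Wald")
  expect_equal(f$method, "wald")
  expect_equal(f$beta, wald_ratio(0.2, 0.1, 0.05)$beta)
  # joint sign flip leaves the estimate unchanged
  dat3 <- dat; dat3$beta_x <- -dat3$beta_x; dat3$beta_y <- -dat3$beta_y
  expect_equal(ivw_fixed(dat3)$beta, e$beta, tolerance = 1e-12)
})

test_that("Egger regression fits exactly linear pleiotropy and is oriented", {
  dat <- data.frame(beta_x = c(0.1, 0.2, 0.3, 0.4),
                    beta_y = 0.05 + 0.3 * c(0.1, 0.2, 0.3, 0.4),
                    se_y = rep(0.05, 4))
  e <- mr_egger(dat)
  expect_equal(e$beta, 0.3, tolerance = 1e-10)
  expect_equal(e$egger_intercept, 0.05, tolerance = 1e-10)
  # orientation: flipping a row's joint sign changes nothing
  dat2 <- dat; dat2$beta_x[2] <- -dat2$beta_x[2]; dat2$beta_y[2] <- -dat2$beta_y[2]
  e2 <- mr_egger(dat2)
  expect_equal(e2$beta, e$beta, tolerance = 1e-10)
  expect_equal(e2$egger_intercept, e$egger_intercept, tolerance = 1e-10)
  expect_message(expect_null(mr_egger(dat[1:2, ])), ">= 3")
})

test_that("the weighted median interpolates the weighted ratio distribution", {
  dat <- data.frame(variant_id = c("a", "b", "c"),
                    beta_x = c(1, 1, 1), se_x = c(0.01, 0.01, 0.01),
                    beta_y = c(0.4, 0.5, 10), se_y = c(1, 1, 1))
  wm <- weighted_median(dat, seed = 1)
  expect_equal(wm$beta, 0.5, tolerance = 1e-12)
  # constant ratios give the constant with a small bootstrap SE
  dat2 <- data.frame(variant_id = c("a", "b", "c"),
                     beta_x = c(0.1, 0.2, 0.3), se_x = rep(1e-6, 3),
                     beta_y = 0.7 * c(0.1, 0.2, 0.3), se_y = rep(1e-6, 3))
  wm2 <- weighted_median(dat2, seed = 1)
  expect_equal(wm2$beta, 0.7, tolerance = 1e-6)
  expect_lt(wm2$se, 1e-4)
  # equal weights with odd n: the sample median of ratios
  set.seed(31)
  r <- sort(rnorm(5, 1, 0.3))
  dat3 <- data.frame(variant_id = letters[1:5], beta_x = 1, se_x = 0.01,
                     beta_y = r, se_y = 1)
  expect_equal(weighted_median(dat3, seed = 2)$beta, median(r), tolerance = 1e-9)
  # deterministic under a fixed seed
  expect_equal(weighted_median(dat, seed = 9)$se, weighted_median(dat, seed = 9)$se)
  expect_message(expect_null(weighted_median(dat[1:2, ])), ">= 3")
})

test_that("the weighted median resists a 30% invalid-instrument minority", {
  set.seed(7)
  wm_est <- ivw_est <- numeric(500)
  for (i in 1:500) {
    n <- 20
    bx <- runif(n, 0.1, 0.2); sx <- rep(0.003, n); sy <- rep(0.003, n)
    pleio <- ifelse(seq_len(n) <= 6, 0.1, 0)   # 30% invalid, inflated ratios
    d <- data.frame(variant_id = as.character(1:n),
                    beta_x = rnorm(n, bx, sx), se_x = sx,
                    beta_y = rnorm(n, 0.3 * bx + pleio, sy), se_y = sy)
    wm_est[i] <- weighted_median(d, seed = i)$beta
    ivw_est[i] <- ivw_fixed(d)$beta
  }
  expect_lt(abs(mean(wm_est) - 0.3), 0.03)
  expect_gt(mean(ivw_est), 0.35)  # IVW is biased upward by the invalid set
})

test_that("Steiger filtering drops outcome-dominant rows, strict inequality", {
  dat <- data.frame(variant_id = c("a", "b", "c"),
                    beta_x = c(0.10, 0.20, 0.15),
                    beta_y = c(0.20, 0.10, 0.15))
  out <- steiger_filter(dat)
  expect_equal(out$variant_id, c("b", "c"))      # equality is kept
  expect_equal(attr(out, "steiger_dropped"), "a")
})

test_that("BH adjustment matches the brute-force step-up on random input", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(17)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("instrument selection applies the window, strict p cut, and clumping", {
  R <- diag(5); R[1, 2] <- R[2, 1] <- sqrt(0.5)  # r2 = 0.5 between v1, v2
  ld <- ld_matrix(R, paste0("v", 1:5), "1", c(1:4 * 1000, 900000))
  meta <- data.frame(variant_id = paste0("v", 1:5), chrom = "1",
                     pos = c(1:4 * 1000, 900000),
                     pvalue = c(1e-8, 1e-6, 5e-5, 1e-7, 1e-9))
  win <- list(chrom = "1", start = 500, end = 5000)
  ins <- select_cis_instruments(meta, win, ld, flank_bp = 10000)
  # v5 is outside the window; v3 sits exactly at the cut (excluded);
  # v2 is clumped away by v1 at r2 >= 0.1
  expect_setequal(ins, c("v1", "v4"))
  # relaxing the r2 threshold to 0.6 keeps both v1 and v2
  ins2 <- select_cis_instruments(meta, win, ld, flank_bp = 10000, r2_cut = 0.6)
  expect_setequal(ins2, c("v1", "v2", "v4"))
})

test_that("IVW calibration: coverage and type-I error at nominal levels", {
  set.seed(42)
  nrep <- 500; nins <- 20
  cover <- rej0 <- logical(nrep)
  for (i in seq_len(nrep)) {
    bx <- runif(nins, 0.05, 0.15)
    bxh <- rnorm(nins, bx, 0.01)
    sy <- rep(0.02, nins)
    e1 <- ivw_fixed(data.frame(beta_x = bxh, beta_y = rnorm(nins, 0.3 * bx, sy),
                               se_y = sy))
    e0 <- ivw_fixed(data.frame(beta_x = bxh, beta_y = rnorm(nins, 0, sy),
                               se_y = sy))
    cover[i] <- abs(e1$beta - 0.3) < 1.96 * e1$se
    rej0[i] <- e0$pvalue < 0.05
  }
  expect_gte(mean(cover), 0.93); expect_lte(mean(cover), 0.97)
  expect_gte(mean(rej0), 0.03); expect_lte(mean(rej0), 0.07)
})

test_that("Egger detects planted directional pleiotropy", {
  set.seed(99)
  rej <- vapply(1:500, function(i) {
    bx <- runif(20, 0.05, 0.15); sy <- rep(0.01, 20)
    by <- rnorm(20, 0.05 + 0.2 * bx, sy)
    mr_egger(data.frame(beta_x = bx, beta_y = by, se_y = sy))$intercept_p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.8)
})
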