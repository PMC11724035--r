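test_that("sample-size-weighted meta-analysis follows the METAL scheme", {
  one <- meta_sample_size(2.5, 6000)
  expect_equal(one$z_meta, 2.5)
  expect_equal(one$p_meta, 2 * pnorm(-2.5))
  expect_equal(one$direction, "+")

  cancel <- meta_sample_size(c(3, -3), c(5000, 5000))
  expect_equal(cancel$z_meta, 0)
  expect_equal(cancel$direction, "+-")

  two <- meta_sample_size(c(3, 2), c(1000, 4000))
  expect_equal(two$z_meta, (sqrt(1000) * 3 + sqrt(4000) * 2) / sqrt(5000),
               tolerance = 1e-12)
  expect_equal(two$z_meta, 3.1305, tolerance = 1e-4)
  expect_equal(two$n_total, 5000)

  miss <- meta_sample_size(c(NA, 2, 0), c(1000, 4000, 2000))
  expect_equal(miss$direction, "?+0")
  expect_equal(miss$n_total, 6000)
  expect_null(meta_sample_size(c(NA, NA), c(1, 1)))
})

test_that("equal-N equal-z meta over K cohorts gives sqrt(K) scaling", {
  for (K in 2:5) {
    m <- meta_sample_size(rep(1.7, K), rep(3000, K))
    expect_equal(m$z_meta, sqrt(K) * 1.7, tolerance = 1e-12)
  }
})

test_that("standardized beta reconstruction matches the closed form", {
  r0 <- reconstruct_beta_se(0, 0.3, 5000)
  expect_equal(r0$beta_hat, 0)
  expect_equal(r0$se_hat, 1 / sqrt(2 * 0.3 * 0.7 * 5000))
  r <- reconstruct_beta_se(3.1305, 0.3, 5000)
  expect_equal(r$beta_hat, 0.06825, tolerance = 1e-4)
  expect_equal(r$se_hat, 0.02180, tolerance = 1e-4)
  expect_equal(r$beta_hat / r$se_hat, 3.1305, tolerance = 1e-9)
  expect_error(reconstruct_beta_se(1, 0, 1000), "\\(0, 1\\)")
})

test_that("reconstruction inverts the generative model", {
  ld <- ar1_ld_matrix(2, 0)
  eaf <- setNames(c(0.3, 0.3), ld$variant_id)
  arch <- true_architecture(setNames(0.1, ld$variant_id[1]), trait_h2 = 0.1)
  bh <- vapply(1:500, function(s) {
    simulate_cohort_sumstats(ld, arch, 20000, eaf, seed = s)$records$beta[1]
  }, numeric(1))
  mc_se <- sd(bh) / sqrt(length(bh))
  # the marginal per-allele effect implied by a standardized-genotype
  # effect b is b / sqrt(2 f (1-f))
  expect_lt(abs(mean(bh) - 0.1 / sqrt(2 * 0.3 * 0.7)), 3 * mc_se)
})

test_that("Cochran Q matches the direct arithmetic and chi-square oracle", {
  same <- cochran_q(c(0.2, 0.2, 0.2), c(0.1, 0.2, 0.1))
  expect_equal(same$Q, 0)
  expect_equal(same$het_p, 1)
  toy <- cochran_q(c(0.1, 0.3), c(0.1, 0.1))
  expect_equal(toy$Q, 2.0, tolerance = 1e-12)
  expect_equal(toy$het_p, 0.1573, tolerance = 1e-4)
  expect_equal(toy$het_p, pchisq(2, 1, lower.tail = FALSE), tolerance = 1e-12)
  # invariant under cohort reordering
  set.seed(4)
  b <- rnorm(4, 0.1, 0.05); s <- runif(4, 0.02, 0.1)
  perm <- sample(4)
  expect_equal(cochran_q(b, s)$Q, cochran_q(b[perm], s[perm])$Q)
  expect_true(is.na(cochran_q(c(0.1, NA), c(0.1, 0.1))$Q))
  expect_error(cochran_q(c(0.1, 0.2), c(0, 0.1)), "positive")
})

test_that("genomic lambda matches closed forms and limits", {
  # all p = 0.5: the observed median chi-square equals the null median
  # qnorm(0.75)^2 = 0.4549364, so lambda is exactly 1
  expect_warning(l_half <- genomic_lambda(rep(0.5, 50)), "100")
  expect_equal(l_half, qnorm(0.75)^2 / qchisq(0.5, 1), tolerance = 1e-12)
  expect_equal(l_half, 1, tolerance = 1e-10)
  grid <- (1:10000 - 0.5) / 10000
  expect_lt(abs(genomic_lambda(grid) - 1), 0.02)
})

test_that("explained variance sums 2f(1-f)beta^2 and recovers planted truth", {
  expect_equal(explained_variance(0.5, 0.1), 0.005)
  expect_equal(explained_variance(numeric(0), numeric(0)), 0)
  # planted architecture: 3 independent causal variants with total
  # standardized variance 0.03 (per-allele effects recovered at leads)
  ld <- ar1_ld_matrix(3, 0)
  f <- c(0.2, 0.3, 0.4)
  eaf <- setNames(f, ld$variant_id)
  b_std <- sqrt(0.03 / 3)  # per-variant standardized-genotype effect
  arch <- true_architecture(setNames(rep(b_std, 3), ld$variant_id),
                            trait_h2 = 0.05)
  ev <- vapply(1:200, function(s) {
    r <- simulate_cohort_sumstats(ld, arch, 30000, eaf, seed = s)$records
    explained_variance(r$eaf, r$beta)
  }, numeric(1))
  expect_lt(abs(mean(ev) - 0.03), 0.01)
})

test_that("table-level meta-analysis keeps z/p/beta/se mutually consistent", {
  ld <- toy_ld(40, 0.8)
  set.seed(6); eaf <- setNames(runif(40, 0.05, 0.5), ld$variant_id)
  arch <- true_architecture(setNames(0.1, ld$variant_id[20]), trait_h2 = 0.1)
  sets <- lapply(1:3, function(i)
    simulate_cohort_sumstats(ld, arch, c(8000, 12000, 20000)[i], eaf,
                             seed = 50 + i, cohort_id = paste0("c", i)))
  names(sets) <- paste0("c", 1:3)
  m <- meta_analyze(sets)
  expect_equal(nrow(m), 40)
  expect_equal(m$p_meta, 2 * pnorm(-abs(m$z_meta)), tolerance = 1e-12)
  expect_equal(m$beta_hat / m$se_hat, m$z_meta, tolerance = 1e-9)
  expect_true(all(m$k == 3))
  expect_true(all(nchar(m$direction) == 3))
  expect_true(all(m$Q >= 0))
  # meta of a single cohort reproduces it exactly
  m1 <- meta_analyze(sets[1])
  at <- match(sets$c1$records$variant_id, m1$variant_id)
  expect_equal(m1$z_meta[at], sets$c1$records$z, tolerance = 1e-12)
  expect_equal(m1$p_meta[at], sets$c1$records$pvalue, tolerance = 1e-12)
  # a cohort missing the trait contributes a constant '?' column
  m2 <- meta_analyze(list(c1 = sets$c1, c2 = NULL, c3 = sets$c3))
  expect_true(all(nchar(m2$direction) == 3))
  expect_true(all(substr(m2$direction, 2, 2) == "?"))
  expect_true(all(m2$k == 2))
})
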