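test_that("same seed gives identical summary statistics", {
  ld <- toy_ld(20, 0.8)
  set.seed(5); eaf <- setNames(runif(20, 0.05, 0.5), ld$variant_id)
  arch <- true_architecture(setNames(0.1, ld$variant_id[10]), trait_h2 = 0.1)
  a <- simulate_cohort_sumstats(ld, arch, 5000, eaf, seed = 42)
  b <- simulate_cohort_sumstats(ld, arch, 5000, eaf, seed = 42)
  expect_identical(a$records, b$records)
  d1 <- simulate_disease_gwas(ld, setNames(0.1, ld$variant_id[10]), 0.3,
                              1000, 2000, eaf, seed = 7)
  d2 <- simulate_disease_gwas(ld, setNames(0.1, ld$variant_id[10]), 0.3,
                              1000, 2000, eaf, seed = 7)
  expect_identical(d1$records, d2$records)
})

test_that("null architecture gives calibrated marginal z over seeds", {
  ld <- ar1_ld_matrix(5, 0)
  eaf <- setNames(rep(0.3, 5), ld$variant_id)
  arch <- true_architecture(setNames(numeric(0), character(0)))
  Z <- t(vapply(1:1000, function(s) {
    simulate_cohort_sumstats(ld, arch, 5000, eaf, seed = s)$records$z
  }, numeric(5)))
  expect_true(all(abs(colMeans(Z)) < 0.1))
  expect_true(all(apply(Z, 2, var) > 0.9 & apply(Z, 2, var) < 1.1))
})

test_that("a planted effect has the model-implied expected z", {
  ld <- ar1_ld_matrix(2, 0)
  eaf <- setNames(c(0.3, 0.3), ld$variant_id)
  arch <- true_architecture(setNames(0.1, ld$variant_id[1]), trait_h2 = 0.1)
  z1 <- vapply(1:1000, function(s) {
    simulate_cohort_sumstats(ld, arch, 10000, eaf, seed = s)$records$z[1]
  }, numeric(1))
  mc_se <- sd(z1) / sqrt(length(z1))
  expect_lt(abs(mean(z1) - sqrt(10000) * 0.1), 3 * mc_se)
})

test_that("the disease generator is null-calibrated and scales SEs by n_eff", {
  ld <- ar1_ld_matrix(10, 0)
  eaf <- setNames(rep(0.25, 10), ld$variant_id)
  zs <- unlist(lapply(1:200, function(s) {
    simulate_disease_gwas(ld, setNames(0.1, ld$variant_id[1]), theta_true = 0,
                          5000, 10000, eaf, seed = s)$records$z
  }))
  expect_lt(abs(mean(zs)), 0.05)
  expect_true(var(zs) > 0.9 && var(zs) < 1.1)
  d <- simulate_disease_gwas(ld, setNames(0.1, ld$variant_id[1]), 0.3,
                             5000, 10000, eaf, seed = 1)
  n_eff <- 4 / (1 / 5000 + 1 / 10000)
  expect_equal(d$records$se, rep(1 / sqrt(2 * 0.25 * 0.75 * n_eff), 10),
               tolerance = 1e-12)
  expect_error(simulate_disease_gwas(ld, setNames(0.1, ld$variant_id[1]), 0.3,
                                     50, 10000, eaf, seed = 1), ">= 100")
})

test_that("panel simulation respects the cohort-overlap map", {
  cfg <- sim_config(cytokines = c("CK1", "CK2"),
                    panel_overlap = list(CK1 = c("cohortA", "cohortB", "cohortC"),
                                         CK2 = c("cohortB")),
                    n_variants = 30, seed = 3)
  p <- simulate_panel(cfg)
  expect_length(p$sumstats$CK1, 3)
  expect_length(p$sumstats$CK2, 1)
  expect_named(p$sumstats$CK2, "cohortB")
  expect_error(sim_config(panel_overlap = list(CK1 = character(0))),
               "at least one cohort")
})

test_that("a cohort-specific effect is flagged as heterogeneous", {
  # b = 0.15 in cohort 1 only, n = 8000 per cohort: Cochran Q should
  # reject at 0.05 in at least 80% of seeds
  ld <- ar1_ld_matrix(30, 0.9)
  v <- ld$variant_id[15]
  arch <- true_architecture(setNames(0.15, v), trait_h2 = 0.1,
                            cohort_specific = setNames(list("c1"), v))
  set.seed(8); eaf <- setNames(runif(30, 0.05, 0.5), ld$variant_id)
  hits <- vapply(1:200, function(s) {
    sets <- lapply(c("c1", "c2", "c3"), function(co)
      simulate_cohort_sumstats(ld, arch, 8000, eaf,
                               seed = s * 13 + match(co, c("c1", "c2", "c3")),
                               cohort_id = co))
    names(sets) <- c("c1", "c2", "c3")
    m <- meta_analyze(sets)
    m$het_p[match(v, m$variant_id)] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("assay shifts rescale effects multiplicatively", {
  ld <- ar1_ld_matrix(2, 0)
  eaf <- setNames(c(0.3, 0.3), ld$variant_id)
  arch <- true_architecture(setNames(0.1, ld$variant_id[1]), trait_h2 = 0.1,
                            assay_shift = c(big = 1.5))
  z <- vapply(1:400, function(s) {
    simulate_cohort_sumstats(ld, arch, 10000, eaf, seed = s,
                             cohort_id = "big")$records$z[1]
  }, numeric(1))
  expect_lt(abs(mean(z) - sqrt(10000) * 0.15), 3 * sd(z) / sqrt(length(z)))
  expect_error(true_architecture(setNames(0.1, "v"), assay_shift = c(a = -1)),
               "> 0")
  expect_error(true_architecture(setNames(c(0.4, 0.4), c("a", "b")),
                                 trait_h2 = 0.1), "exceeds")
})
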