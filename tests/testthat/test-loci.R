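test_that("greedy clumping resolves the three-variant example", {
  # v1-v2 in LD (r2 = 0.25 >= 0.1), v3 independent; v1 has the smallest p
  R <- diag(3); R[1, 2] <- R[2, 1] <- 0.5
  ld <- ld_matrix(R, c("v1", "v2", "v3"), "1", c(1000, 2000, 3000))
  rec <- data.frame(variant_id = c("v1", "v2", "v3"), chrom = "1",
                    pos = c(1000, 2000, 3000),
                    pvalue = c(1e-10, 1e-9, 1e-8))
  leads <- clump(rec, ld, p_threshold = 1e-5, r2_threshold = 0.1)
  expect_setequal(leads$variant_id, c("v1", "v3"))
  # with no LD every significant variant is its own lead
  leads0 <- clump(rec, ld_matrix(diag(3), c("v1", "v2", "v3"), "1",
                                 c(1000, 2000, 3000)),
                  p_threshold = 1e-5, r2_threshold = 0.1)
  expect_setequal(leads0$variant_id, c("v1", "v2", "v3"))
  # a single significant variant is its own lead
  rec1 <- rec; rec1$pvalue <- c(1e-10, 0.5, 0.5)
  expect_equal(clump(rec1, ld, p_threshold = 1e-5)$variant_id, "v1")
  # variants absent from the LD reference are excluded with a message
  rec2 <- rbind(rec, data.frame(variant_id = "ghost", chrom = "1",
                                pos = 4000, pvalue = 1e-12))
  expect_message(l2 <- clump(rec2, ld, p_threshold = 1e-5), "absent")
  expect_false("ghost" %in% l2$variant_id)
})

test_that("clumping equals exhaustive greedy selection on random instances", {
  set.seed(13)
  for (case in 1:200) {
    n <- sample(2:12, 1)
    R <- random_corr(n)
    ids <- paste0("v", seq_len(n))
    pos <- sort(sample(1000:50000, n))
    ld <- ld_matrix(R, ids, "1", pos)
    pv <- runif(n, 0, 2e-5)
    rec <- data.frame(variant_id = ids, chrom = "1", pos = pos, pvalue = pv)
    r2_thr <- sample(c(0.001, 0.1, 0.5), 1)
    win <- sample(c(5000, 20000, 1e6), 1)
    got <- sort(clump(rec, ld, p_threshold = 1e-5, r2_threshold = r2_thr,
                      window_bp = win)$variant_id)
    want <- oracle_clump(ids, rep("1", n), pos, pv, R^2, 1e-5, r2_thr, win)
    expect_identical(got, want)
  }
})

test_that("locus merging chains nearby leads and is monotone in separation", {
  leads <- data.frame(variant_id = c("a", "b"), chrom = "1",
                      pos = c(1.0e6, 1.8e6), pvalue = c(1e-9, 1e-10))
  expect_equal(nrow(merge_to_loci(leads)), 1)
  leads2 <- data.frame(variant_id = c("a", "b"), chrom = "1",
                       pos = c(1.0e6, 2.5e6), pvalue = c(1e-9, 1e-10))
  expect_equal(nrow(merge_to_loci(leads2)), 2)
  # chained: 1.0, 1.9, 2.8 Mb merge transitively into one locus
  leads3 <- data.frame(variant_id = c("a", "b", "c"), chrom = "1",
                       pos = c(1.0e6, 1.9e6, 2.8e6),
                       pvalue = c(1e-9, 1e-12, 1e-10))
  l3 <- merge_to_loci(leads3)
  expect_equal(nrow(l3), 1)
  expect_equal(l3$lead_variant_id, "b")
  expect_equal(l3$start, 1.0e6)
  expect_equal(l3$end, 2.8e6)
  # number of loci is non-increasing in the separation threshold
  set.seed(14)
  leads4 <- data.frame(variant_id = paste0("v", 1:20), chrom = "1",
                       pos = sort(sample(1:2e7, 20)),
                       pvalue = runif(20, 0, 1e-8))
  seps <- c(1e5, 5e5, 1e6, 5e6)
  counts <- vapply(seps, function(s) nrow(merge_to_loci(leads4, s)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  # different chromosomes never merge
  leads5 <- data.frame(variant_id = c("a", "b"), chrom = c("1", "2"),
                       pos = c(1e6, 1e6), pvalue = c(1e-9, 1e-9))
  expect_equal(nrow(merge_to_loci(leads5)), 2)
})

test_that("cis/trans classification uses a closed 300 kb window", {
  gene <- list(chrom = "1", start = 1000000, end = 1050000)
  mk <- function(pos, chrom = "1") {
    merge_to_loci(data.frame(variant_id = "v", chrom = chrom, pos = pos,
                             pvalue = 1e-9), trait_id = "CK")
  }
  expect_equal(classify_cis_trans(mk(1000000 - 250000), gene)$label, "cis")
  expect_equal(classify_cis_trans(mk(1000000 - 300000), gene)$label, "cis")
  expect_equal(classify_cis_trans(mk(1000000 - 300001), gene)$label, "trans")
  expect_equal(classify_cis_trans(mk(1050000 + 300000), gene)$label, "cis")
  expect_equal(classify_cis_trans(mk(1000000, chrom = "2"), gene)$label, "trans")
  expect_message(out <- classify_cis_trans(mk(1e6), NULL), "no gene-panel")
  expect_true(is.na(out$label))
})

test_that("replication rates count significant, concordant variants", {
  rec <- data.frame(variant_id = paste0("v", 1:12), chrom = "1",
                    pos = 1:12 * 1000,
                    effect_allele = "A", other_allele = "G", eaf = 0.3,
                    beta = rep(c(0.1, -0.1), 6), se = 0.01,
                    pvalue = c(rep(1e-9, 10), 0.5, 0.5), n = 10000)
  ref <- sumstats_set(rec, "CK", "ref", validate = FALSE)
  # target: 6 of the 10 significant variants replicate (4 fail: 2 by p,
  # 2 by direction)
  tg_rec <- rec
  tg_rec$pvalue <- c(rep(0.01, 6), 0.5, 0.5, 0.01, 0.01, 0.5, 0.5)
  tg_rec$beta[9:10] <- -tg_rec$beta[9:10]
  tg <- sumstats_set(tg_rec, "CK", "tgt", validate = FALSE)
  rr <- replication_rates(ref, list(tgt = tg), gw_p = 5e-8)
  expect_equal(rr$n_significant, 10)
  expect_equal(rr$n_replicated, 6)
  expect_equal(rr$rate, 0.6)
  # self-replication is perfect
  rr_self <- replication_rates(ref, list(ref = ref), gw_p = 5e-8)
  expect_equal(rr_self$rate, 1)
  # absent variants shrink the denominator when drop_missing = TRUE
  tg2 <- sumstats_set(tg_rec[1:5, ], "CK", "small", validate = FALSE)
  rr2 <- replication_rates(ref, list(small = tg2), gw_p = 5e-8)
  expect_equal(rr2$n_significant, 5)
  rr3 <- replication_rates(ref, list(small = tg2), gw_p = 5e-8,
                           drop_missing = FALSE)
  expect_equal(rr3$n_significant, 10)
  # summary aggregates across traits
  s <- replication_summary(rbind(rr, rr))
  expect_equal(s$median_rate, 0.6)
  expect_equal(s$n_traits, 2)
})
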