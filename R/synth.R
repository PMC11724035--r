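#' True genetic architecture for a simulated trait
#'
#' Ground-truth registry used by the summary-statistic generator and by
#' parameter-recovery tests: joint standardized per-allele effects on the
#' standardized-genotype scale, the gene whose window carries the planted
#' cis effects, per-cohort assay rescalings (emulating different affinity
#' assays measuring the same analyte on different effective scales), and
#' effects that exist only in named cohorts (planted heterogeneity).
#'
#' @param causal_effects Named numeric vector, variant_id -> joint
#'   standardized effect.
#' @param cis_gene Gene id whose window holds the planted cis effects.
#' @param trait_h2 Heritability target; planted effects must satisfy
#'   `sum(b^2) <= trait_h2` (variance on the standardized trait scale).
#' @param assay_shift Named numeric vector, cohort -> multiplicative
#'   effect rescaling (> 0); cohorts not named default to 1.
#' @param cohort_specific Named list, variant_id -> character vector of
#'   cohorts in which that effect exists (elsewhere it is masked to 0).
#'
#' @return Object of class `true_architecture`.
#' @export
true_architecture <- function(causal_effects, cis_gene = NA_character_,
                              trait_h2 = 0.1, assay_shift = NULL,
                              cohort_specific = list()) {
  if (length(causal_effects) && is.null(names(causal_effects))) {
    stop("causal_effects must be named by variant_id")
  }
  if (sum(causal_effects^2) > trait_h2 + 1e-9) {
    stop("sum of squared planted effects exceeds trait_h2")
  }
  if (!is.null(assay_shift) && any(assay_shift <= 0)) stop("assay_shift must be > 0")
  structure(list(causal_effects = causal_effects, cis_gene = cis_gene,
                 trait_h2 = trait_h2,
                 assay_shift = assay_shift %||% numeric(0),
                 cohort_specific = cohort_specific),
            class = "true_architecture")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Effects as seen by one cohort: assay rescaling plus cohort masking.
cohort_effects <- function(arch, cohort_id) {
  b <- arch$causal_effects
  if (length(arch$cohort_specific)) {
    for (v in names(arch$cohort_specific)) {
      if (v %in% names(b) && !(cohort_id %in% arch$cohort_specific[[v]])) {
        b[v] <- 0
      }
    }
  }
  shift <- if (!is.null(cohort_id) && cohort_id %in% names(arch$assay_shift)) {
    arch$assay_shift[[cohort_id]]
  } else 1
  b * shift
}

# Deterministic synthetic allele pairs: a fixed fraction of palindromic
# A/T variants (every k-th variant) among default A/G pairs, so that
# harmonization logic is exercised identically across cohorts.
synthetic_alleles <- function(n, palindromic_frac = 0.05) {
  ea <- rep("A", n); oa <- rep("G", n)
  if (palindromic_frac > 0) {
    every <- max(1L, round(1 / palindromic_frac))
    pal <- seq_len(n) %% every == 0L
    oa[pal] <- "T"
  }
  list(effect_allele = ea, other_allele = oa)
}

# z ~ MVN(sqrt(n) R b, R) drawn with one Cholesky factor per block.
rss_draw_z <- function(ld, b_joint, n) {
  mu <- sqrt(n) * as.vector(ld$R %*% b_joint)
  U <- chol_ridge(ld$R)
  mu + as.vector(t(U) %*% stats::rnorm(length(mu)))
}

#' Simulate one cohort's GWAS summary statistics
#'
#' Draws marginal z-statistics directly under the summary-statistic
#' (RSS-style) model `z ~ MVN(sqrt(n) R b, R)`, where `b` holds the joint
#' standardized effects after applying the cohort's assay rescaling and
#' cohort masking, and `R` is the block LD matrix. Standardized betas and
#' SEs are then derived as `beta = z / sqrt(2 f (1-f) (n + z^2))`,
#' `se = 1 / sqrt(2 f (1-f) (n + z^2))`, with two-sided normal p-values.
#'
#' @param ld An [ld_matrix] or list of blocks (independent across blocks).
#' @param arch A [true_architecture]; its variant ids must be a subset of
#'   the LD reference's.
#' @param n Sample size (> 1).
#' @param eaf Named (or LD-ordered) effect-allele frequencies in
#'   `(0, 0.5]` (minor-allele orientation).
#' @param seed Integer seed; identical seeds give identical output.
#' @param cohort_id,trait_id Metadata recorded in the returned set.
#' @param palindromic_frac Fraction of variants emitted with palindromic
#'   A/T alleles (default 0.05).
#'
#' @return A [sumstats_set] (quantitative).
#' @export
simulate_cohort_sumstats <- function(ld, arch, n, eaf, seed,
                                     cohort_id = "cohort", trait_id = "trait",
                                     palindromic_frac = 0.05) {
  if (n <= 1) stop("n must exceed 1")
  if (inherits(ld, "ld_matrix")) ld <- list(ld)
  all_ids <- unlist(lapply(ld, `[[`, "variant_id"), use.names = FALSE)
  if (!all(names(arch$causal_effects) %in% all_ids)) {
    stop("architecture names variants absent from the LD reference")
  }
  if (is.null(names(eaf))) names(eaf) <- all_ids
  if (any(eaf <= 0 | eaf > 0.5)) stop("eaf must lie in (0, 0.5]")
  b_all <- stats::setNames(numeric(length(all_ids)), all_ids)
  bc <- cohort_effects(arch, cohort_id)
  b_all[names(bc)] <- bc
  set.seed(seed)
  rows <- lapply(ld, function(block) {
    ids <- block$variant_id
    z <- rss_draw_z(block, b_all[ids], n)
    f <- eaf[ids]
    rec <- reconstruct_beta_se(z, f, n)
    al <- synthetic_alleles(length(ids), palindromic_frac)
    data.frame(variant_id = ids, chrom = block$chrom, pos = block$pos,
               effect_allele = al$effect_allele, other_allele = al$other_allele,
               eaf = unname(f), beta = rec$beta_hat, se = rec$se_hat,
               pvalue = 2 * stats::pnorm(-abs(z)), n = n, z = z)
  })
  sumstats_set(do.call(rbind, rows), trait_id, cohort_id, "quantitative",
               validate = FALSE)
}

#' Simulate a binary-disease outcome GWAS
#'
#' Emits log-odds effects with effective-sample-size standard errors
#' `se_j = 1 / sqrt(2 f (1-f) n_eff)`, `n_eff = 4 / (1/n_case +
#' 1/n_control)`. The per-variant true log-odds effect is `theta_true *
#' beta_X` at the supplied exposure instruments (zero elsewhere), on the
#' same standardized-genotype scale as [true_architecture()], so that the
#' per-allele outcome and exposure effects remain commensurate and the
#' causal ratio of a valid instrument equals `theta_true`. Sampling noise
#' is LD-correlated exactly as in [simulate_cohort_sumstats()].
#'
#' @param ld LD reference ([ld_matrix] or list of blocks).
#' @param instrument_effects Named numeric vector, variant_id -> joint
#'   standardized exposure effect `beta_X` (standardized-genotype scale).
#' @param theta_true Causal log-odds per SD of the exposure.
#' @param n_case,n_control Case/control counts (each >= 100).
#' @param eaf Effect-allele frequencies as in [simulate_cohort_sumstats()].
#' @param seed Integer seed.
#' @param trait_id Disease identifier.
#'
#' @return A [sumstats_set] (binary, `n = n_case + n_control`).
#' @export
simulate_disease_gwas <- function(ld, instrument_effects, theta_true,
                                  n_case, n_control, eaf, seed,
                                  trait_id = "disease") {
  if (!is.finite(theta_true)) stop("theta_true must be finite")
  if (n_case < 100 || n_control < 100) stop("n_case and n_control must each be >= 100")
  if (inherits(ld, "ld_matrix")) ld <- list(ld)
  all_ids <- unlist(lapply(ld, `[[`, "variant_id"), use.names = FALSE)
  if (is.null(names(eaf))) names(eaf) <- all_ids
  n_eff <- 4 / (1 / n_case + 1 / n_control)
  se_all <- 1 / sqrt(2 * eaf * (1 - eaf) * n_eff)
  gamma <- stats::setNames(numeric(length(all_ids)), all_ids)
  shared <- intersect(names(instrument_effects), all_ids)
  gamma[shared] <- theta_true * instrument_effects[shared]
  set.seed(seed)
  rows <- lapply(ld, function(block) {
    ids <- block$variant_id
    # joint noncentrality on the standardized-genotype scale, where the
    # per-variant SE is 1/sqrt(n_eff)
    eta <- sqrt(n_eff) * gamma[ids]
    mu <- as.vector(block$R %*% eta)
    U <- chol_ridge(block$R)
    z <- mu + as.vector(t(U) %*% stats::rnorm(length(ids)))
    se <- se_all[ids]
    al <- synthetic_alleles(length(ids))
    data.frame(variant_id = ids, chrom = block$chrom, pos = block$pos,
               effect_allele = al$effect_allele, other_allele = al$other_allele,
               eaf = unname(eaf[ids]), beta = z * se, se = unname(se),
               pvalue = 2 * stats::pnorm(-abs(z)),
               n = n_case + n_control, z = z)
  })
  sumstats_set(do.call(rbind, rows), trait_id, "disease_gwas", "binary",
               validate = FALSE)
}

#' Simulation configuration for a multi-cohort cytokine panel
#'
#' Defaults emulate three proteomics cohorts of very different sizes
#' measuring partially overlapping cytokine panels on different assays,
#' with one LD block per cytokine gene region.
#'
#' @param cytokines Character vector of cytokine names.
#' @param cohorts Character vector of cohort names (direction-string
#'   order).
#' @param sample_sizes Named per-cohort sample sizes.
#' @param panel_overlap Named list cytokine -> cohorts measuring it;
#'   default: all cytokines in all cohorts except every third cytokine
#'   missing from the smallest cohort.
#' @param n_variants Variants per gene-region LD block.
#' @param spacing Base pairs between adjacent variants.
#' @param ar1_rho AR(1) LD decay parameter.
#' @param maf_range Range for uniform minor-allele frequencies.
#' @param cis_effects Standardized joint effects planted inside each gene
#'   window (two cis signals per cytokine by default).
#' @param assay_shift Named per-cohort multiplicative effect rescaling.
#' @param network_theta Square matrix (cytokine x cytokine) of causal
#'   effects: `network_theta[a, b]` is the effect of cytokine a on
#'   cytokine b in SD per SD; b's GWAS then shows signal at a's cis
#'   variants with joint effect `theta * b_a`.
#' @param cohort_specific Named list variant_id -> cohorts (planted
#'   heterogeneity), as in [true_architecture()].
#' @param disease_params List with `n_case`, `n_control` and `theta`
#'   (named numeric matrix-like list cytokine -> disease -> log-odds per
#'   SD), used by [run_pipeline()].
#' @param palindromic_frac Fraction of palindromic A/T variants.
#' @param seed Integer master seed.
#'
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(cytokines = paste0("CK", 1:8),
                       cohorts = c("cohortA", "cohortB", "cohortC"),
                       sample_sizes = c(cohortA = 10000, cohortB = 20000,
                                        cohortC = 35000),
                       panel_overlap = NULL,
                       n_variants = 200L, spacing = 2000L, ar1_rho = 0.9,
                       maf_range = c(0.05, 0.5),
                       cis_effects = c(0.12, 0.09, 0.07),
                       assay_shift = NULL,
                       network_theta = NULL,
                       cohort_specific = list(),
                       disease_params = list(n_case = 20000, n_control = 40000,
                                             theta = NULL),
                       palindromic_frac = 0.05,
                       seed = 1L) {
  if (ar1_rho < 0 || ar1_rho >= 1) stop("ar1_rho must lie in [0, 1)")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5) stop("maf_range must lie in (0, 0.5]")
  if (is.null(panel_overlap)) {
    panel_overlap <- stats::setNames(lapply(seq_along(cytokines), function(i) {
      if (i %% 3 == 0) cohorts[-1] else cohorts
    }), cytokines)
  }
  if (any(lengths(panel_overlap) == 0)) {
    stop("every cytokine must be measured in at least one cohort")
  }
  if (is.null(names(sample_sizes))) names(sample_sizes) <- cohorts
  if (is.null(assay_shift)) {
    assay_shift <- stats::setNames(rep(1, length(cohorts)), cohorts)
  }
  if (is.null(network_theta)) {
    network_theta <- matrix(0, length(cytokines), length(cytokines),
                            dimnames = list(cytokines, cytokines))
  }
  structure(list(cytokines = cytokines, cohorts = cohorts,
                 sample_sizes = sample_sizes, panel_overlap = panel_overlap,
                 n_variants = as.integer(n_variants),
                 spacing = as.integer(spacing), ar1_rho = ar1_rho,
                 maf_range = maf_range, cis_effects = cis_effects,
                 assay_shift = assay_shift, network_theta = network_theta,
                 cohort_specific = cohort_specific,
                 disease_params = disease_params,
                 palindromic_frac = palindromic_frac,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic sub-seed derivation, kept below 2^31.
sub_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 1009) %% 2147483647)
}

#' Simulate a full multi-cohort cytokine panel
#'
#' Builds one AR(1) LD block per cytokine gene region (cross-block LD is
#' exactly zero; each region sits on its own synthetic chromosome), plants
#' the configured cis effects in each gene window plus cross-cytokine
#' network effects, and emits a summary-statistic set for every
#' (cytokine, cohort) pair in the panel-overlap map. The truth registry
#' (architectures, frequencies, gene panel) is returned for recovery
#' tests.
#'
#' @param config A [sim_config].
#'
#' @return List with `sumstats` (nested list `[[cytokine]][[cohort]]`),
#'   `ld` (named list of [ld_matrix] per cytokine region), `eaf` (named
#'   list of per-region frequencies), `gene_panel` (BED-like data frame:
#'   `chrom`, `start` (0-based), `end`, `gene_id`, `cytokine_id`), `arch`
#'   (named list of [true_architecture]) and `config`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ck <- config$cytokines
  n_ck <- length(ck)
  ld <- vector("list", n_ck); names(ld) <- ck
  eaf <- vector("list", n_ck); names(eaf) <- ck
  arch <- vector("list", n_ck); names(arch) <- ck
  gene_rows <- vector("list", n_ck)
  m <- config$n_variants
  for (i in seq_len(n_ck)) {
    chrom <- as.character(i)
    ld[[i]] <- ar1_ld_matrix(m, config$ar1_rho, chrom = chrom,
                             start_pos = 1000000L, spacing = config$spacing)
    set.seed(sub_seed(config$seed, i))
    f <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    names(f) <- ld[[i]]$variant_id
    eaf[[i]] <- f
    # gene body occupies the middle fifth of the block
    lo <- ld[[i]]$pos[ceiling(m * 0.4)]
    hi <- ld[[i]]$pos[ceiling(m * 0.6)]
    gene_rows[[i]] <- data.frame(chrom = chrom, start = lo - 1L, end = hi,
                                 gene_id = paste0("GENE_", ck[i]),
                                 cytokine_id = ck[i])
  }
  gene_panel <- do.call(rbind, gene_rows)
  # plant cis effects across each gene's cis window; picks are spread out
  # so they stay mutually independent at the instrument-clumping r2
  for (i in seq_len(n_ck)) {
    k_cis <- length(config$cis_effects)
    picks <- round(seq(0.25 * m, 0.75 * m, length.out = k_cis))
    b <- stats::setNames(config$cis_effects, ld[[i]]$variant_id[picks])
    arch[[i]] <- list(cis = b)
  }
  # add network effects: cytokine b inherits theta * (a's cis effects)
  theta <- config$network_theta
  effects <- vector("list", n_ck); names(effects) <- ck
  for (bi in seq_len(n_ck)) {
    b_all <- arch[[bi]]$cis
    for (ai in seq_len(n_ck)) {
      th <- theta[ai, bi]
      if (ai != bi && th != 0) {
        inherited <- th * arch[[ai]]$cis
        b_all <- c(b_all, inherited)
      }
    }
    h2 <- sum(b_all^2) + 1e-9
    effects[[bi]] <- true_architecture(b_all, cis_gene = paste0("GENE_", ck[bi]),
                                       trait_h2 = max(h2, 0.1),
                                       assay_shift = config$assay_shift,
                                       cohort_specific = config$cohort_specific)
  }
  all_eaf <- unlist(unname(eaf))
  sumstats <- vector("list", n_ck); names(sumstats) <- ck
  idx <- 0L
  for (i in seq_len(n_ck)) {
    per_cohort <- list()
    for (co in config$cohorts) {
      idx <- idx + 1L
      if (!(co %in% config$panel_overlap[[ck[i]]])) next
      per_cohort[[co]] <- simulate_cohort_sumstats(
        unname(ld), effects[[i]], config$sample_sizes[[co]], all_eaf,
        seed = sub_seed(config$seed, 1000L + idx),
        cohort_id = co, trait_id = ck[i],
        palindromic_frac = config$palindromic_frac)
    }
    sumstats[[ck[i]]] <- per_cohort
  }
  list(sumstats = sumstats, ld = ld, eaf = eaf, gene_panel = gene_panel,
       arch = effects, config = config)
}

#' Simulate a cis-eQTL exposure set
#'
#' Expression of a gene measured in a large expression cohort: a
#' quantitative GWAS over the gene's LD block with planted cis effects,
#' reusing the summary-statistic model of [simulate_cohort_sumstats()].
#'
#' @param ld [ld_matrix] for the gene region.
#' @param eaf Frequencies for the region.
#' @param gene_id Gene identifier.
#' @param cis_effects Standardized joint effects for the expression trait
#'   (planted at the same relative positions as the panel's cis signals).
#' @param n Expression-cohort sample size (default 30000).
#' @param seed Integer seed.
#'
#' @return A [sumstats_set] with `trait_id = gene_id`.
#' @export
simulate_eqtl_sumstats <- function(ld, eaf, gene_id, cis_effects, n = 30000,
                                   seed = 1L) {
  arch <- true_architecture(cis_effects, cis_gene = gene_id,
                            trait_h2 = max(sum(cis_effects^2) + 1e-9, 0.1))
  simulate_cohort_sumstats(ld, arch, n, eaf, seed,
                           cohort_id = "expression_cohort", trait_id = gene_id)
}
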