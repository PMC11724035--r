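# End-to-end orchestration on synthetic data: simulate -> meta -> loci ->
# finemap -> ldsc -> mr network -> disease screen -> twas -> coloc ->
# report, every stage materialized as a plain TSV.

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Demonstration pipeline configuration
#'
#' Three cohorts, eight cytokines and two diseases with one planted
#' cytokine-to-cytokine causal link (CK1 raises CK2, 0.4 SD per SD) and
#' two planted cytokine-to-disease effects (CK1 raises disease risk at
#' 0.3 log-odds per SD; CK2 lowers disease2 risk at -0.25), so the
#' network, screen and colocalization stages all have recoverable truth.
#'
#' @param seed Master seed.
#' @param n_cytokines Number of cytokines (>= 2; default 8).
#' @return A [sim_config] with `network_theta` and `disease_params$theta`
#'   populated.
#' @export
demo_config <- function(seed = 1L, n_cytokines = 8L) {
  ck <- paste0("CK", seq_len(n_cytokines))
  theta_net <- matrix(0, n_cytokines, n_cytokines, dimnames = list(ck, ck))
  theta_net["CK1", "CK2"] <- 0.4
  diseases <- c("disease1", "disease2")
  theta_dis <- matrix(0, n_cytokines, 2, dimnames = list(ck, diseases))
  theta_dis["CK1", "disease1"] <- 0.3
  theta_dis["CK2", "disease2"] <- -0.25
  sim_config(cytokines = ck, network_theta = theta_net,
             assay_shift = c(cohortA = 1, cohortB = 0.85, cohortC = 1.15),
             disease_params = list(n_case = 20000, n_control = 40000,
                                   theta = theta_dis),
             seed = seed)
}

simulate_diseases <- function(panel) {
  config <- panel$config
  theta <- config$disease_params$theta
  if (is.null(theta)) return(list())
  all_eaf <- unlist(unname(panel$eaf))
  out <- list()
  for (d in seq_len(ncol(theta))) {
    gamma <- numeric(0)
    for (ck in rownames(theta)) {
      if (theta[ck, d] != 0) {
        g <- theta[ck, d] * panel$arch[[ck]]$causal_effects
        gamma <- c(gamma, g)
      }
    }
    if (length(gamma) > 0) {
      gamma <- tapply(gamma, names(gamma), sum)  # sum effects at shared variants
    }
    ds <- colnames(theta)[d]
    out[[ds]] <- simulate_disease_gwas(
      unname(panel$ld), gamma, theta_true = 1,
      n_case = config$disease_params$n_case,
      n_control = config$disease_params$n_control,
      eaf = all_eaf, seed = sub_seed(config$seed, 5000L + d), trait_id = ds)
  }
  out
}

simulate_eqtl_panel <- function(panel, n = 30000, effect = 0.15) {
  config <- panel$config
  out <- list()
  for (i in seq_along(config$cytokines)) {
    ck <- config$cytokines[i]
    gene <- paste0("GENE_", ck)
    cis <- panel$arch[[ck]]$causal_effects
    cis <- cis[grepl(paste0("^snp", i, "_"), names(cis))]  # own-region effects
    eff <- stats::setNames(rep(effect, length(cis)), names(cis))
    out[[gene]] <- simulate_eqtl_sumstats(panel$ld[[ck]], panel$eaf[[ck]],
                                          gene, eff, n = n,
                                          seed = sub_seed(config$seed, 7000L + i))
  }
  out
}

#' Run the full analysis pipeline on synthetic data
#'
#' Simulates the multi-cohort cytokine panel, disease GWASs and eQTL
#' exposure sets defined by `config`, then runs meta-analysis,
#' replication, locus calling, fine-mapping, LD-score genetic
#' correlation, network MR, the disease screen, transcriptome-wide MR and
#' colocalization of FDR-significant screen hits, and summarizes the
#' results. With `out_dir` set, every stage writes a TSV and a JSON
#' manifest records the configuration, seed and per-stage row counts;
#' outputs are byte-identical across reruns with the same config.
#'
#' @param config A [sim_config] (see [demo_config()]).
#' @param out_dir Output directory (created); `NULL` skips writing.
#' @param gw_p Genome-wide significance threshold (default 5e-8).
#' @param locus_r2 Clumping threshold for locus calling (default 0.001).
#' @param instrument_r2 Clumping threshold for MR instruments (default
#'   0.1).
#' @param flank_bp Cis window flank (default 300 kb).
#' @param fdr_level FDR level for MR families (default 0.05).
#' @param coloc_threshold PP4 call threshold (default 0.8).
#' @param coverage Credible-set coverage target (default 0.95).
#' @param stages Character vector of stages to run (any of `"finemap"`,
#'   `"ldsc"`, `"network"`, `"screen"`, `"twas"`, `"coloc"`); the
#'   simulate/meta/loci core always runs.
#'
#' @return List with `panel`, `meta` (named list), `replication`,
#'   `loci`, `finemap`, `ldsc`, `network`, `screen`, `twas`, `chains`,
#'   `coloc` and `summary`.
#' @export
run_pipeline <- function(config = demo_config(), out_dir = NULL,
                         gw_p = 5e-8, locus_r2 = 0.001, instrument_r2 = 0.1,
                         flank_bp = 3e5, fdr_level = 0.05,
                         coloc_threshold = 0.8, coverage = 0.95,
                         stages = c("finemap", "ldsc", "network", "screen",
                                    "twas", "coloc")) {
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ck_names <- config$cytokines

  # --- simulate ---------------------------------------------------------
  panel <- simulate_panel(config)
  diseases <- simulate_diseases(panel)
  eqtl <- if ("twas" %in% stages) simulate_eqtl_panel(panel) else list()
  if (!is.null(out_dir)) {
    ss_dir <- file.path(out_dir, "sumstats")
    dir.create(ss_dir, showWarnings = FALSE)
    for (ck in ck_names) for (co in names(panel$sumstats[[ck]])) {
      write_sumstats(panel$sumstats[[ck]][[co]],
                     file.path(ss_dir, paste0(ck, "_", co, ".tsv")))
    }
    for (ds in names(diseases)) {
      write_sumstats(diseases[[ds]], file.path(ss_dir, paste0(ds, ".tsv")))
    }
    write_tsv(panel$gene_panel, file.path(out_dir, "gene_panel.tsv"))
    truth <- do.call(rbind, lapply(ck_names, function(ck) {
      b <- panel$arch[[ck]]$causal_effects
      data.frame(cytokine = ck, variant_id = names(b), effect = unname(b))
    }))
    write_tsv(truth, file.path(out_dir, "truth_registry.tsv"))
    ld_dir <- file.path(out_dir, "ld")
    dir.create(ld_dir, showWarnings = FALSE)
    for (ck in ck_names) {
      b <- panel$ld[[ck]]
      utils::write.table(round(b$R, 6), file.path(ld_dir, paste0(ck, ".ld")),
                         sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      write_tsv(data.frame(variant_id = b$variant_id, chrom = b$chrom,
                           pos = b$pos),
                file.path(ld_dir, paste0(ck, ".varindex.tsv")))
    }
  }

  # --- meta + replication ----------------------------------------------
  meta_list <- list()
  lambdas <- numeric(0)
  for (ck in ck_names) {
    sets <- lapply(config$cohorts, function(co) panel$sumstats[[ck]][[co]])
    names(sets) <- config$cohorts
    meta_list[[ck]] <- meta_analyze(sets)
    lambdas[ck] <- genomic_lambda(meta_list[[ck]]$p_meta)
  }
  replication <- list()
  for (ck in ck_names) {
    cohorts_here <- names(panel$sumstats[[ck]])
    if (length(cohorts_here) < 2) next
    for (ref in cohorts_here) {
      targets <- panel$sumstats[[ck]][setdiff(cohorts_here, ref)]
      replication[[paste(ck, ref)]] <-
        replication_rates(panel$sumstats[[ck]][[ref]], targets, gw_p = gw_p)
    }
  }
  replication <- do.call(rbind, replication)
  rownames(replication) <- NULL
  rep_summary <- if (!is.null(replication)) replication_summary(replication) else NULL

  # --- loci -------------------------------------------------------------
  ld_all <- unname(panel$ld)
  loci_list <- list()
  ev <- numeric(0)
  for (ck in ck_names) {
    leads <- clump(meta_list[[ck]][, c("variant_id", "chrom", "pos", "p_meta")] |>
                     stats::setNames(c("variant_id", "chrom", "pos", "pvalue")),
                   ld_all, p_threshold = gw_p, r2_threshold = locus_r2)
    loci <- merge_to_loci(leads, trait_id = ck)
    win <- gene_window_for(panel$gene_panel, ck)
    loci <- classify_cis_trans(loci, win, flank_bp = flank_bp)
    loci_list[[ck]] <- loci
    at <- match(loci$lead_variant_id, meta_list[[ck]]$variant_id)
    ev[ck] <- explained_variance(meta_list[[ck]]$eaf[at],
                                 meta_list[[ck]]$beta_hat[at])
  }
  loci_all <- do.call(rbind, loci_list)
  rownames(loci_all) <- NULL

  # --- finemap ----------------------------------------------------------
  finemap_all <- NULL
  if ("finemap" %in% stages) {
    fm <- lapply(ck_names, function(ck) {
      if (nrow(loci_list[[ck]]) == 0) return(NULL)
      cbind(trait_id = ck,
            finemap_loci(meta_list[[ck]], loci_list[[ck]], coverage = coverage))
    })
    finemap_all <- do.call(rbind, Filter(Negate(is.null), fm))
    rownames(finemap_all) <- NULL
  }

  # --- ldsc -------------------------------------------------------------
  ldsc_out <- NULL
  if ("ldsc" %in% stages && length(ck_names) >= 2) {
    ids <- meta_list[[1]]$variant_id
    Z <- vapply(ck_names, function(ck) {
      meta_list[[ck]]$z_meta[match(ids, meta_list[[ck]]$variant_id)]
    }, numeric(length(ids)))
    n_tr <- vapply(ck_names, function(ck) stats::median(meta_list[[ck]]$n_total),
                   numeric(1))
    ell <- ld_scores(ld_all)[ids]
    ldsc_out <- rg_matrix(Z, n_tr, ell)
  }

  # --- mr network -------------------------------------------------------
  network <- NULL
  if ("network" %in% stages && length(ck_names) >= 2) {
    network <- mr_network(meta_list, panel$gene_panel, ld_all,
                          flank_bp = flank_bp, r2_cut = instrument_r2,
                          fdr_level = fdr_level, seed = config$seed)
  }

  # --- disease screen ---------------------------------------------------
  screen <- NULL
  if ("screen" %in% stages && length(diseases) > 0) {
    screen <- disease_screen(meta_list, diseases, panel$gene_panel, ld_all,
                             flank_bp = flank_bp, r2_cut = instrument_r2,
                             fdr_level = fdr_level, seed = config$seed)
  }

  # --- twas + upstream chains ------------------------------------------
  twas <- NULL; chains <- NULL
  if ("twas" %in% stages && length(eqtl) > 0) {
    twas <- twas_mr(eqtl, meta_list, panel$gene_panel, ld_all,
                    flank_bp = flank_bp, fdr_level = fdr_level,
                    seed = config$seed)
    if (!is.null(twas) && !is.null(screen)) {
      ts <- twas[twas$significant %in% TRUE, c("exposure", "outcome")]
      sc <- screen[screen$significant %in% TRUE, c("exposure", "outcome")]
      chains <- merge(stats::setNames(ts, c("gene", "cytokine")),
                      stats::setNames(sc, c("cytokine", "disease")),
                      by = "cytokine")[, c("gene", "cytokine", "disease")]
    }
  }

  # --- coloc ------------------------------------------------------------
  coloc_out <- NULL
  if ("coloc" %in% stages && !is.null(screen)) {
    hits <- unique(screen[screen$significant %in% TRUE, c("exposure", "outcome")])
    rows <- lapply(seq_len(nrow(hits)), function(i) {
      ck <- hits$exposure[i]; ds <- hits$outcome[i]
      win <- gene_window_for(panel$gene_panel, ck)
      m <- meta_list[[ck]]
      reg1 <- m[m$chrom == win$chrom & m$pos >= win$start - flank_bp &
                  m$pos <= win$end + flank_bp, ]
      d <- diseases[[ds]]$records
      reg2 <- d[d$chrom == win$chrom & d$pos >= win$start - flank_bp &
                  d$pos <= win$end + flank_bp, ]
      res <- coloc_abf(reg1, reg2, W2 = 0.2^2,
                       region_id = paste0(ck, "__", ds))
      coloc_call(res, threshold = coloc_threshold)
    })
    coloc_out <- do.call(rbind, rows)
  }

  # --- report -----------------------------------------------------------
  summary <- summarize_results(meta_list, loci_all, network, screen,
                               coloc_out, rep_summary, lambdas, ev)

  result <- list(panel = panel, diseases = diseases, meta = meta_list,
                 replication = replication, replication_summary = rep_summary,
                 loci = loci_all, finemap = finemap_all, ldsc = ldsc_out,
                 network = network, screen = screen, twas = twas,
                 chains = chains, coloc = coloc_out, lambdas = lambdas,
                 explained_variance = ev, summary = summary)

  if (!is.null(out_dir)) {
    for (ck in ck_names) {
      write_tsv(meta_list[[ck]], file.path(out_dir, paste0("meta_", ck, ".tsv")))
    }
    if (!is.null(replication)) write_tsv(replication, file.path(out_dir, "replication.tsv"))
    if (!is.null(rep_summary)) write_tsv(rep_summary, file.path(out_dir, "replication_summary.tsv"))
    write_tsv(loci_all, file.path(out_dir, "loci.tsv"))
    if (!is.null(finemap_all)) write_tsv(finemap_all, file.path(out_dir, "finemap.tsv"))
    if (!is.null(ldsc_out)) {
      write_tsv(ldsc_out$details, file.path(out_dir, "ldsc.tsv"))
      utils::write.table(round(ldsc_out$rg, 6), file.path(out_dir, "rg_matrix.tsv"),
                         sep = "\t", quote = FALSE)
    }
    if (!is.null(network)) write_tsv(network, file.path(out_dir, "mr_network.tsv"))
    if (!is.null(screen)) write_tsv(screen, file.path(out_dir, "mr_screen.tsv"))
    if (!is.null(twas)) write_tsv(twas, file.path(out_dir, "mr_twas.tsv"))
    if (!is.null(chains) && nrow(chains) > 0) write_tsv(chains, file.path(out_dir, "chains.tsv"))
    if (!is.null(coloc_out)) write_tsv(coloc_out, file.path(out_dir, "coloc.tsv"))
    manifest <- list(
      package = "cytomr",
      seed = config$seed,
      cohorts = config$cohorts,
      cytokines = ck_names,
      thresholds = list(gw_p = gw_p, locus_r2 = locus_r2,
                        instrument_r2 = instrument_r2, flank_bp = flank_bp,
                        fdr_level = fdr_level, coloc_threshold = coloc_threshold,
                        coverage = coverage),
      stages = stages,
      rows = list(
        meta = sum(vapply(meta_list, nrow, integer(1))),
        loci = nrow(loci_all),
        finemap = if (is.null(finemap_all)) 0L else nrow(finemap_all),
        network = if (is.null(network)) 0L else nrow(network),
        screen = if (is.null(screen)) 0L else nrow(screen),
        coloc = if (is.null(coloc_out)) 0L else nrow(coloc_out)),
      summary = summary)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

#' Summary statistics over the pipeline outputs
#'
#' Aggregates the stage outputs into the headline quantities: locus
#' counts (total/cis/trans), the Spearman rank correlation between lead
#' minor-allele frequency and absolute standardized effect, a
#' Mann-Whitney comparison of cis versus trans lead effect sizes, a
#' pleiotropy histogram (lead variants by number of associated
#' cytokines, optionally excluding an HLA-like interval), network and
#' screen hit counts, colocalization counts, replication medians, and
#' the genomic-lambda and explained-variance ranges.
#'
#' @param meta_list Named list of meta data frames.
#' @param loci Combined locus table (with `label`, `trait_id`).
#' @param network,screen,coloc,rep_summary Stage outputs (or `NULL`).
#' @param lambdas,explained_variance Named per-trait vectors.
#' @param hla_exclude Optional list(chrom, start, end) interval excluded
#'   from the pleiotropy count (default `NULL`).
#'
#' @return Named list of summary quantities.
#' @export
summarize_results <- function(meta_list, loci, network = NULL, screen = NULL,
                              coloc = NULL, rep_summary = NULL,
                              lambdas = NULL, explained_variance = NULL,
                              hla_exclude = NULL) {
  out <- list(n_loci = nrow(loci),
              n_cis = sum(loci$label == "cis", na.rm = TRUE),
              n_trans = sum(loci$label == "trans", na.rm = TRUE))
  # lead-variant table with per-trait effect sizes
  leads <- NULL
  if (nrow(loci) > 0) {
    leads <- do.call(rbind, lapply(seq_len(nrow(loci)), function(i) {
      m <- meta_list[[loci$trait_id[i]]]
      at <- match(loci$lead_variant_id[i], m$variant_id)
      data.frame(trait_id = loci$trait_id[i], variant_id = loci$lead_variant_id[i],
                 chrom = loci$chrom[i], pos = loci$lead_pos[i],
                 label = loci$label[i],
                 maf = pmin(m$eaf[at], 1 - m$eaf[at]),
                 abs_beta = abs(m$beta_hat[at]))
    }))
  }
  if (!is.null(leads) && nrow(leads) >= 3) {
    ct <- suppressWarnings(stats::cor.test(leads$maf, leads$abs_beta,
                                           method = "spearman", exact = FALSE))
    out$maf_beta_spearman <- unname(ct$estimate)
    out$maf_beta_spearman_p <- ct$p.value
  } else {
    out$maf_beta_spearman <- NA_real_
    out$maf_beta_spearman_p <- NA_real_
  }
  cis_b <- leads$abs_beta[leads$label == "cis"]
  trans_b <- leads$abs_beta[leads$label == "trans"]
  if (length(cis_b) >= 1 && length(trans_b) >= 1) {
    wt <- suppressWarnings(stats::wilcox.test(cis_b, trans_b, exact = FALSE))
    out$cis_trans_test_p <- wt$p.value
    out$mean_abs_beta_cis <- mean(cis_b)
    out$mean_abs_beta_trans <- mean(trans_b)
  }
  if (!is.null(leads)) {
    pl <- leads
    if (!is.null(hla_exclude)) {
      pl <- pl[!(pl$chrom == hla_exclude$chrom & pl$pos >= hla_exclude$start &
                   pl$pos <= hla_exclude$end), ]
    }
    counts <- table(table(unique(pl[, c("trait_id", "variant_id")])$variant_id))
    out$pleiotropy_histogram <- stats::setNames(as.integer(counts), names(counts))
    out$n_pleiotropic <- sum(as.integer(counts)[as.integer(names(counts)) > 1])
  }
  if (!is.null(network)) {
    sig <- network[network$significant %in% TRUE, ]
    out$network_edges <- nrow(sig)
    out$network_positive <- sum(sig$beta > 0)
    out$network_negative <- sum(sig$beta < 0)
  }
  if (!is.null(screen)) {
    sig <- screen[screen$significant %in% TRUE, ]
    out$screen_hits <- nrow(sig)
    out$screen_positive <- sum(sig$beta > 0)
    out$screen_negative <- sum(sig$beta < 0)
  }
  if (!is.null(coloc)) out$n_colocalized <- sum(coloc$colocalized)
  if (!is.null(rep_summary)) {
    out$replication_median <- stats::median(rep_summary$median_rate)
  }
  if (!is.null(lambdas)) out$lambda_range <- range(lambdas)
  if (!is.null(explained_variance)) out$explained_variance_range <-
    range(explained_variance)
  out
}
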