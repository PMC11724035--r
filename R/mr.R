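# Two-sample Mendelian randomization: cis-instrument selection, the IVW,
# Egger and weighted-median estimators, Steiger filtering, BH-FDR, and
# the network / disease-screen drivers.

mr_estimate_row <- function(method, beta, se, pvalue, n_snp,
                            egger_intercept = NA_real_,
                            intercept_p = NA_real_) {
  data.frame(method = method, beta = beta, se = se, pvalue = pvalue,
             n_snp = n_snp, egger_intercept = egger_intercept,
             intercept_p = intercept_p)
}

#' Select cis instruments for an exposure
#'
#' Filters an exposure's meta-analysis results to the window around its
#' encoding gene (gene span plus `flank_bp` on each side), keeps variants
#' associated below `p_cut` (strict), and clumps the survivors at
#' `r2_cut` so the retained instruments are approximately independent.
#' cis-eQTL exposures conventionally use a stricter `r2_cut = 0.01`.
#'
#' @param meta Meta-analysis data frame (needs `variant_id`, `chrom`,
#'   `pos`, `pvalue` or `p_meta`).
#' @param gene_window List/row with `chrom`, `start`, `end` (1-based).
#' @param ld LD reference for clumping.
#' @param flank_bp Cis window flank (default 300 kb).
#' @param p_cut Association threshold (default 5e-5, strict `<`).
#' @param r2_cut Clumping threshold (default 0.1).
#'
#' @return Character vector of instrument variant ids (possibly empty,
#'   with a message giving the reason).
#' @export
select_cis_instruments <- function(meta, gene_window, ld, flank_bp = 3e5,
                                   p_cut = 5e-5, r2_cut = 0.1) {
  meta <- as.data.frame(meta)
  if (!"pvalue" %in% names(meta) && "p_meta" %in% names(meta)) {
    meta$pvalue <- meta$p_meta
  }
  win <- meta[meta$chrom == as.character(gene_window$chrom) &
                meta$pos >= gene_window$start - flank_bp &
                meta$pos <= gene_window$end + flank_bp, , drop = FALSE]
  if (nrow(win) == 0) {
    message("select_cis_instruments: no variants in the cis window")
    return(character(0))
  }
  leads <- clump(win, ld, p_threshold = p_cut, r2_threshold = r2_cut,
                 window_bp = flank_bp + (gene_window$end - gene_window$start))
  if (nrow(leads) == 0) {
    message("select_cis_instruments: no variant below p_cut in the cis window")
  }
  leads$variant_id
}

#' Wald ratio estimate for a single instrument
#'
#' `beta = beta_Y / beta_X` with first-order standard error
#' `se = se_Y / |beta_X|`.
#'
#' @param beta_x,beta_y Exposure and outcome effects (beta_x != 0).
#' @param se_y Outcome standard error.
#'
#' @return One-row estimate data frame (`method = "wald"`).
#' @export
wald_ratio <- function(beta_x, beta_y, se_y) {
  if (beta_x == 0) stop("wald_ratio undefined for beta_x = 0")
  beta <- beta_y / beta_x
  se <- se_y / abs(beta_x)
  mr_estimate_row("wald", beta, se, 2 * stats::pnorm(-abs(beta / se)), 1L)
}

#' Fixed-effects inverse-variance-weighted MR
#'
#' The main causal estimator: `beta = sum(bx by / sy^2) / sum(bx^2 /
#' sy^2)` with `se = 1 / sqrt(sum(bx^2 / sy^2))` and a two-sided normal
#' p-value. With a single instrument it falls back to the Wald ratio
#' (logged), to which it is then identical.
#'
#' @param dat Harmonized data frame with `beta_x`, `beta_y`, `se_y`.
#'
#' @return One-row estimate data frame (`method = "ivw_fe"`).
#' @export
ivw_fixed <- function(dat) {
  n <- nrow(dat)
  if (n < 1) stop("no instruments")
  if (n == 1) {
    message("ivw_fixed: single instrument, falling back to Wald ratio")
    return(wald_ratio(dat$beta_x, dat$beta_y, dat$se_y))
  }
  w <- dat$beta_x^2 / dat$se_y^2
  beta <- sum(dat$beta_x * dat$beta_y / dat$se_y^2) / sum(w)
  se <- 1 / sqrt(sum(w))
  mr_estimate_row("ivw_fe", beta, se, 2 * stats::pnorm(-abs(beta / se)),
                  as.integer(n))
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome on exposure effects with a free
#' intercept, after orienting every row so that `beta_x >= 0`. The slope
#' is the causal estimate and the intercept captures directional
#' pleiotropy; p-values are t-based on `n_snp - 2` degrees of freedom.
#' Requires at least 3 instruments.
#'
#' @param dat Harmonized data frame with `beta_x`, `beta_y`, `se_y`.
#'
#' @return One-row estimate data frame (`method = "egger"`) with
#'   `egger_intercept` and `intercept_p`, or `NULL` with a message when
#'   fewer than 3 instruments are available.
#' @export
mr_egger <- function(dat) {
  n <- nrow(dat)
  if (n < 3) {
    message("mr_egger: needs >= 3 instruments, estimate omitted")
    return(NULL)
  }
  flip <- sign(dat$beta_x)
  flip[flip == 0] <- 1
  bx <- dat$beta_x * flip
  by <- dat$beta_y * flip
  fit <- stats::lm(by ~ bx, weights = 1 / dat$se_y^2)
  cf <- summary(fit)$coefficients
  slope <- cf["bx", "Estimate"]; slope_se <- cf["bx", "Std. Error"]
  icpt <- cf["(Intercept)", "Estimate"]; icpt_se <- cf["(Intercept)", "Std. Error"]
  mr_estimate_row("egger", slope, slope_se,
                  2 * stats::pt(-abs(slope / slope_se), df = n - 2),
                  as.integer(n),
                  egger_intercept = icpt,
                  intercept_p = 2 * stats::pt(-abs(icpt / icpt_se), df = n - 2))
}

# Weight-interpolated median of ratio estimates.
wm_point <- function(ratio, weight) {
  ord <- order(ratio)
  r <- ratio[ord]
  w <- weight[ord] / sum(weight)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(r)])
  stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median MR estimator
#'
#' Ratio estimates `by/bx` are weighted by the inverse variance of the
#' ratio (`bx^2 / sy^2`, normalized); the estimate interpolates the
#' weighted empirical distribution of ordered ratios at probability 0.5.
#' Consistent when instruments carrying at least half the weight are
#' valid. The standard error comes from a seeded parametric bootstrap of
#' `(beta_x, beta_y)`.
#'
#' @param dat Harmonized data frame with `beta_x`, `se_x`, `beta_y`,
#'   `se_y` (>= 3 rows).
#' @param n_boot Bootstrap replicates (default 200).
#' @param seed Bootstrap seed (default 1).
#'
#' @return One-row estimate data frame (`method = "weighted_median"`), or
#'   `NULL` with a message when fewer than 3 instruments are available.
#' @export
weighted_median <- function(dat, n_boot = 200, seed = 1L) {
  n <- nrow(dat)
  if (n < 3) {
    message("weighted_median: needs >= 3 instruments, estimate omitted")
    return(NULL)
  }
  est <- wm_point(dat$beta_y / dat$beta_x, dat$beta_x^2 / dat$se_y^2)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    bx <- stats::rnorm(n, dat$beta_x, dat$se_x)
    by <- stats::rnorm(n, dat$beta_y, dat$se_y)
    wm_point(by / bx, bx^2 / dat$se_y^2)
  }, numeric(1))
  se <- stats::sd(boots)
  mr_estimate_row("weighted_median", est, se,
                  2 * stats::pnorm(-abs(est / se)), as.integer(n))
}

#' Steiger filtering of reverse-causal instruments
#'
#' Drops instruments with a stronger (larger absolute standardized)
#' association with the outcome than with the exposure, i.e. rows with
#' `|beta_y| > |beta_x|` (strict); such variants are more plausibly acting
#' on the outcome first.
#'
#' @param dat Harmonized data frame with `beta_x`, `beta_y`.
#'
#' @return Filtered data frame; attribute `steiger_dropped` holds the
#'   dropped variant ids.
#' @export
steiger_filter <- function(dat) {
  drop <- abs(dat$beta_y) > abs(dat$beta_x)
  out <- dat[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "steiger_dropped") <- dat$variant_id[drop]
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values (q-values); one family per analysis (all
#' tested cytokine pairs of a network run, or all cytokine-by-disease
#' tests of a screen).
#'
#' @param p P-values in `(0, 1]`.
#' @return Q-values (same length).
#' @export
bh_fdr <- function(p) {
  stats::p.adjust(p, method = "BH")
}

# Run all applicable estimators on a harmonized instrument table.
mr_all_methods <- function(dat, n_boot = 200, seed = 1L) {
  out <- list(ivw_fixed(dat))
  if (nrow(dat) >= 3) {
    out <- c(out, list(mr_egger(dat), weighted_median(dat, n_boot, seed)))
  }
  do.call(rbind, Filter(Negate(is.null), out))
}

# Build a harmonized exposure/outcome table from two meta-style data
# frames restricted to the instrument ids. Both tables must carry
# variant_id, effect_allele, other_allele, eaf, beta/se columns (beta_hat/
# se_hat accepted); goes through harmonize_pair so swapped or flipped
# outcome records are aligned.
pair_table <- function(exposure, outcome, instruments,
                       exposure_id = "exposure", outcome_id = "outcome",
                       outcome_type = "quantitative") {
  exp_df <- normalize_assoc(exposure)
  out_df <- normalize_assoc(outcome)
  exp_df <- exp_df[exp_df$variant_id %in% instruments, , drop = FALSE]
  if (nrow(exp_df) == 0) return(NULL)
  shared <- intersect(exp_df$variant_id, out_df$variant_id)
  if (length(shared) == 0) return(NULL)
  ex_set <- sumstats_set(exp_df, exposure_id, "exposure", validate = FALSE)
  oy_set <- sumstats_set(out_df[out_df$variant_id %in% shared, , drop = FALSE],
                         outcome_id, "outcome",
                         trait_type = outcome_type, validate = FALSE)
  h <- suppressMessages(harmonize_pair(ex_set, oy_set))
  if (nrow(h) == 0) return(NULL)
  h
}

# Accept meta_analyze() output or sumstats records as an association table.
normalize_assoc <- function(x) {
  if (inherits(x, "sumstats_set")) x <- x$records
  x <- as.data.frame(x)
  if (!"beta" %in% names(x) && "beta_hat" %in% names(x)) x$beta <- x$beta_hat
  if (!"se" %in% names(x) && "se_hat" %in% names(x)) x$se <- x$se_hat
  if (!"pvalue" %in% names(x) && "p_meta" %in% names(x)) x$pvalue <- x$p_meta
  if (!"n" %in% names(x) && "n_total" %in% names(x)) x$n <- x$n_total
  if (!"z" %in% names(x)) x$z <- x$beta / x$se
  x
}

#' Cytokine-network Mendelian randomization
#'
#' For every ordered pair of cytokines (exposure -> outcome): select the
#' exposure's cis instruments, remove any variant that is also in the
#' outcome's own instrument list (so no variant instruments two cytokines
#' at once), harmonize against the outcome meta-analysis, Steiger-filter,
#' optionally drop heterogeneous variants (`het_p < het_cut`), and run
#' IVW plus Egger and weighted-median sensitivity estimators. IVW
#' p-values are BH-adjusted across all tested pairs (one family per run).
#'
#' @param meta_list Named list of meta-analysis data frames, one per
#'   cytokine.
#' @param gene_panel BED-like data frame (`chrom`, `start` 0-based,
#'   `end`, `gene_id`, `cytokine_id`).
#' @param ld LD reference (list of blocks).
#' @param flank_bp,p_cut,r2_cut Instrument selection (see
#'   [select_cis_instruments()]).
#' @param het_exclude Drop instruments with meta `het_p < het_cut`
#'   (sensitivity re-run; default `FALSE`).
#' @param het_cut Heterogeneity p threshold (default 0.05).
#' @param fdr_level FDR level used for the `significant` flag (default
#'   0.05).
#' @param n_boot,seed Weighted-median bootstrap controls.
#'
#' @return Data frame with one row per (pair, method): `exposure`,
#'   `outcome`, `method`, `n_snp`, `beta`, `se`, `pvalue`,
#'   `egger_intercept`, `intercept_p`, `n_steiger_dropped`, `q` (IVW rows
#'   only), `significant`, `status`. Skipped pairs appear with `status`
#'   explaining why.
#' @export
mr_network <- function(meta_list, gene_panel, ld, flank_bp = 3e5,
                       p_cut = 5e-5, r2_cut = 0.1, het_exclude = FALSE,
                       het_cut = 0.05, fdr_level = 0.05, n_boot = 200,
                       seed = 1L) {
  traits <- names(meta_list)
  if (length(traits) < 2) stop("mr_network needs at least 2 cytokines")
  windows <- lapply(traits, function(tr) gene_window_for(gene_panel, tr))
  names(windows) <- traits
  instruments <- lapply(traits, function(tr) {
    if (is.null(windows[[tr]])) return(character(0))
    suppressMessages(select_cis_instruments(meta_list[[tr]], windows[[tr]], ld,
                                            flank_bp, p_cut, r2_cut))
  })
  names(instruments) <- traits
  rows <- list(); skips <- list()
  for (ex in traits) for (oy in traits) {
    if (ex == oy) next
    ins <- setdiff(instruments[[ex]], instruments[[oy]])
    status <- NULL
    if (length(ins) == 0) {
      status <- "no_instruments_after_overlap_exclusion"
    } else {
      dat <- pair_table(meta_list[[ex]], meta_list[[oy]], ins, ex, oy)
      if (is.null(dat)) status <- "no_overlapping_variants"
    }
    if (is.null(status)) {
      dat$variant_id <- as.character(dat$variant_id)
      if (het_exclude) {
        hp <- meta_list[[ex]]$het_p[match(dat$variant_id,
                                          meta_list[[ex]]$variant_id)]
        dat <- dat[is.na(hp) | hp >= het_cut, , drop = FALSE]
      }
      if (nrow(dat) > 0) dat <- steiger_filter(dat)
      if (nrow(dat) == 0) {
        status <- "no_instruments_after_filtering"
      } else {
        est <- suppressMessages(mr_all_methods(dat, n_boot, seed))
        est <- cbind(exposure = ex, outcome = oy, est,
                     n_steiger_dropped = length(attr(dat, "steiger_dropped")),
                     status = "ok")
        rows[[paste(ex, oy)]] <- est
      }
    }
    if (!is.null(status)) {
      skips[[paste(ex, oy)]] <- data.frame(
        exposure = ex, outcome = oy, method = NA_character_,
        beta = NA_real_, se = NA_real_, pvalue = NA_real_,
        n_snp = 0L, egger_intercept = NA_real_, intercept_p = NA_real_,
        n_steiger_dropped = NA_integer_, status = status)
    }
  }
  out <- do.call(rbind, c(rows, skips))
  rownames(out) <- NULL
  out$q <- NA_real_
  ivw <- out$method %in% "ivw_fe" | out$method %in% "wald"
  out$q[ivw] <- bh_fdr(out$pvalue[ivw])
  out$significant <- !is.na(out$q) & out$q < fdr_level
  out
}

#' Gene window for a cytokine from the BED-like gene panel
#'
#' Converts the panel's 0-based half-open coordinates to the 1-based
#' inclusive window used everywhere else (this is the single conversion
#' boundary between the two conventions).
#'
#' @param gene_panel BED-like data frame (`chrom`, `start`, `end`,
#'   `gene_id`, `cytokine_id`).
#' @param trait Cytokine id to look up.
#'
#' @return List with `chrom`, `start`, `end` (1-based inclusive), or
#'   `NULL` when the trait has no panel entry.
#' @export
gene_window_for <- function(gene_panel, trait) {
  row <- gene_panel[gene_panel$cytokine_id == trait, , drop = FALSE]
  if (nrow(row) == 0) return(NULL)
  # BED-like 0-based half-open -> 1-based inclusive
  list(chrom = as.character(row$chrom[1]), start = row$start[1] + 1L,
       end = row$end[1])
}

#' Cytokine-to-disease Mendelian randomization screen
#'
#' Per cytokine-by-disease pair: cis instruments for the cytokine,
#' harmonization against the disease GWAS (log-odds scale),
#' Steiger-style filtering off by default (exposure and outcome are on
#' different scales), IVW plus sensitivity estimators, and BH-FDR across
#' the whole screen. Effects are reported as odds ratios per SD of the
#' cytokine with 95% confidence intervals `exp(beta +/- 1.96 se)`.
#'
#' @param meta_list Named list of cytokine meta-analysis data frames.
#' @param disease_list Named list of binary-outcome [sumstats_set]s.
#' @param gene_panel,ld,flank_bp,p_cut,r2_cut As in [mr_network()].
#' @param fdr_level FDR level for the `significant` flag (default 0.05).
#' @param n_boot,seed Weighted-median bootstrap controls.
#'
#' @return Data frame with one row per (pair, method) plus `or`,
#'   `or_lo`, `or_hi` columns and family-wide `q` on the IVW rows.
#' @export
disease_screen <- function(meta_list, disease_list, gene_panel, ld,
                           flank_bp = 3e5, p_cut = 5e-5, r2_cut = 0.1,
                           fdr_level = 0.05, n_boot = 200, seed = 1L) {
  rows <- list(); skips <- list()
  for (ck in names(meta_list)) {
    win <- gene_window_for(gene_panel, ck)
    ins <- if (is.null(win)) character(0) else
      suppressMessages(select_cis_instruments(meta_list[[ck]], win, ld,
                                              flank_bp, p_cut, r2_cut))
    for (ds in names(disease_list)) {
      if (length(ins) == 0) {
        skips[[paste(ck, ds)]] <- data.frame(
          exposure = ck, outcome = ds, method = NA_character_,
          beta = NA_real_, se = NA_real_, pvalue = NA_real_, n_snp = 0L,
          egger_intercept = NA_real_, intercept_p = NA_real_,
          status = "no_instruments")
        next
      }
      dat <- pair_table(meta_list[[ck]], disease_list[[ds]], ins, ck, ds,
                        outcome_type = "binary")
      if (is.null(dat)) {
        skips[[paste(ck, ds)]] <- data.frame(
          exposure = ck, outcome = ds, method = NA_character_,
          beta = NA_real_, se = NA_real_, pvalue = NA_real_, n_snp = 0L,
          egger_intercept = NA_real_, intercept_p = NA_real_,
          status = "no_overlapping_variants")
        next
      }
      est <- suppressMessages(mr_all_methods(dat, n_boot, seed))
      rows[[paste(ck, ds)]] <- cbind(exposure = ck, outcome = ds, est,
                                     status = "ok")
    }
  }
  out <- do.call(rbind, c(rows, skips))
  rownames(out) <- NULL
  out$or <- exp(out$beta)
  out$or_lo <- exp(out$beta - 1.96 * out$se)
  out$or_hi <- exp(out$beta + 1.96 * out$se)
  out$q <- NA_real_
  ivw <- out$method %in% "ivw_fe" | out$method %in% "wald"
  out$q[ivw] <- bh_fdr(out$pvalue[ivw])
  out$significant <- !is.na(out$q) & out$q < fdr_level
  out
}

#' Transcriptome-wide MR (eQTL exposures)
#'
#' Gene-expression exposures instrumenting cytokine (or disease)
#' outcomes: identical machinery to the screen but with cis-eQTL
#' instruments clumped at the stricter `r2_cut = 0.01`.
#'
#' @param eqtl_list Named list of eQTL [sumstats_set]s (one per gene;
#'   names are gene ids matching `gene_panel$gene_id`).
#' @param outcome_list Named list of outcome association tables (meta
#'   data frames or [sumstats_set]s).
#' @param gene_panel,ld,flank_bp,p_cut As in [mr_network()].
#' @param r2_cut Clumping threshold for eQTL instruments (default 0.01).
#' @param fdr_level,n_boot,seed As in [mr_network()].
#'
#' @return Long-format estimate table with family-wide `q` on IVW rows.
#' @export
twas_mr <- function(eqtl_list, outcome_list, gene_panel, ld, flank_bp = 3e5,
                    p_cut = 5e-5, r2_cut = 0.01, fdr_level = 0.05,
                    n_boot = 200, seed = 1L) {
  rows <- list()
  for (g in names(eqtl_list)) {
    row <- gene_panel[gene_panel$gene_id == g, , drop = FALSE]
    if (nrow(row) == 0) next
    win <- list(chrom = as.character(row$chrom[1]), start = row$start[1] + 1L,
                end = row$end[1])
    exp_df <- normalize_assoc(eqtl_list[[g]])
    ins <- suppressMessages(select_cis_instruments(exp_df, win, ld, flank_bp,
                                                   p_cut, r2_cut))
    if (length(ins) == 0) next
    for (oy in names(outcome_list)) {
      dat <- pair_table(exp_df, outcome_list[[oy]], ins, g, oy)
      if (is.null(dat)) next
      est <- suppressMessages(mr_all_methods(dat, n_boot, seed))
      rows[[paste(g, oy)]] <- cbind(exposure = g, outcome = oy, est,
                                    status = "ok")
    }
  }
  if (length(rows) == 0) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- NA_real_
  ivw <- out$method %in% "ivw_fe" | out$method %in% "wald"
  out$q[ivw] <- bh_fdr(out$pvalue[ivw])
  out$significant <- !is.na(out$q) & out$q < fdr_level
  out
}

#' Directional concordance of sensitivity estimators with IVW
#'
#' Fraction of pairs whose Egger (or weighted-median) estimate agrees in
#' sign with the IVW estimate, computed over rows flagged significant.
#'
#' @param mr_table Output of [mr_network()], [disease_screen()] or
#'   [twas_mr()].
#'
#' @return Named numeric vector, one concordance fraction per sensitivity
#'   method (NA when no comparable rows).
#' @export
directional_concordance <- function(mr_table) {
  ok <- mr_table[!is.na(mr_table$method), ]
  main <- ok[ok$method %in% c("ivw_fe", "wald") & ok$significant, ]
  vapply(c(egger = "egger", weighted_median = "weighted_median"), function(m) {
    sens <- ok[ok$method == m, ]
    key <- paste(main$exposure, main$outcome)
    at <- match(key, paste(sens$exposure, sens$outcome))
    comp <- !is.na(at)
    if (!any(comp)) return(NA_real_)
    mean(sign(sens$beta[at[comp]]) == sign(main$beta[comp]))
  }, numeric(1))
}
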