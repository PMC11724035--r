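#' Greedy LD clumping
#'
#' Repeatedly takes the smallest-p unassigned variant below the
#' significance threshold as an index (lead) variant and removes every
#' unassigned variant within `window_bp` of it whose squared correlation
#' with it reaches `r2_threshold`, until no significant variant remains.
#' Ties on p are broken by ascending (chrom, pos). Variants absent from
#' the LD reference are excluded with a logged count.
#'
#' @param records Data frame with columns `variant_id`, `chrom`, `pos`,
#'   `pvalue`.
#' @param ld [ld_matrix] or list of blocks covering the candidates.
#' @param p_threshold Significance threshold (default genome-wide 5e-8).
#' @param r2_threshold Variants with `r2 >=` this value to a lead are
#'   assigned to it (default 0.001, the independence threshold used for
#'   locus calling; instrument selection uses 0.1).
#' @param window_bp Clumping window on each side of the lead (default
#'   1 Mb).
#'
#' @return Data frame of lead variants (`variant_id`, `chrom`, `pos`,
#'   `pvalue`), ordered by (chrom, pos).
#' @export
clump <- function(records, ld, p_threshold = 5e-8, r2_threshold = 0.001,
                  window_bp = 1e6) {
  records <- as.data.frame(records)
  idx <- ld_index(ld)
  known <- records$variant_id %in% names(idx$block)
  if (any(!known)) {
    message("clump: excluded ", sum(!known), " variant(s) absent from the LD reference")
    records <- records[known, , drop = FALSE]
  }
  cand <- records[!is.na(records$pvalue) & records$pvalue < p_threshold, ,
                  drop = FALSE]
  cand <- cand[order(cand$pvalue, cand$chrom, cand$pos), ]
  leads <- integer(0)
  assigned <- rep(FALSE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (assigned[i]) next
    leads <- c(leads, i)
    assigned[i] <- TRUE
    open <- which(!assigned & cand$chrom == cand$chrom[i] &
                    abs(cand$pos - cand$pos[i]) <= window_bp)
    if (length(open)) {
      r2 <- ld_r2_with(idx, cand$variant_id[i], cand$variant_id[open])
      assigned[open[r2 >= r2_threshold]] <- TRUE
    }
  }
  out <- cand[leads, c("variant_id", "chrom", "pos", "pvalue")]
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  out
}

#' Merge clumped leads into independent loci
#'
#' Chained merge: consecutive leads on the same chromosome separated by
#' at most `min_separation_bp` join the same locus, so a run of leads
#' each within 1 Mb of its neighbor forms a single locus. The locus lead
#' is its smallest-p member.
#'
#' @param leads Data frame as returned by [clump()] (sorted by chrom,
#'   pos).
#' @param min_separation_bp Maximum gap joining two leads (default 1 Mb:
#'   loci are independent when separated by more than 1 Mb in either
#'   direction).
#' @param trait_id Optional trait label copied to the output.
#'
#' @return Data frame with one row per locus: `locus_id`, `chrom`,
#'   `start`, `end` (span over members, 1-based inclusive),
#'   `lead_variant_id`, `lead_p`, `n_leads`, `members`
#'   (comma-collapsed ids), `trait_id`.
#' @export
merge_to_loci <- function(leads, min_separation_bp = 1e6, trait_id = NA_character_) {
  leads <- leads[order(leads$chrom, leads$pos), , drop = FALSE]
  n <- nrow(leads)
  if (n == 0) {
    return(data.frame(locus_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      lead_variant_id = character(0), lead_pos = integer(0),
                      lead_p = numeric(0), n_leads = integer(0),
                      members = character(0), trait_id = character(0)))
  }
  new_locus <- c(TRUE, leads$chrom[-1] != leads$chrom[-n] |
                   diff(leads$pos) > min_separation_bp)
  grp <- cumsum(new_locus)
  rows <- lapply(split(seq_len(n), grp), function(ii) {
    sub <- leads[ii, ]
    best <- which.min(sub$pvalue)
    data.frame(chrom = sub$chrom[1], start = min(sub$pos), end = max(sub$pos),
               lead_variant_id = sub$variant_id[best],
               lead_pos = sub$pos[best], lead_p = sub$pvalue[best],
               n_leads = nrow(sub),
               members = paste(sub$variant_id, collapse = ","))
  })
  out <- do.call(rbind, rows)
  out <- cbind(locus_id = sprintf("%s_locus%02d",
                                  ifelse(is.na(trait_id), "trait", trait_id),
                                  seq_len(nrow(out))),
               out, trait_id = trait_id)
  rownames(out) <- NULL
  out
}

#' Classify loci as cis- or trans-acting
#'
#' A locus is cis when its lead variant lies within the closed interval
#' `[gene_start - flank_bp, gene_end + flank_bp]` on the encoding gene's
#' chromosome, and trans otherwise.
#'
#' @param loci Data frame from [merge_to_loci()].
#' @param gene_window List or one-row data frame with `chrom`, `start`,
#'   `end` (1-based inclusive gene coordinates). `NULL` yields label
#'   `NA` with a message.
#' @param flank_bp Cis window flank (default 300 kb).
#'
#' @return `loci` with a `label` column (`"cis"`/`"trans"`).
#' @export
classify_cis_trans <- function(loci, gene_window, flank_bp = 3e5) {
  if (is.null(gene_window)) {
    message("classify_cis_trans: trait has no gene-panel entry; labels missing")
    loci$label <- NA_character_
    return(loci)
  }
  if (!all(c("chrom", "start", "end") %in% names(gene_window))) {
    stop("gene_window must provide chrom, start, end")
  }
  loci$label <- ifelse(
    loci$chrom == as.character(gene_window$chrom) &
      loci$lead_pos >= gene_window$start - flank_bp &
      loci$lead_pos <= gene_window$end + flank_bp,
    "cis", "trans")
  loci
}

#' Cross-assay replication of significant variants
#'
#' Takes the variants reaching genome-wide significance in a reference
#' cohort and asks, for each target cohort, what fraction replicate:
#' present in the target, target p below `rep_p`, and directionally
#' concordant (same sign of beta). Variants missing from the target panel
#' are excluded from the denominator by default (configurable), matching
#' availability-filtered replication reporting.
#'
#' @param reference A [sumstats_set].
#' @param targets Named list of [sumstats_set] target cohorts.
#' @param gw_p Genome-wide significance defining the reference set
#'   (default 5e-8).
#' @param rep_p Replication p-value threshold (default 0.05).
#' @param drop_missing Exclude reference variants absent from a target
#'   from that target's denominator (default `TRUE`).
#'
#' @return Data frame with one row per target: `reference_cohort`,
#'   `target_cohort`, `trait_id`, `n_significant`, `n_replicated`,
#'   `rate`.
#' @export
replication_rates <- function(reference, targets, gw_p = 5e-8, rep_p = 0.05,
                              drop_missing = TRUE) {
  ref <- reference$records
  sig <- ref[!is.na(ref$pvalue) & ref$pvalue < gw_p, , drop = FALSE]
  rows <- lapply(names(targets), function(tc) {
    tr <- targets[[tc]]$records
    at <- match(sig$variant_id, tr$variant_id)
    present <- !is.na(at)
    denom <- if (drop_missing) sig[present, , drop = FALSE] else sig
    at_d <- match(denom$variant_id, tr$variant_id)
    rep_ok <- !is.na(at_d) & tr$pvalue[at_d] < rep_p &
      sign(tr$beta[at_d]) == sign(denom$beta)
    n_sig <- nrow(denom)
    data.frame(reference_cohort = reference$cohort_id, target_cohort = tc,
               trait_id = reference$trait_id, n_significant = n_sig,
               n_replicated = sum(rep_ok),
               rate = if (n_sig > 0) sum(rep_ok) / n_sig else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize replication rates across traits
#'
#' Median and interquartile range of per-trait replication rates for each
#' (reference, target) cohort pair.
#'
#' @param reports Data frame of stacked [replication_rates()] outputs.
#'
#' @return Data frame with `reference_cohort`, `target_cohort`,
#'   `n_traits`, `median_rate`, `q25`, `q75`.
#' @export
replication_summary <- function(reports) {
  reports <- reports[!is.na(reports$rate), , drop = FALSE]
  key <- interaction(reports$reference_cohort, reports$target_cohort, drop = TRUE)
  rows <- lapply(split(reports, key), function(sub) {
    q <- stats::quantile(sub$rate, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(reference_cohort = sub$reference_cohort[1],
               target_cohort = sub$target_cohort[1],
               n_traits = nrow(sub), median_rate = q[2], q25 = q[1], q75 = q[3])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
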