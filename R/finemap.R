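#' Wakefield approximate Bayes factor (log scale)
#'
#' Log approximate Bayes factor for association of a single variant,
#' comparing a normal prior with variance `W` on the true effect against
#' the point null: `log ABF = 0.5 * (log(V / (V + W)) + z^2 * W / (V +
#' W))` with `V = se^2` and `z = beta / se`, oriented so that larger
#' values mean stronger association.
#'
#' @param beta Effect estimate(s).
#' @param se Standard error(s) (> 0).
#' @param W Prior variance of the true effect (default `0.15^2`, the
#'   usual choice for standardized quantitative traits).
#'
#' @return Log ABF (vectorized).
#' @export
wakefield_log_abf <- function(beta, se, W = 0.15^2) {
  if (any(se <= 0)) stop("se must be positive")
  if (any(W <= 0)) stop("prior variance W must be positive")
  V <- se^2
  z <- beta / se
  0.5 * (log(V / (V + W)) + z^2 * W / (V + W))
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' 95% credible set under a single-causal-variant model
#'
#' Assumes exactly one causal variant in the locus with a flat prior over
#' variants. Posterior inclusion probabilities are the per-variant
#' Wakefield ABFs normalized in log space; the credible set is the
#' minimal prefix of variants, ordered by descending PIP (ties broken by
#' position), whose cumulative PIP reaches the coverage target.
#'
#' This is a deliberate single-effect simplification: loci carrying
#' several independent signals are summarized by their strongest one.
#'
#' @param records Data frame with `variant_id`, `pos`, `beta`, `se` (the
#'   meta-analysis `beta_hat`/`se_hat` columns are accepted as synonyms).
#' @param W Prior effect variance (see [wakefield_log_abf()]).
#' @param coverage Coverage target in `(0, 1]` (default 0.95).
#' @param lead_variant_id Optional lead id; sets `contains_lead`.
#'
#' @return Object of class `credible_set`: list with `variant_ids`
#'   (descending PIP order), `pips` (same order, summing to 1 over the
#'   locus), `set` (ids in the credible set), `cumulative` (cumulative PIP
#'   of the set), `coverage_target`, `contains_lead` and `model =
#'   "single_causal_abf"`.
#' @export
credible_set <- function(records, W = 0.15^2, coverage = 0.95,
                         lead_variant_id = NULL) {
  records <- as.data.frame(records)
  if (!"beta" %in% names(records) && "beta_hat" %in% names(records)) {
    records$beta <- records$beta_hat
  }
  if (!"se" %in% names(records) && "se_hat" %in% names(records)) {
    records$se <- records$se_hat
  }
  stopifnot(nrow(records) >= 1)
  labf <- wakefield_log_abf(records$beta, records$se, W)
  lpip <- labf - log_sum_exp(labf)
  pip <- exp(lpip)
  ord <- order(-pip, records$pos)
  pip <- pip[ord]
  ids <- records$variant_id[ord]
  cum <- cumsum(pip)
  size <- which(cum >= coverage - 1e-12)[1]
  if (is.na(size)) size <- length(pip)
  set <- ids[seq_len(size)]
  structure(list(variant_ids = ids, pips = stats::setNames(pip, ids),
                 set = set, cumulative = cum[size],
                 coverage_target = coverage,
                 contains_lead = if (is.null(lead_variant_id)) NA else
                   lead_variant_id %in% set,
                 model = "single_causal_abf"),
            class = "credible_set")
}

#' @export
print.credible_set <- function(x, ...) {
  cat("<credible_set> ", length(x$set), "/", length(x$variant_ids),
      " variants, cumulative PIP ", sprintf("%.3f", x$cumulative),
      " (target ", x$coverage_target, ", single-causal ABF model)\n", sep = "")
  invisible(x)
}

#' Fine-map all loci of a trait
#'
#' Runs [credible_set()] on every locus, restricting to the locus span
#' plus a flank.
#'
#' @param meta Meta-analysis data frame (from [meta_analyze()]).
#' @param loci Locus table (from [merge_to_loci()]).
#' @param W,coverage See [credible_set()].
#' @param flank_bp Span flank for the fine-mapped region (default 100 kb).
#'
#' @return Data frame with one row per variant per locus: `locus_id`,
#'   `variant_id`, `pip`, `in_credible_set`, `contains_lead`,
#'   `set_size`.
#' @export
finemap_loci <- function(meta, loci, W = 0.15^2, coverage = 0.95,
                         flank_bp = 1e5) {
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    reg <- meta[meta$chrom == loci$chrom[i] &
                  meta$pos >= loci$start[i] - flank_bp &
                  meta$pos <= loci$end[i] + flank_bp, , drop = FALSE]
    cs <- credible_set(data.frame(variant_id = reg$variant_id, pos = reg$pos,
                                  beta = reg$beta_hat, se = reg$se_hat),
                       W = W, coverage = coverage,
                       lead_variant_id = loci$lead_variant_id[i])
    data.frame(locus_id = loci$locus_id[i], variant_id = cs$variant_ids,
               pip = unname(cs$pips),
               in_credible_set = cs$variant_ids %in% cs$set,
               contains_lead = cs$contains_lead, set_size = length(cs$set))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
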