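#' LD reference matrix
#'
#' Container for a signed pairwise variant correlation matrix with its
#' variant index. Correlations are on the haplotype scale, so `R[j, k]^2`
#' is the usual r-squared used for clumping and LD scores.
#'
#' @param R Square numeric matrix of signed correlations in `[-1, 1]`.
#' @param variant_id Character vector of unique variant identifiers.
#' @param chrom Chromosome label (single string).
#' @param pos Integer vector of 1-based base-pair positions, sorted
#'   ascending, parallel to `variant_id`.
#'
#' @return An object of class `ld_matrix`: a list with elements
#'   `variant_id`, `chrom`, `pos` and `R` (dimnames set to `variant_id`).
#' @export
ld_matrix <- function(R, variant_id, chrom, pos) {
  R <- as.matrix(R)
  m <- length(variant_id)
  if (nrow(R) != m || ncol(R) != m) {
    stop("R must be a ", m, " x ", m, " matrix matching variant_id")
  }
  if (anyDuplicated(variant_id)) stop("variant_id must be unique")
  if (length(pos) != m) stop("pos must be parallel to variant_id")
  if (is.unsorted(pos)) stop("pos must be sorted ascending")
  if (any(pos < 1)) stop("positions are 1-based; pos >= 1 required")
  if (max(abs(R - t(R))) > 1e-10) stop("R must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-10) stop("R must have unit diagonal")
  if (max(abs(R)) > 1 + 1e-10) stop("|R| must not exceed 1")
  ev_min <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8) stop("R is not positive semi-definite (min eigenvalue ",
                           format(ev_min), ")")
  dimnames(R) <- list(variant_id, variant_id)
  structure(list(variant_id = as.character(variant_id),
                 chrom = as.character(chrom[1]),
                 pos = as.integer(pos),
                 R = R),
            class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat("<ld_matrix> ", length(x$variant_id), " variants on chr", x$chrom,
      " [", min(x$pos), "-", max(x$pos), "]\n", sep = "")
  invisible(x)
}

#' AR(1) LD reference block
#'
#' Builds a first-order autoregressive correlation structure,
#' `R[j, k] = rho^|j - k|`, over equally spaced variants. AR(1)
#' correlation matrices are positive definite for `0 <= rho < 1`, which
#' makes them a convenient stand-in for a haplotype-panel LD reference.
#'
#' @param n_variants Number of variants in the block (>= 1).
#' @param rho AR(1) decay parameter in `[0, 1)`.
#' @param chrom Chromosome label.
#' @param start_pos 1-based position of the first variant.
#' @param spacing Base pairs between adjacent variants.
#' @param id_prefix Prefix for generated variant identifiers; defaults to
#'   `"snp<chrom>"`.
#'
#' @return An [ld_matrix] object.
#' @examples
#' ld <- ar1_ld_matrix(5, 0.5, chrom = "1")
#' ld$R[1, 3]  # 0.25
#' @export
ar1_ld_matrix <- function(n_variants, rho, chrom = "1", start_pos = 1000000L,
                          spacing = 2000L, id_prefix = NULL) {
  if (n_variants < 1) stop("n_variants must be >= 1")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1); rho >= 1 gives a non-PSD request")
  if (is.null(id_prefix)) id_prefix <- paste0("snp", chrom, "_")
  j <- seq_len(n_variants)
  R <- rho^abs(outer(j, j, "-"))
  pos <- as.integer(start_pos + (j - 1L) * spacing)
  ld_matrix(R, paste0(id_prefix, sprintf("%05d", j)), chrom, pos)
}

#' Per-variant LD scores
#'
#' The LD score of variant j is the sum of squared correlations with
#' every variant in its block, including itself: `ell_j = sum_k r2_jk`.
#' These are the regressors used by LD-score regression.
#'
#' @param ld An [ld_matrix] or list of `ld_matrix` blocks (cross-block LD
#'   is taken as zero).
#'
#' @return Named numeric vector of LD scores (always >= 1).
#' @export
ld_scores <- function(ld) {
  if (inherits(ld, "ld_matrix")) ld <- list(ld)
  out <- lapply(ld, function(b) rowSums(b$R^2))
  unlist(out, use.names = TRUE)
}

# Cholesky factor with a ridge fallback: adds 1e-8 to the diagonal when
# the matrix is numerically semi-definite.
chol_ridge <- function(R, ridge = 1e-8) {
  U <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(U)) {
    U <- chol(R + diag(ridge, nrow(R)))
  }
  U
}

# Look up squared correlation between a lead and a set of variants that
# live in the same block; variants in different blocks have r2 = 0.
# `index` is the environment built by ld_index().
ld_index <- function(ld) {
  if (inherits(ld, "ld_matrix")) ld <- list(ld)
  block <- integer(0)
  within <- integer(0)
  ids <- character(0)
  for (b in seq_along(ld)) {
    v <- ld[[b]]$variant_id
    ids <- c(ids, v)
    block <- c(block, rep.int(b, length(v)))
    within <- c(within, seq_along(v))
  }
  list(blocks = ld, block = stats::setNames(block, ids),
       within = stats::setNames(within, ids))
}

ld_r2_with <- function(idx, lead_id, other_ids) {
  bl <- idx$block[[lead_id]]
  r2 <- numeric(length(other_ids))
  same <- !is.na(idx$block[other_ids]) & idx$block[other_ids] == bl
  if (any(same)) {
    Rb <- idx$blocks[[bl]]$R
    r2[same] <- Rb[idx$within[[lead_id]], idx$within[other_ids[same]]]^2
  }
  r2
}
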