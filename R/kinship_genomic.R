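#' Hardy-Weinberg equilibrium chi-square P-value
#'
#' One-degree-of-freedom goodness-of-fit test of the genotype counts
#' against the Hardy-Weinberg expectation at the sample allele frequency,
#' without continuity correction. A monomorphic sample carries no evidence
#' against equilibrium and returns 1.
#'
#' @param n0,n1,n2 counts of the three genotype classes (0, 1 and 2 copies
#'   of the second allele).
#' @return P-value in \[0, 1\].
#' @export
hwe_pvalue <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  if (n < 1) stop("at least one genotype required")
  p <- (n1 + 2 * n2) / (2 * n)
  if (p <= 0 || p >= 1) return(1)
  expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  chisq <- sum((c(n0, n1, n2) - expd)^2 / expd)
  stats::pchisq(chisq, df = 1, lower.tail = FALSE)
}

#' Genotype quality control
#'
#' Removes SNPs with call rate below `call_rate_min`, minor allele frequency
#' below `maf_min`, or Hardy-Weinberg P-value below `hwe_p_min` (all strict
#' inequalities, so boundary values are retained). Filters are applied in
#' the order call rate, MAF, HWE, and each removed SNP is attributed to the
#' first filter it fails. Missing calls of retained SNPs are imputed to the
#' SNP mean rounded to the nearest integer code.
#'
#' @param g a [genotype_set]; may contain missing calls.
#' @param cfg a [run_config] supplying the thresholds.
#' @return List with `genotypes` (post-QC [genotype_set], no missing calls)
#'   and `report` (a `qc_report`: per-filter counts and SNP id lists).
#' @export
qc_filter <- function(g, cfg = run_config()) {
  calls <- g$calls
  n <- nrow(calls)
  call_rate <- colMeans(!is.na(calls))
  p <- colMeans(calls, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  hwe <- vapply(seq_len(ncol(calls)), function(j) {
    x <- calls[, j]
    hwe_pvalue(sum(x == 0, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
               sum(x == 2, na.rm = TRUE))
  }, numeric(1))

  fail_cr <- call_rate < cfg$call_rate_min
  fail_maf <- !fail_cr & maf < cfg$maf_min
  fail_hwe <- !fail_cr & !fail_maf & hwe < cfg$hwe_p_min
  keep <- !(fail_cr | fail_maf | fail_hwe)
  if (!any(keep)) stop("no SNPs retained after quality control")

  kept <- calls[, keep, drop = FALSE]
  # mean-impute then round; the study panel was fully imputed upstream, so
  # this path mostly serves synthetic or degenerate inputs
  if (anyNA(kept)) {
    for (j in which(colSums(is.na(kept)) > 0L)) {
      miss <- is.na(kept[, j])
      kept[miss, j] <- round(mean(kept[, j], na.rm = TRUE))
    }
  }
  ids <- g$map$snp_id
  report <- structure(list(
    n_input = ncol(calls),
    n_removed_callrate = sum(fail_cr),
    n_removed_maf = sum(fail_maf),
    n_removed_hwe = sum(fail_hwe),
    n_retained = sum(keep),
    removed_callrate = ids[fail_cr],
    removed_maf = ids[fail_maf],
    removed_hwe = ids[fail_hwe]
  ), class = "qc_report")
  list(genotypes = genotype_set(kept, g$map[keep, , drop = FALSE]),
       report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Genotype QC:", x$n_input, "SNPs in;",
      x$n_removed_callrate, "failed call rate,",
      x$n_removed_maf, "failed MAF,",
      x$n_removed_hwe, "failed HWE;",
      x$n_retained, "retained\n")
  invisible(x)
}

#' Allele frequencies of the current population
#'
#' Frequency of the second (counted) allele per SNP: mean additive code
#' over non-missing animals divided by 2.
#'
#' @param g a [genotype_set].
#' @return Named numeric vector of frequencies.
#' @export
allele_freq <- function(g) {
  p <- colMeans(g$calls, na.rm = TRUE) / 2
  names(p) <- g$map$snp_id
  p
}

#' Normalisation constant lambda
#'
#' `lambda = 1 / sum(2 p_i (1 - p_i))`, the ratio of the per-SNP to the
#' total additive variance under the unweighted model; used to put the
#' genomic relationship matrix on the pedigree scale.
#'
#' @param p allele frequencies, strictly inside (0, 1).
#' @return The scalar lambda.
#' @export
lambda_norm <- function(p) {
  if (!length(p)) stop("empty frequency vector")
  if (any(p <= 0 | p >= 1)) stop("allele frequencies must be in (0, 1)")
  1 / sum(2 * p * (1 - p))
}

#' Centered genotype matrix Z
#'
#' Subtracts `2 p_i` from each column of the additive code matrix, so
#' columns have mean zero at the supplied frequencies.
#'
#' @param g a post-QC [genotype_set].
#' @param p allele frequencies (defaults to the observed ones).
#' @return Numeric matrix of the same shape as `g$calls`.
#' @export
z_matrix <- function(g, p = allele_freq(g)) {
  sweep(g$calls, 2L, 2 * p, `-`)
}

#' Weighted genomic relationship matrix
#'
#' `G = Z diag(d) Z' * lambda` with Z the frequency-centered genotypes and
#' `lambda = 1 / sum(2 p (1 - p))`. With unit weights this is the standard
#' first-method genomic relationship matrix; SNP weights d re-emphasise
#' markers between re-weighting iterations.
#'
#' @param g a post-QC [genotype_set] (no missing calls).
#' @param p allele frequencies.
#' @param weights per-SNP non-negative weights (default all 1).
#' @return Symmetric matrix with animal ids as dimnames.
#' @export
g_matrix <- function(g, p = allele_freq(g), weights = NULL) {
  m <- ncol(g$calls)
  if (is.null(weights)) weights <- rep(1, m)
  if (length(weights) != m) stop("weights length must equal SNP count")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (length(p) != m) stop("frequency vector length must equal SNP count")
  Z <- z_matrix(g, p)
  Zw <- sweep(Z, 2L, sqrt(weights), `*`)
  tcrossprod(Zw) * lambda_norm(p)
}

#' Tune G for compatibility with A22 and blend
#'
#' Finds scalars (a, b) such that `a + b G` matches A22 in both its mean
#' diagonal and overall mean (two-moment compatibility tuning), then blends:
#' `G_w = (1 - tau) (a + b G) + tau A22`. The blend guarantees
#' invertibility when G is rank-deficient (more SNPs than animals is not
#' enough if animals are clones, and n > m always leaves G singular).
#'
#' @param G genomic relationship matrix.
#' @param A22 pedigree relationship block for the same animals, same order.
#' @param tau blend weight on A22 (default 0.05).
#' @return The tuned, blended matrix, with attribute `tuning` = c(a, b, tau).
#' @export
tune_and_blend <- function(G, A22, tau = 0.05) {
  stopifnot(all(dim(G) == dim(A22)))
  md_g <- mean(diag(G)); m_g <- mean(G)
  md_a <- mean(diag(A22)); m_a <- mean(A22)
  denom <- md_g - m_g
  if (!is.finite(denom) || abs(denom) < 1e-12) {
    stop("cannot tune: G has no diagonal/off-diagonal contrast")
  }
  b <- (md_a - m_a) / denom
  a <- m_a - b * m_g
  if (!is.finite(a) || !is.finite(b)) stop("non-finite tuning coefficients")
  Gw <- (1 - tau) * (a + b * G) + tau * A22
  dimnames(Gw) <- dimnames(A22)
  attr(Gw, "tuning") <- c(a = a, b = b, tau = tau)
  Gw
}

#' Assemble the inverse of the single-step H matrix
#'
#' `H^-1 = A^-1 + [0 0; 0 G_w^-1 - A22^-1]`: the pedigree inverse plus a
#' correction in the genotyped block only. Rows and columns of
#' non-genotyped animals are exactly those of A^-1.
#'
#' @param Ainv pedigree inverse for all animals (dimnames required).
#' @param A22inv inverse of the genotyped pedigree block.
#' @param Gw_inv inverse of the tuned, blended genomic matrix.
#' @param genotyped character ids of the genotyped animals, in the order of
#'   the genomic matrices.
#' @return Matrix of class `"h_inverse"` with attribute `genotyped`.
#' @export
h_inverse <- function(Ainv, A22inv, Gw_inv, genotyped) {
  H <- Ainv
  if (length(genotyped)) {
    stopifnot(length(genotyped) == nrow(Gw_inv),
              all(dim(A22inv) == dim(Gw_inv)))
    missing_ids <- setdiff(genotyped, rownames(Ainv))
    if (length(missing_ids)) {
      stop("genotyped ids absent from pedigree: ",
           paste(utils::head(missing_ids, 5), collapse = ", "))
    }
    H[genotyped, genotyped] <- H[genotyped, genotyped] + (Gw_inv - A22inv)
  }
  attr(H, "genotyped") <- genotyped
  class(H) <- c("h_inverse", class(H))
  H
}

#' Invert the blended genomic matrix
#'
#' Thin wrapper around a dense solve that turns numerical singularity into
#' an actionable error.
#'
#' @param Gw blended matrix from [tune_and_blend()].
#' @return Its inverse.
#' @export
invert_gw <- function(Gw) {
  tryCatch(solve(Gw),
           error = function(e) {
             stop("blended genomic matrix is singular; increase the blend ",
                  "weight tau (", conditionMessage(e), ")")
           })
}
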