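#' Back-solve SNP effects from genomic breeding values
#'
#' Allele-substitution effects from the equivalence of the SNP and animal
#' models: `u = D Z' (Z D Z')^-1 a_g`, with Z the frequency-centered
#' genotypes and D the diagonal SNP weights. This equals
#' `lambda D Z' G*^-1 a_g` because `G* = Z D Z' lambda` and lambda cancels;
#' the solve is done against the raw `Z D Z'` system. When that system is
#' singular (always the case when centering at the observed frequencies,
#' which nulls the ones vector) the solve falls back to
#' `lambda D Z' Gw^-1 a_g` against the blended matrix if one is supplied,
#' or to the minimum-norm least-squares solution otherwise; both paths
#' warn.
#'
#' @param a_hat_g breeding values of the genotyped animals, aligned with the
#'   genotype matrix row order.
#' @param g post-QC [genotype_set].
#' @param p allele frequencies.
#' @param weights per-SNP weights d (default all 1).
#' @param Gw optional blended genomic matrix for the singular fallback.
#' @return Named vector of per-SNP effects (trait units per allele copy).
#' @export
backsolve_snp_effects <- function(a_hat_g, g, p = allele_freq(g),
                                  weights = NULL, Gw = NULL) {
  m <- ncol(g$calls)
  if (is.null(weights)) weights <- rep(1, m)
  stopifnot(length(a_hat_g) == nrow(g$calls), length(weights) == m)
  Z <- z_matrix(g, p)
  Zw <- sweep(Z, 2L, sqrt(weights), `*`)
  S <- tcrossprod(Zw)
  # S is PSD; Cholesky both detects rank deficiency (centering at the
  # observed frequencies puts the ones vector in the null space of S, so
  # this is the common path in a full pipeline run) and solves when PD.
  R <- tryCatch(chol(S), error = function(e) NULL)
  v <- if (!is.null(R) && min(diag(R)) > 1e-7 * max(diag(R))) {
    backsolve(R, forwardsolve(t(R), a_hat_g))
  } else {
    NULL
  }
  if (is.null(v)) {
    if (!is.null(Gw)) {
      warning("Z D Z' singular; back-solving against the blended matrix")
      v <- solve(Gw, a_hat_g) * lambda_norm(p)
    } else {
      warning("Z D Z' singular; using the minimum-norm least-squares solve")
      sv <- svd(S)
      pos <- sv$d > max(dim(S)) * max(sv$d, 0) * .Machine$double.eps
      v <- sv$v[, pos, drop = FALSE] %*%
        (crossprod(sv$u[, pos, drop = FALSE], a_hat_g) / sv$d[pos])
    }
  }
  u <- weights * drop(crossprod(Z, v))
  stats::setNames(u, g$map$snp_id)
}

#' Per-SNP variance shares and next-iteration weights
#'
#' Each SNP's contribution to the additive variance is
#' `u_i^2 * 2 p_i (1 - p_i)`. Next-iteration weights are the shares
#' rescaled to a constant trace, `sum(d) = M`, so the overall variance
#' scale does not drift between re-weighting iterations. If every effect is
#' zero the weights fall back to 1.
#'
#' @param u_hat per-SNP effects.
#' @param p allele frequencies.
#' @return List with `var_share` and `weight_next`, both length M.
#' @export
snp_variance_shares <- function(u_hat, p) {
  stopifnot(length(u_hat) == length(p))
  var_share <- u_hat^2 * 2 * p * (1 - p)
  total <- sum(var_share)
  weight_next <- if (total > 0) {
    var_share * length(u_hat) / total
  } else {
    rep(1, length(u_hat))
  }
  list(var_share = var_share, weight_next = weight_next)
}

#' Per-SNP significance tests
#'
#' Two modes. `"as-printed"` follows the published per-SNP statistic
#' `t_i = u_i / sqrt(var_share_i / n_i)` referred to a t distribution with
#' `n_i - 1` degrees of freedom, where `n_i` is the number of animals with a
#' genotype at SNP i. Because `var_share_i` is built from `u_i` itself,
#' `|t_i|` is constant in `u_i` and the statistic is degenerate as a test;
#' it is kept as the default for fidelity. `"empirical"` scales each effect
#' by the genome-wide standard deviation of effects, `t_i = u_i /
#' sd(u)`, a calibrated large-sample alternative.
#'
#' @param u_hat per-SNP effects.
#' @param var_share per-SNP variance shares from [snp_variance_shares()].
#' @param n_per_snp animals with a genotype at each SNP (scalar or vector).
#' @param mode `"as-printed"` or `"empirical"`.
#' @return Data frame with `t_stat`, `p_value`, `minus_log10_p`.
#' @export
snp_pvalues <- function(u_hat, var_share, n_per_snp,
                        mode = c("as-printed", "empirical")) {
  mode <- match.arg(mode)
  m <- length(u_hat)
  n_per_snp <- rep_len(n_per_snp, m)
  if (any(n_per_snp < 2)) stop("need at least 2 animals per SNP")
  if (mode == "as-printed") {
    se <- sqrt(var_share / n_per_snp)
    t_stat <- ifelse(u_hat == 0, 0, u_hat / se)
    bad <- var_share == 0 & u_hat != 0
    if (any(bad)) {
      warning(sum(bad), " SNP(s) with zero variance share but nonzero ",
              "effect; P set to NaN")
      t_stat[bad] <- NaN
    }
  } else {
    s <- stats::sd(u_hat)
    t_stat <- if (s > 0) u_hat / s else rep(0, m)
  }
  p_value <- 2 * stats::pt(abs(t_stat), df = n_per_snp - 1,
                           lower.tail = FALSE)
  data.frame(t_stat = t_stat, p_value = p_value,
             minus_log10_p = -log10(p_value))
}

#' Iteratively re-weighted single-step SNP effects
#'
#' Iteration 0 back-solves effects with unit weights (D = I). Each further
#' iteration rebuilds the weighted genomic matrix from the previous
#' variance shares, reassembles H^-1, re-solves the mixed-model equations
#' for breeding values at fixed variance components, and back-solves again.
#' The default single iteration emphasises large-effect regions without the
#' variance-scale collapse of long weighting chains.
#'
#' @param d design list from [build_design()].
#' @param g post-QC [genotype_set].
#' @param Ainv,A22,A22inv pedigree matrices from the kinship stage.
#' @param vc fixed variance components used in every solve.
#' @param n_iter number of re-weighting iterations (0 = unweighted).
#' @param tau blend weight for [tune_and_blend()].
#' @return List with `u_hat`, `var_share`, `weight_next`, `weights` (the
#'   weights actually used in the final solve), `fit` (final `model_fit`),
#'   `a_hat_g`, and `p` (allele frequencies).
#' @export
iterate_weights <- function(d, g, Ainv, A22, A22inv, vc, n_iter = 1L,
                            tau = 0.05) {
  if (n_iter < 0) stop("n_iter must be >= 0")
  p <- allele_freq(g)
  ids <- genotyped_ids(g)
  weights <- rep(1, ncol(g$calls))
  u_hat <- NULL
  for (iter in 0:n_iter) {
    G <- g_matrix(g, p, weights)
    Gw <- tune_and_blend(G, A22, tau)
    Hinv <- h_inverse(Ainv, A22inv, invert_gw(Gw), ids)
    fit <- solve_mme(d, Hinv, vc)
    a_hat_g <- fit$a_hat[ids]
    u_hat <- backsolve_snp_effects(a_hat_g, g, p, weights, Gw = Gw)
    shares <- snp_variance_shares(u_hat, p)
    used <- weights
    weights <- shares$weight_next
  }
  list(u_hat = u_hat, var_share = shares$var_share,
       weight_next = shares$weight_next, weights = used, fit = fit,
       a_hat_g = a_hat_g, p = p)
}
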