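#' Run configuration for the single-step GWAS pipeline
#'
#' Bundles the tunable parameters of every stage with the study defaults:
#' genotype QC thresholds (call rate 0.90, MAF 0.05, HWE P 1e-6, all
#' strict-inequality exclusions), the G/A22 blend weight tau, the 5-SNP
#' sliding window and its 0.5% variance-explained selection threshold, the
#' Gibbs sampler schedule (100,000 rounds, 9,000 burn-in at study scale),
#' one re-weighting iteration, and the Bonferroni alpha of 0.01.
#'
#' @param call_rate_min minimum genotype call rate; SNPs strictly below are
#'   removed.
#' @param maf_min minimum minor allele frequency (strict).
#' @param hwe_p_min minimum Hardy-Weinberg chi-square P-value (strict).
#' @param tau blend weight of A22 into the tuned G (`G_w = (1 - tau) G_t +
#'   tau A22`).
#' @param window_size number of adjacent SNPs per window.
#' @param window_step slide step in SNPs (1 = moving windows; `window_size`
#'   = disjoint blocks).
#' @param ve_threshold informative-window threshold, percent of genetic
#'   variance (inclusive: windows at exactly the threshold are kept).
#' @param chain_length,burn_in,thin Gibbs sampler schedule.
#' @param seed integer seed for the Gibbs sampler.
#' @param reweight_iters number of re-weighting iterations after the
#'   unweighted (D = I) pass.
#' @param pvalue_mode `"as-printed"` for the per-SNP t-test built from the
#'   SNP's own variance share, `"empirical"` for a genome-wide
#'   standard-deviation scaling (see [snp_pvalues()]).
#' @param bonferroni_alpha genome-wide significance level before dividing by
#'   the SNP count.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(call_rate_min = 0.90,
                       maf_min = 0.05,
                       hwe_p_min = 1e-6,
                       tau = 0.05,
                       window_size = 5L,
                       window_step = 1L,
                       ve_threshold = 0.5,
                       chain_length = 100000L,
                       burn_in = 9000L,
                       thin = 10L,
                       seed = 1L,
                       reweight_iters = 1L,
                       pvalue_mode = c("as-printed", "empirical"),
                       bonferroni_alpha = 0.01) {
  pvalue_mode <- match.arg(pvalue_mode)
  stopifnot(call_rate_min >= 0, call_rate_min <= 1,
            maf_min >= 0, maf_min <= 0.5,
            hwe_p_min >= 0, hwe_p_min <= 1,
            tau >= 0, tau <= 1,
            window_size >= 1, window_step >= 1,
            ve_threshold >= 0,
            chain_length >= 1, thin >= 1,
            reweight_iters >= 0,
            bonferroni_alpha > 0, bonferroni_alpha < 1)
  if (burn_in >= chain_length) stop("burn_in must be < chain_length")
  structure(list(call_rate_min = call_rate_min, maf_min = maf_min,
                 hwe_p_min = hwe_p_min, tau = tau,
                 window_size = as.integer(window_size),
                 window_step = as.integer(window_step),
                 ve_threshold = ve_threshold,
                 chain_length = as.integer(chain_length),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed),
                 reweight_iters = as.integer(reweight_iters),
                 pvalue_mode = pvalue_mode,
                 bonferroni_alpha = bonferroni_alpha),
            class = "run_config")
}

#' Bonferroni genome-wide threshold on the -log10(P) scale
#'
#' The genome-wide significance level is `alpha / N` over the `N` SNPs
#' tested; returned as `-log10(alpha / N)` for plotting against
#' `-log10(P)` tracks.
#'
#' @param n_snps number of SNPs tested.
#' @param alpha family-wise error rate.
#' @return `-log10(alpha / n_snps)`.
#' @export
bonferroni_threshold <- function(n_snps, alpha = 0.01) {
  stopifnot(n_snps >= 1, alpha > 0, alpha < 1)
  -log10(alpha / n_snps)
}
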