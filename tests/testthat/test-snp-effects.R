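test_that("back-solved effects reconstruct the breeding values", {
  # fewer animals than SNPs and p away from the observed mean keeps ZDZ'
  # nonsingular, so the identity Z u = a_g holds exactly
  set.seed(1)
  calls <- random_calls(20, runif(50, 0.2, 0.8), seed = 1)
  g <- make_gs(calls)
  p <- runif(50, 0.3, 0.7)
  a_g <- rnorm(20)
  for (w in list(NULL, runif(50, 0.1, 2))) {
    u <- backsolve_snp_effects(a_g, g, p, weights = w)
    Z <- z_matrix(g, p)
    expect_equal(drop(Z %*% u), a_g, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("back-solving matches the dense pseudo-inverse oracle", {
  set.seed(2)
  calls <- random_calls(20, runif(50, 0.2, 0.8), seed = 2)
  g <- make_gs(calls)
  p <- runif(50, 0.3, 0.7)
  d <- runif(50, 0.5, 1.5)
  a_g <- rnorm(20)
  Z <- z_matrix(g, p)
  oracle <- diag(d) %*% t(Z) %*% solve(Z %*% diag(d) %*% t(Z)) %*% a_g
  u <- backsolve_snp_effects(a_g, g, p, weights = d)
  expect_equal(unname(u), drop(oracle), tolerance = 1e-8)
})

test_that("single-SNP back-solve reduces to the scalar projection", {
  calls <- matrix(c(0, 1, 2, 2, 0), 5, 1)
  g <- make_gs(calls)
  p <- 0.4
  a_g <- c(0.3, -0.1, 0.5, 0.2, -0.4)
  z <- drop(z_matrix(g, p))
  # one SNP over five animals: rank-1 system, minimum-norm solve applies
  expect_warning(u <- backsolve_snp_effects(a_g, g, p), "minimum-norm")
  expect_equal(unname(u), sum(z * a_g) / sum(z^2), tolerance = 1e-12)
})

test_that("singular centered system falls back to the blended matrix", {
  set.seed(3)
  calls <- random_calls(40, runif(20, 0.2, 0.8), seed = 3)
  g <- make_gs(calls)  # n > m: ZDZ' rank-deficient
  p <- allele_freq(g)  # exact centering also nulls the ones vector
  a_g <- rnorm(40)
  A22 <- diag(40) + 0.02
  Gw <- tune_and_blend(g_matrix(g, p), A22, tau = 0.05)
  expect_warning(u <- backsolve_snp_effects(a_g, g, p, Gw = Gw), "singular")
  expect_equal(unname(u),
               unname(drop(t(z_matrix(g, p)) %*% solve(Gw, a_g))) *
                 lambda_norm(p),
               tolerance = 1e-10)
})

test_that("allele flips negate effects and preserve variance shares", {
  set.seed(4)
  calls <- random_calls(15, runif(30, 0.2, 0.8), seed = 4)
  g <- make_gs(calls)
  p <- runif(30, 0.3, 0.7)
  a_g <- rnorm(15)
  u1 <- backsolve_snp_effects(a_g, g, p)
  flip <- 7
  calls2 <- calls; calls2[, flip] <- 2 - calls2[, flip]
  p2 <- p; p2[flip] <- 1 - p2[flip]
  u2 <- backsolve_snp_effects(a_g, make_gs(calls2), p2)
  expect_equal(unname(u2[flip]), -unname(u1[flip]), tolerance = 1e-8)
  expect_equal(unname(u2[-flip]), unname(u1[-flip]), tolerance = 1e-8)
  s1 <- snp_variance_shares(u1, p)
  s2 <- snp_variance_shares(u2, p2)
  expect_equal(s1$var_share, s2$var_share, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("variance shares and next weights follow the published plug-in", {
  p <- c(0.5, 0.2, 0.4)
  u <- c(1, 0, -2)
  s <- snp_variance_shares(u, p)
  expect_equal(s$var_share[1], 0.5)  # u = 1, p = 0.5
  expect_equal(s$var_share[2], 0)
  expect_equal(s$var_share[3], 4 * 2 * 0.4 * 0.6)
  expect_equal(sum(s$weight_next), 3)  # constant trace
  # all-zero effects: unit weights, not NaN
  s0 <- snp_variance_shares(c(0, 0), c(0.3, 0.4))
  expect_equal(s0$weight_next, c(1, 1))
})

test_that("per-SNP t-test honours symmetry and the t-distribution oracle", {
  p <- rep(0.5, 4)
  u <- c(0, 1, -1, 2)
  vs <- snp_variance_shares(u, p)$var_share
  out <- snp_pvalues(u, vs, n_per_snp = 10)
  expect_equal(out$t_stat[1], 0)
  expect_equal(out$p_value[1], 1)
  expect_equal(out$p_value[2], out$p_value[3])  # P(u) = P(-u)
  # hand-sized oracle: |t| = 2.262 at 9 df is the two-sided 5% point
  expect_equal(2 * pt(2.262, df = 9, lower.tail = FALSE), 0.05,
               tolerance = 1e-3)
  # as-printed statistic: t = u / sqrt(u^2 2p(1-p) / n) = sqrt(n / (2p(1-p)))
  expect_equal(abs(out$t_stat[2]), sqrt(10 / 0.5), tolerance = 1e-12)
  expect_equal(abs(out$t_stat[4]), abs(out$t_stat[2]), tolerance = 1e-12)
})

test_that("empirical mode is calibrated on a pure-noise simulation", {
  cfg <- sim_config(seed = 41, n_founder_dams = 80, n_cows = 300,
                    n_ungenotyped = 0, n_snps = 2000, n_chromosomes = 2,
                    n_qtl = 0, qtl_variance_fractions = numeric(0),
                    h2_target = 0.3)
  dat <- simulate_dataset(cfg)
  rc <- run_config(reweight_iters = 0, pvalue_mode = "empirical", seed = 1)
  fit <- suppressWarnings(
    run_ssgwas(dat$pedigree, dat$genotypes, dat$phenotypes, cfg$trait_name,
               rc, vc = list(sigma2_a = dat$truth$sigma2_a,
                             sigma2_e = dat$truth$sigma2_e)))
  frac <- mean(fit$snp_table$p_value < 0.05)
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.10)
})

test_that("re-weighting with uniform weights is a fixed point", {
  set.seed(6)
  cfg <- sim_config(seed = 6, n_founder_dams = 20, n_cows = 60,
                    n_ungenotyped = 0, n_snps = 150, n_chromosomes = 1,
                    h2_target = 0.3)
  dat <- simulate_dataset(cfg)
  qc <- qc_filter(dat$genotypes, run_config())
  g <- qc$genotypes
  ids <- genotyped_ids(g)
  d <- build_design(dat$phenotypes, dat$pedigree, cfg$trait_name)
  A <- a_matrix(dat$pedigree)
  Ainv <- a_inverse(dat$pedigree)
  A22 <- subset_a22(A, ids)
  vc <- list(sigma2_a = dat$truth$sigma2_a, sigma2_e = dat$truth$sigma2_e)
  r0 <- suppressWarnings(
    iterate_weights(d, g, Ainv, A22, solve(A22), vc, n_iter = 0))
  expect_equal(unname(r0$weights), rep(1, ncol(g$calls)))
  expect_error(iterate_weights(d, g, Ainv, A22, solve(A22), vc, -1), ">= 0")
  # D proportional to I is a fixed point of the back-solve identity
  set.seed(7)
  calls <- random_calls(20, runif(50, 0.2, 0.8), seed = 7)
  gs <- make_gs(calls)
  p <- runif(50, 0.3, 0.7)
  a_g <- rnorm(20)
  expect_equal(backsolve_snp_effects(a_g, gs, p, weights = rep(3.7, 50)),
               backsolve_snp_effects(a_g, gs, p), tolerance = 1e-8)
})

test_that("Bonferroni thresholds come from the alpha/N formula", {
  expect_equal(bonferroni_threshold(100, 0.01), 4)
  expect_equal(bonferroni_threshold(1, 0.05), -log10(0.05))
  expect_equal(bonferroni_threshold(586304, 0.01),
               -log10(0.01 / 586304))
  expect_equal(round(bonferroni_threshold(586304, 0.01), 2), 7.77)
})
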