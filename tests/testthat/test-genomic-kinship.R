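test_that("HWE chi-square P-value behaves at the landmark counts", {
  expect_equal(hwe_pvalue(25, 50, 25), 1)  # perfect HWE, chi-square 0
  # complete heterozygote deficit at p = 0.5: chi-square = n = 100
  expect_equal(hwe_pvalue(50, 0, 50),
               pchisq(100, df = 1, lower.tail = FALSE))
  expect_lt(hwe_pvalue(50, 0, 50), 1e-6)
  expect_equal(hwe_pvalue(0, 0, 60), 1)  # monomorphic
  expect_equal(hwe_pvalue(60, 0, 0), 1)
  expect_error(hwe_pvalue(0, 0, 0), "at least one")
})

test_that("QC removes planted failures with first-filter attribution", {
  set.seed(99)
  n <- 200
  p <- runif(100, 0.2, 0.5)
  calls <- random_calls(n, p, seed = 99)
  # plant disjoint failures: 7 call-rate, 11 MAF, 3 HWE
  cr_idx <- 1:7; maf_idx <- 8:18; hwe_idx <- 19:21
  for (j in cr_idx) calls[sample(n, 25), j] <- NA      # 87.5% call rate
  for (j in maf_idx) calls[, j] <- rbinom(n, 2, 0.01)  # MAF ~ 0.01
  calls[, maf_idx[1]] <- 0                             # monomorphic
  for (j in hwe_idx) calls[, j] <- 2 * rbinom(n, 1, 0.5)  # no hets
  g <- make_gs(calls)
  res <- qc_filter(g, run_config())
  rep <- res$report
  expect_equal(rep$n_removed_callrate, 7)
  expect_equal(rep$n_removed_maf, 11)
  expect_equal(rep$n_removed_hwe, 3)
  expect_equal(rep$n_retained, 79)
  expect_equal(rep$n_input,
               rep$n_retained + rep$n_removed_callrate +
                 rep$n_removed_maf + rep$n_removed_hwe)
  expect_false(anyNA(res$genotypes$calls))
  # a SNP failing both call rate and MAF is attributed to call rate
  calls2 <- calls
  calls2[, maf_idx[2]][sample(n, 30)] <- NA
  rep2 <- qc_filter(make_gs(calls2), run_config())$report
  expect_equal(rep2$n_removed_callrate, 8)
  expect_equal(rep2$n_removed_maf, 10)
})

test_that("QC attribution is invariant to SNP input order", {
  set.seed(5)
  calls <- random_calls(100, runif(50, 0.05, 0.5), seed = 5)
  calls[, 1:4] <- rbinom(100 * 4, 2, 0.01)
  for (j in 5:6) calls[sample(100, 15), j] <- NA
  g <- make_gs(calls)
  rep1 <- qc_filter(g, run_config())$report
  perm <- sample(ncol(calls))
  g2 <- genotype_set(calls[, perm], g$map[perm, ])
  rep2 <- qc_filter(g2, run_config())$report
  for (fld in c("n_removed_callrate", "n_removed_maf", "n_removed_hwe",
                "n_retained")) {
    expect_equal(rep1[[fld]], rep2[[fld]])
  }
  expect_setequal(rep1$removed_maf, rep2$removed_maf)
})

test_that("boundary SNPs at the exact thresholds are retained", {
  # call rate exactly 0.90 (18/20), MAF exactly 0.05 on 20 animals
  calls <- cbind(c(rep(NA, 2), rep(1, 18)),           # call rate = 0.90
                 c(rep(0, 18), 1, 1))                 # p = 2/40 = 0.05
  calls <- cbind(calls, random_calls(20, rep(0.4, 3), seed = 2))
  rep <- qc_filter(make_gs(calls), run_config())$report
  expect_equal(rep$n_removed_callrate, 0)  # 0.90 is not < 0.90
  expect_false("s002" %in% rep$removed_maf)  # 0.05 is not < 0.05
  expect_equal(rep$n_retained, 5)
})

test_that("allele frequencies match the allele-counting oracle", {
  expect_equal(unname(allele_freq(make_gs(matrix(c(0, 1, 2), 3, 1)))), 0.5)
  set.seed(3)
  calls <- random_calls(200, runif(20, 0.1, 0.9), seed = 3)
  g <- make_gs(calls)
  oracle <- apply(calls, 2, function(x) sum(x) / (2 * length(x)))
  expect_equal(unname(allele_freq(g)), oracle)
})

test_that("lambda is the reciprocal sum of 2p(1-p)", {
  expect_equal(lambda_norm(0.5), 2)
  expect_equal(lambda_norm(rep(0.5, 10)), 2 / 10)
  set.seed(8)
  p <- runif(200, 0.05, 0.95)
  acc <- 0
  for (pi in p) acc <- acc + 2 * pi * (1 - pi)  # term-by-term oracle
  expect_equal(lambda_norm(p), 1 / acc)
  expect_error(lambda_norm(numeric(0)), "empty")
  expect_error(lambda_norm(c(0.2, 1)), "in \\(0, 1\\)")
})

test_that("G matches hand arithmetic and Monte-Carlo expectation", {
  # one SNP, p = 0.5, animals coded 0/1/2: Z = (-1, 0, 1), lambda = 2
  g1 <- make_gs(matrix(c(0, 1, 2), 3, 1))
  G1 <- g_matrix(g1, p = 0.5)
  expect_equal(diag(G1), c(2, 0, 2), ignore_attr = TRUE)
  expect_equal(G1[1, 3], -2)
  # zero weight on all but one SNP gives rank <= 1
  set.seed(4)
  calls <- random_calls(10, runif(8, 0.2, 0.8), seed = 4)
  g <- make_gs(calls)
  Gr <- g_matrix(g, weights = c(1, rep(0, 7)))
  expect_lte(qr(Gr)$rank, 1)
  # large HWE panel: mean diagonal close to 1
  p <- runif(1000, 0.1, 0.9)
  gbig <- make_gs(random_calls(200, p, seed = 10))
  Gd <- g_matrix(gbig, p = p)
  expect_lt(abs(mean(diag(Gd)) - 1), 0.05)
})

test_that("G is invariant to allele-coding flips when weights are unit", {
  set.seed(12)
  calls <- random_calls(30, runif(40, 0.2, 0.8), seed = 12)
  g <- make_gs(calls)
  G <- g_matrix(g)
  flip <- sample(40, 10)
  calls2 <- calls
  calls2[, flip] <- 2 - calls2[, flip]
  G2 <- g_matrix(make_gs(calls2))
  expect_equal(G, G2, tolerance = 1e-10)
})

test_that("tuning matches A22 moments; blending endpoints behave", {
  set.seed(21)
  ped <- random_pedigree(40, seed = 21)
  A <- a_matrix(ped)
  ids <- ped$animal[21:40]
  A22 <- subset_a22(A, ids)
  calls <- random_calls(20, runif(60, 0.2, 0.8), seed = 22)
  rownames(calls) <- ids
  G <- g_matrix(make_gs(calls))
  # oracle: solve the 2x2 moment system directly
  M <- rbind(c(1, mean(diag(G))), c(1, mean(G)))
  ab <- solve(M, c(mean(diag(A22)), mean(A22)))
  Gt <- tune_and_blend(G, A22, tau = 0)
  expect_equal(unname(attr(Gt, "tuning")[c("a", "b")]), unname(ab),
               tolerance = 1e-10)
  expect_equal(mean(diag(Gt)), mean(diag(A22)), tolerance = 1e-10)
  expect_equal(mean(Gt), mean(A22), tolerance = 1e-10)
  # fixed point and tau = 1 endpoint
  expect_equal(tune_and_blend(A22, A22, tau = 0), A22, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(tune_and_blend(G, A22, tau = 1), A22, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_error(tune_and_blend(matrix(1, 4, 4), diag(4)), "tune")
})

test_that("H inverse reduces to A inverse and matches the dense-H oracle", {
  ped <- random_pedigree(30, seed = 31)
  Ainv <- a_inverse(ped)
  # no genotyped animals: identical to A inverse
  H0 <- h_inverse(Ainv, matrix(0, 0, 0), matrix(0, 0, 0), character(0))
  expect_equal(unclass(H0), Ainv, ignore_attr = TRUE, tolerance = 1e-10)
  # Gw = A22: zero correction
  A <- a_matrix(ped)
  ids <- ped$animal[21:30]
  A22 <- subset_a22(A, ids)
  H1 <- h_inverse(Ainv, solve(A22), solve(A22), ids)
  expect_equal(unclass(H1), Ainv, ignore_attr = TRUE, tolerance = 1e-10)
  # dense oracle: build H explicitly from the joint-distribution formula
  set.seed(32)
  pfix <- runif(50, 0.2, 0.8)
  calls <- random_calls(10, pfix, seed = 32)
  rownames(calls) <- ids
  Gw <- tune_and_blend(g_matrix(make_gs(calls), p = pfix), A22, tau = 0.05)
  other <- setdiff(ped$animal, ids)
  A11 <- A[other, other]; A12 <- A[other, ids]; A21 <- t(A12)
  B <- solve(A22, A21)      # A22^-1 A21
  Dlt <- Gw - A22
  H <- A
  H[other, other] <- A11 + t(B) %*% Dlt %*% B
  H[other, ids] <- A12 + t(B) %*% Dlt
  H[ids, other] <- t(H[other, ids])
  H[ids, ids] <- Gw
  Hinv <- h_inverse(Ainv, solve(A22), solve(Gw), ids)
  expect_equal(unclass(Hinv), solve(H), ignore_attr = TRUE,
               tolerance = 1e-6)
  # symmetry and untouched non-genotyped block
  expect_equal(unclass(Hinv), t(unclass(Hinv)), ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_equal(unclass(Hinv)[other, other], Ainv[other, other])
})
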