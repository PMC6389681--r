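#' Simulation configuration
#'
#' Defaults emulate the study design the pipeline targets: 614 phenotyped
#' cows descended from 19 sire families across 19 farms, 598 of them
#' genotyped; trait on the alpha-s1-casein scale (mean 35.45, SD 17.46
#' wt/wt%); a polygenic background plus one major QTL region absorbing 25%
#' of the additive variance (a DGAT1-like architecture); heritability 0.3.
#' Marker density is desk-scale: 2,000 biallelic SNPs on 5 chromosomes with
#' founder frequencies uniform on (0.05, 0.5).
#'
#' @param seed integer seed (mandatory; every operation is deterministic
#'   given it).
#' @param n_sires founder sires (sire families).
#' @param n_founder_dams founder dams.
#' @param n_generations generations bred below the founders; the last one
#'   is the phenotyped cow cohort.
#' @param n_cows cows in the final generation.
#' @param n_ungenotyped cows left out of the genotype panel (phenotyped
#'   only).
#' @param n_snps,n_chromosomes marker panel dimensions.
#' @param maf_low,maf_high founder allele frequency range.
#' @param n_qtl number of QTL drawn from the simulated SNPs.
#' @param qtl_variance_fractions per-QTL share of the additive variance
#'   (recycled to `n_qtl`; sum must be <= 1).
#' @param h2_target narrow-sense heritability target.
#' @param trait_name,trait_mean,trait_sd phenotype scale.
#' @param n_farms,n_lactations,n_parities fixed-effect level counts.
#' @param farm_sd,lactation_sd,parity_sd fixed-effect standard deviations
#'   as fractions of the phenotypic SD.
#' @param missing_rate fraction of genotype calls set missing.
#' @param n_monomorphic,n_low_callrate,n_hwe_fail planted QC-failing SNPs
#'   (disjoint sets; for QC tests).
#' @param hide_qtl if TRUE the QTL SNPs are masked from the analysis panel
#'   (hidden-QTL regime); default keeps them observed so back-solving can
#'   recover them.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(seed,
                       n_sires = 19L,
                       n_founder_dams = 150L,
                       n_generations = 2L,
                       n_cows = 614L,
                       n_ungenotyped = 16L,
                       n_snps = 2000L,
                       n_chromosomes = 5L,
                       maf_low = 0.05, maf_high = 0.5,
                       n_qtl = 1L,
                       qtl_variance_fractions = 0.25,
                       h2_target = 0.3,
                       trait_name = "alpha_s1_casein",
                       trait_mean = 35.45, trait_sd = 17.46,
                       n_farms = 19L, n_lactations = 3L, n_parities = 3L,
                       farm_sd = 0.3, lactation_sd = 0.2, parity_sd = 0.1,
                       missing_rate = 0,
                       n_monomorphic = 0L, n_low_callrate = 0L,
                       n_hwe_fail = 0L,
                       hide_qtl = FALSE) {
  if (missing(seed)) stop("seed is mandatory")
  qtl_variance_fractions <- rep_len(qtl_variance_fractions, n_qtl)
  stopifnot(h2_target >= 0, h2_target < 1,
            sum(qtl_variance_fractions) <= 1,
            maf_low > 0, maf_high <= 0.5, maf_low <= maf_high,
            n_generations >= 0, n_cows >= 1 || n_generations == 0,
            n_ungenotyped >= 0, n_ungenotyped < n_cows || n_generations == 0,
            missing_rate >= 0, missing_rate < 1)
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a sire-family pedigree
#'
#' Generation 0 holds the founder sires and dams. Each later generation is
#' bred by mating the founder sires (so the cohort is structured into sire
#' families, as in progeny-testing dairy designs) to dams sampled from the
#' previous generation's females; both parents of every non-founder are
#' recorded.
#'
#' @param cfg a [sim_config].
#' @return A [pedigree]; the final generation's ids carry prefix "C".
#' @export
simulate_pedigree <- function(cfg) {
  set.seed(cfg$seed)
  sires <- paste0("S", seq_len(cfg$n_sires))
  dams <- paste0("D0_", seq_len(cfg$n_founder_dams))
  animal <- c(sires, dams)
  sire <- rep(NA_character_, length(animal))
  dam <- rep(NA_character_, length(animal))
  prev_females <- dams
  if (cfg$n_generations >= 1L) {
    for (gen in seq_len(cfg$n_generations)) {
      last <- gen == cfg$n_generations
      size <- if (last) cfg$n_cows else cfg$n_founder_dams
      ids <- if (last) paste0("C", seq_len(size)) else {
        paste0("D", gen, "_", seq_len(size))
      }
      s <- sample(sires, size, replace = TRUE)
      d <- sample(prev_females, size, replace = TRUE)
      animal <- c(animal, ids)
      sire <- c(sire, s)
      dam <- c(dam, d)
      prev_females <- ids
    }
  }
  pedigree(animal, sire, dam)
}

#' Gene-drop genotypes down a pedigree
#'
#' Founder allele frequencies are drawn uniform on (`maf_low`, `maf_high`);
#' founder genotypes are Binomial(2, p) per locus, and every non-founder
#' receives one allele from each parent by Mendelian sampling
#' (Bernoulli(g_parent / 2) per locus), loci independent (no LD). Optional
#' missingness and planted QC-failing SNPs (monomorphic, low call rate,
#' extreme heterozygote-deficit) are injected afterwards into disjoint SNP
#' sets recorded in the `planted` attribute.
#'
#' @param ped pedigree from [simulate_pedigree()].
#' @param cfg a [sim_config].
#' @return A [genotype_set] for all pedigree animals, with attributes
#'   `founder_freq` and `planted`.
#' @export
simulate_genotypes <- function(ped, cfg) {
  set.seed(cfg$seed + 1L)
  m <- cfg$n_snps
  n <- nrow(ped)
  p0 <- stats::runif(m, cfg$maf_low, cfg$maf_high)
  idx <- seq_len(n)
  names(idx) <- ped$animal
  si <- unname(idx[ped$sire])
  di <- unname(idx[ped$dam])
  calls <- matrix(0, n, m, dimnames = list(ped$animal, NULL))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    from_sire <- if (is.na(s)) stats::rbinom(m, 1L, p0) else {
      stats::rbinom(m, 1L, calls[s, ] / 2)
    }
    from_dam <- if (is.na(d)) stats::rbinom(m, 1L, p0) else {
      stats::rbinom(m, 1L, calls[d, ] / 2)
    }
    calls[i, ] <- from_sire + from_dam
  }
  planted <- list(monomorphic = integer(0), low_callrate = integer(0),
                  hwe_fail = integer(0))
  n_plant <- cfg$n_monomorphic + cfg$n_low_callrate + cfg$n_hwe_fail
  if (n_plant > 0L) {
    chosen <- sample.int(m, n_plant)
    planted$monomorphic <- chosen[seq_len(cfg$n_monomorphic)]
    planted$low_callrate <- chosen[cfg$n_monomorphic + seq_len(cfg$n_low_callrate)]
    planted$hwe_fail <- chosen[cfg$n_monomorphic + cfg$n_low_callrate +
                                 seq_len(cfg$n_hwe_fail)]
    calls[, planted$monomorphic] <- 0
    for (j in planted$low_callrate) {
      calls[sample.int(n, ceiling(0.2 * n)), j] <- NA
    }
    for (j in planted$hwe_fail) {  # all homozygotes, no heterozygotes
      calls[, j] <- 2 * stats::rbinom(n, 1L, 0.5)
    }
  }
  if (cfg$missing_rate > 0) {
    drop_idx <- which(stats::runif(n * m) < cfg$missing_rate)
    calls[drop_idx] <- NA
  }
  # markers spread uniformly over n_chromosomes chromosomes of ~100 Mbp
  chrom <- sort(rep(seq_len(cfg$n_chromosomes), length.out = m))
  per_chr <- table(chrom)
  pos <- unlist(lapply(per_chr, function(k) sort(sample.int(1e8, k))),
                use.names = FALSE)
  map <- data.frame(snp_id = sprintf("SNP%05d", seq_len(m)),
                    chromosome = paste0("chr", chrom),
                    position_bp = pos)
  g <- genotype_set(calls, map)
  attr(g, "founder_freq") <- p0
  attr(g, "planted") <- lapply(planted, function(ix) map$snp_id[ix])
  g
}

#' Simulate phenotypes with a QTL-plus-polygenic architecture
#'
#' True breeding values are the sum of QTL contributions (effects sized so
#' each QTL explains its configured fraction of the additive variance) and
#' a polygenic remainder drawn from N(0, A sigma2_poly). Residuals are iid
#' normal, scaled so the realized heritability targets `h2_target`; farm,
#' lactation and parity effects are drawn from the configured normal SDs.
#' The whole phenotype is then shifted/scaled to `trait_mean`/`trait_sd`,
#' with all true components rescaled in lockstep.
#'
#' @param ped pedigree from [simulate_pedigree()].
#' @param g genotype set over all pedigree animals (pre-masking).
#' @param cfg a [sim_config].
#' @return List with `phenotypes` (one record per cow) and `truth` (true
#'   breeding values of the cows, QTL ids/effects, realized h2 and variance
#'   components on the final scale).
#' @export
simulate_phenotypes <- function(ped, g, cfg) {
  set.seed(cfg$seed + 2L)
  cows <- grep("^C", ped$animal, value = TRUE)
  if (!length(cows)) stop("pedigree has no cow generation")
  m <- ncol(g$calls)
  usable <- which(!(g$map$snp_id %in% unlist(attr(g, "planted"))))
  if (cfg$n_qtl > length(usable)) stop("QTL index outside SNP range")
  qtl_idx <- sort(sample(usable, cfg$n_qtl))
  calls_cows <- g$calls[cows, , drop = FALSE]
  sigma2_a_target <- 1
  frac <- cfg$qtl_variance_fractions
  a_qtl <- numeric(length(cows))
  qtl_eff <- numeric(cfg$n_qtl)
  if (cfg$n_qtl > 0L) {
    for (k in seq_len(cfg$n_qtl)) {
      gq <- calls_cows[, qtl_idx[k]]
      vq <- stats::var(gq)
      if (vq == 0) stop("QTL SNP is monomorphic among cows; reseed")
      qtl_eff[k] <- sqrt(frac[k] * sigma2_a_target / vq)
      a_qtl <- a_qtl + qtl_eff[k] * (gq - mean(gq))
    }
  }
  s2_poly <- (1 - sum(frac)) * sigma2_a_target
  A <- a_matrix(ped)
  u_all <- if (s2_poly > 0) {
    L <- chol(A + diag(1e-8, nrow(A)))
    drop(crossprod(L, stats::rnorm(nrow(A)))) * sqrt(s2_poly)
  } else {
    numeric(nrow(A))
  }
  names(u_all) <- ped$animal
  a <- a_qtl + u_all[cows]
  va <- stats::var(a)
  e <- if (cfg$h2_target > 0) {
    stats::rnorm(length(cows), 0, sqrt(va * (1 - cfg$h2_target) /
                                         cfg$h2_target))
  } else {
    a <- a * 0  # h2 = 0 edge: no additive signal at all
    stats::rnorm(length(cows), 0, 1)
  }
  farm <- sample(paste0("farm", seq_len(cfg$n_farms)), length(cows),
                 replace = TRUE)
  lact <- sample(paste0("lact", seq_len(cfg$n_lactations)), length(cows),
                 replace = TRUE)
  par_ <- sample(paste0("par", seq_len(cfg$n_parities)), length(cows),
                 replace = TRUE)
  sd_y0 <- stats::sd(a + e)
  farm_eff <- stats::rnorm(cfg$n_farms, 0, cfg$farm_sd * sd_y0)
  lact_eff <- stats::rnorm(cfg$n_lactations, 0, cfg$lactation_sd * sd_y0)
  par_eff <- stats::rnorm(cfg$n_parities, 0, cfg$parity_sd * sd_y0)
  fixed <- farm_eff[match(farm, paste0("farm", seq_len(cfg$n_farms)))] +
    lact_eff[match(lact, paste0("lact", seq_len(cfg$n_lactations)))] +
    par_eff[match(par_, paste0("par", seq_len(cfg$n_parities)))]
  y0 <- fixed + a + e
  scale_c <- if (stats::sd(y0) > 0) cfg$trait_sd / stats::sd(y0) else 1
  y <- cfg$trait_mean + (y0 - mean(y0)) * scale_c
  a_s <- a * scale_c
  e_s <- e * scale_c
  sigma2_a <- stats::var(a_s)
  sigma2_e <- stats::var(e_s)
  ph <- data.frame(animal = cows, trait = cfg$trait_name, value = y,
                   farm = farm, lactation = lact, parity = par_,
                   stringsAsFactors = FALSE)
  class(ph) <- c("phenotype_table", "data.frame")
  truth <- list(a_true = stats::setNames(a_s, cows),
                qtl_snp = g$map$snp_id[qtl_idx],
                qtl_index = qtl_idx,
                qtl_effect = qtl_eff * scale_c,
                sigma2_a = sigma2_a, sigma2_e = sigma2_e,
                realized_h2 = sigma2_a / (sigma2_a + sigma2_e))
  list(phenotypes = ph, truth = truth)
}

#' Simulate a complete analysis-ready dataset
#'
#' Runs [simulate_pedigree()], [simulate_genotypes()] and
#' [simulate_phenotypes()], then restricts the genotype panel to the
#' genotyped cows (all cows minus `n_ungenotyped` randomly chosen ones) and
#' optionally masks the QTL SNPs (`hide_qtl`).
#'
#' @param cfg a [sim_config].
#' @return List with `pedigree`, `genotypes` (analysis panel),
#'   `phenotypes`, `truth`, and `genotypes_full` (all animals, all SNPs).
#' @export
simulate_dataset <- function(cfg) {
  ped <- simulate_pedigree(cfg)
  g_full <- simulate_genotypes(ped, cfg)
  sim <- simulate_phenotypes(ped, g_full, cfg)
  cows <- sim$phenotypes$animal
  set.seed(cfg$seed + 3L)
  ungeno <- if (cfg$n_ungenotyped > 0) {
    sample(cows, cfg$n_ungenotyped)
  } else {
    character(0)
  }
  keep_animals <- setdiff(cows, ungeno)
  keep_snps <- if (isTRUE(cfg$hide_qtl)) {
    setdiff(seq_len(ncol(g_full$calls)), sim$truth$qtl_index)
  } else {
    seq_len(ncol(g_full$calls))
  }
  panel <- genotype_set(g_full$calls[keep_animals, keep_snps, drop = FALSE],
                        g_full$map[keep_snps, , drop = FALSE])
  attr(panel, "planted") <- attr(g_full, "planted")
  list(pedigree = ped, genotypes = panel, phenotypes = sim$phenotypes,
       truth = sim$truth, genotypes_full = g_full)
}
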