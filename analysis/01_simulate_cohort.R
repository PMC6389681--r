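#!/usr/bin/env Rscript
# Stage 1: simulate the study-design cohort and write it out as the plain
# text inputs the rest of the workflow reads (pedigree CSV, additive
# genotype text + map, phenotype CSV), plus the ground truth for later
# comparison. 614 cows from 19 sire families on 19 farms, 598 genotyped,
# 2,000 SNPs on 5 chromosomes, one QTL absorbing 25% of the additive
# variance, heritability 0.3.

library(sswgwas)

seed <- 2024L
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = seed, n_snps = 2000L, n_chromosomes = 5L,
                  n_qtl = 1L, qtl_variance_fractions = 0.25,
                  h2_target = 0.3)
dat <- simulate_dataset(cfg)

write_pedigree(dat$pedigree, "results/data/pedigree.csv")
write_genotypes(dat$genotypes, "results/data/genotypes.txt",
                "results/data/genotypes.map")
write_phenotypes(dat$phenotypes, "results/data/phenotypes.csv")
truth <- data.frame(qtl_snp = dat$truth$qtl_snp,
                    qtl_effect = dat$truth$qtl_effect,
                    sigma2_a = dat$truth$sigma2_a,
                    sigma2_e = dat$truth$sigma2_e,
                    realized_h2 = dat$truth$realized_h2)
write.table(truth, "results/data/truth.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

cat("Simulated", nrow(dat$phenotypes), "cows (",
    length(genotyped_ids(dat$genotypes)), "genotyped ) with",
    ncol(dat$genotypes$calls), "SNPs\n")
cat("Planted QTL", dat$truth$qtl_snp, "explaining 25% of sigma2_a;",
    "realized h2 =", round(dat$truth$realized_h2, 3), "\n")
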