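#!/usr/bin/env Rscript
# Stage 2: genotype quality control. SNPs are excluded for call rate below
# 90%, minor allele frequency below 0.05, or Hardy-Weinberg chi-square
# P below 1e-6 (strict inequalities, first-failing-filter attribution).

library(sswgwas)

geno <- read_genotypes("results/data/genotypes.txt",
                       "results/data/genotypes.map")
res <- qc_filter(geno, run_config())
print(res$report)

qc_tab <- data.frame(
  filter = c("call_rate", "maf", "hwe", "retained"),
  n = c(res$report$n_removed_callrate, res$report$n_removed_maf,
        res$report$n_removed_hwe, res$report$n_retained))
write.table(qc_tab, "results/qc_summary.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write_genotypes(res$genotypes, "results/data/genotypes_qc.txt",
                "results/data/genotypes_qc.map")
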