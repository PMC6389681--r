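#!/usr/bin/env Rscript
# Stage 5: window-level reporting. Selects informative windows (>= 0.5% of
# genetic variance), checks whether the top window localizes the planted
# QTL, annotates windows against a small gene coordinate file, and
# reproduces the region aggregation arithmetic on the reference
# milk-protein window table.

library(sswgwas)

windows <- read.delim("results/windows.tsv")
class(windows) <- c("window_table", "data.frame")
truth <- read.delim("results/data/truth.tsv")
geno_qc <- read_genotypes("results/data/genotypes_qc.txt",
                          "results/data/genotypes_qc.map")

inf <- informative_windows(windows, 0.5)
cat(nrow(inf), "informative windows out of", nrow(windows), "\n")
write.table(inf, "results/informative_windows.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

j <- match(truth$qtl_snp, geno_qc$map$snp_id)
top <- windows[which.max(windows$ve_percent), ]
cat("Top window", top$window_id, "on", top$chromosome, "explains",
    round(top$ve_percent, 2), "% of sigma2_a; planted QTL is SNP index",
    j, "\n")

# annotate the informative windows against a toy gene file built around
# the top windows (synthetic coordinates; a real run would use a BED of
# the annotation of the genome build the map refers to)
bed <- file.path(tempdir(), "genes.bed")
writeLines(sprintf("%s\t%d\t%d\tGENE_%02d", inf$chromosome,
                   pmax(inf$start_bp - 5000L, 0L), inf$end_bp + 5000L,
                   seq_len(nrow(inf))), bed)
ann <- annotate_windows(inf, read_bed(bed))
write.table(ann, "results/window_annotation.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

# region aggregation on the reference milk-protein window table
regions <- rbind(
  data.frame(trait = "alpha_s1_casein", chrom = "7", lo = 64.5e6, hi = 64.6e6),
  data.frame(trait = "alpha_s2_casein", chrom = "14", lo = 1.8e6, hi = 2.1e6),
  data.frame(trait = "beta_casein", chrom = "21", lo = 47.7e6, hi = 47.9e6),
  data.frame(trait = "alpha_lactalbumin", chrom = "11", lo = 68.59e6, hi = 76.95e6),
  data.frame(trait = "protein_percentage", chrom = "7", lo = 53.86e6, hi = 70.4e6),
  data.frame(trait = "protein_yield", chrom = "18", lo = 43.37e6, hi = 46.97e6))
regions$n_windows <- NA_integer_
regions$total_ve <- NA_real_
for (i in seq_len(nrow(regions))) {
  agg <- aggregate_region(reference_windows(regions$trait[i]),
                          regions$chrom[i], regions$lo[i], regions$hi[i])
  regions$n_windows[i] <- agg$n_windows
  regions$total_ve[i] <- agg$total_ve_percent
}
print(regions)
write.table(regions, "results/reference_region_totals.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
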