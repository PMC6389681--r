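# Small in-code fixtures shared across test files.

# Two unrelated founders and their offspring.
trio_pedigree <- function() {
  pedigree(c("S", "D", "X"), c(NA, NA, "S"), c(NA, NA, "D"))
}

# Random pedigree: founders plus animals whose parents are drawn from
# earlier animals (or unknown), always topologically valid.
random_pedigree <- function(n, n_founders = max(4L, n %/% 5L), seed = 1L) {
  set.seed(seed)
  animal <- paste0("A", seq_len(n))
  sire <- rep(NA_character_, n)
  dam <- rep(NA_character_, n)
  for (i in (n_founders + 1L):n) {
    pool <- animal[seq_len(i - 1L)]
    sire[i] <- sample(pool, 1L)
    dam[i] <- sample(setdiff(pool, sire[i]), 1L)
  }
  pedigree(animal, sire, dam)
}

# Genotype set with given call matrix and auto map (one chromosome).
make_gs <- function(calls, chrom = NULL) {
  m <- ncol(calls)
  map <- data.frame(
    snp_id = sprintf("s%03d", seq_len(m)),
    chromosome = if (is.null(chrom)) rep("1", m) else chrom,
    position_bp = seq_len(m) * 1000L)
  genotype_set(calls, map)
}

# HWE genotypes at frequency p for n animals (rows) and length(p) SNPs.
random_calls <- function(n, p, seed = 1L) {
  set.seed(seed)
  vapply(p, function(pi) stats::rbinom(n, 2L, pi), numeric(n))
}
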