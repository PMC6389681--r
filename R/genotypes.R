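#' Construct a genotype set
#'
#' Couples an animals-by-markers matrix of additive genotype codes (counts
#' of the second allele, 0/1/2, `NA` = missing) with a marker map. Markers
#' are stored sorted by (chromosome, position), chromosomes ordered by first
#' appearance in the map, bp ties broken by snp id; calls are permuted in
#' lockstep.
#'
#' @param calls numeric matrix, animals in rows (rownames = animal ids),
#'   markers in columns.
#' @param map data frame with columns `snp_id`, `chromosome`, `position_bp`.
#' @return A list of class `"genotype_set"` with elements `calls` and `map`.
#' @export
genotype_set <- function(calls, map) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls))) {
    rownames(calls) <- paste0("ID", seq_len(nrow(calls)))
  }
  need <- c("snp_id", "chromosome", "position_bp")
  if (!all(need %in% names(map))) {
    stop("map must have columns snp_id, chromosome, position_bp")
  }
  map <- data.frame(snp_id = as.character(map$snp_id),
                    chromosome = as.character(map$chromosome),
                    position_bp = as.integer(map$position_bp),
                    stringsAsFactors = FALSE)
  if (ncol(calls) != nrow(map)) {
    stop("genotype matrix has ", ncol(calls), " columns but map has ",
         nrow(map), " markers")
  }
  if (anyDuplicated(map$snp_id)) stop("duplicate snp ids in map")
  if (any(map$position_bp < 1L, na.rm = TRUE)) {
    stop("positions must be 1-based (>= 1)")
  }
  bad <- which(!(calls %in% c(0, 1, 2)) & !is.na(calls))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(calls)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(calls)) + 1L
    stop("invalid genotype code ", calls[i, j], " at (animal '",
         rownames(calls)[i], "', snp '", map$snp_id[j], "')")
  }
  chrom_levels <- unique(map$chromosome)
  ord <- order(match(map$chromosome, chrom_levels), map$position_bp,
               map$snp_id)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  calls <- calls[, ord, drop = FALSE]
  colnames(calls) <- map$snp_id
  structure(list(calls = calls, map = map, chrom_levels = chrom_levels),
            class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat("GenotypeSet:", nrow(x$calls), "animals x", ncol(x$calls), "SNPs on",
      length(x$chrom_levels), "chromosome(s);",
      sum(is.na(x$calls)), "missing calls\n")
  invisible(x)
}

#' Animal ids of a genotype set
#' @param g a [genotype_set].
#' @return character vector of animal ids in matrix row order.
#' @export
genotyped_ids <- function(g) rownames(g$calls)

#' Read genotypes from additive text plus a marker map
#'
#' The genotype file is whitespace-delimited, one row per animal: an animal
#' id in the first column followed by one additive code (0/1/2, `NA` =
#' missing) per SNP. A headerless id-less matrix (exactly as many columns as
#' map rows) is also accepted, with row numbers used as ids. The map is the
#' PLINK 4-column layout: chromosome, snp id, genetic distance (ignored),
#' bp position.
#'
#' @param raw_path path to the genotype table.
#' @param map_path path to the marker map.
#' @return A [genotype_set] with markers sorted by (chromosome, bp).
#' @export
read_genotypes <- function(raw_path, map_path) {
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = c("character", "character",
                                          "character", "integer"))
  if (ncol(map) != 4L) stop("map file must have 4 columns (chr, id, cM, bp)")
  names(map) <- c("chromosome", "snp_id", "cm", "position_bp")
  raw <- utils::read.table(raw_path, header = FALSE, na.strings = "NA",
                           colClasses = "character")
  m <- nrow(map)
  if (ncol(raw) == m + 1L) {
    ids <- raw[[1L]]
    raw <- raw[, -1L, drop = FALSE]
  } else if (ncol(raw) == m) {
    ids <- as.character(seq_len(nrow(raw)))
  } else {
    stop("genotype file has ", ncol(raw), " columns; expected ", m,
         " (or ", m + 1L, " with a leading id column) to match the map")
  }
  calls <- suppressWarnings(matrix(as.numeric(as.matrix(raw)),
                                   nrow = nrow(raw)))
  rownames(calls) <- ids
  genotype_set(calls, map[c("snp_id", "chromosome", "position_bp")])
}

#' Write a genotype set as additive text plus map
#'
#' Inverse of [read_genotypes()].
#'
#' @param g a [genotype_set].
#' @param raw_path,map_path output paths.
#' @export
write_genotypes <- function(g, raw_path, map_path) {
  map <- data.frame(g$map$chromosome, g$map$snp_id, 0, g$map$position_bp)
  utils::write.table(map, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  out <- data.frame(id = rownames(g$calls), g$calls, check.names = FALSE)
  utils::write.table(out, raw_path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(raw_path)
}
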