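#' Sliding-window percentage of genetic variance explained
#'
#' For each run of `w` consecutive SNPs on one chromosome, the window's
#' genetic value per genotyped animal is `a_win = sum_j Z_j u_j` over the
#' member SNPs (Z centered as in the genomic relationship matrix). The
#' window's VE is the sample variance (denominator n - 1) of those values
#' across animals as a percentage of the total additive variance.
#' Window ids are the genome-order index of the first member SNP.
#'
#' @param g post-QC [genotype_set] aligned with `u_hat`.
#' @param u_hat per-SNP effects.
#' @param sigma2_a total additive genetic variance (> 0).
#' @param w window size in SNPs (default 5).
#' @param step slide step in SNPs (default 1, moving windows).
#' @param p allele frequencies used for centering.
#' @return Data frame of class `"window_table"`: `window_id`, `chromosome`,
#'   `start_bp`, `end_bp` (1-based inclusive, from the first/last member
#'   SNP), `ve_percent`.
#' @export
window_variance <- function(g, u_hat, sigma2_a, w = 5L, step = 1L,
                            p = allele_freq(g)) {
  stopifnot(sigma2_a > 0, w >= 1, step >= 1,
            length(u_hat) == ncol(g$calls))
  Z <- z_matrix(g, p)
  map <- g$map
  out <- list()
  for (chrom in unique(map$chromosome)) {
    idx <- which(map$chromosome == chrom)
    m_c <- length(idx)
    if (m_c < w) next  # too few SNPs for one window on this chromosome
    contrib <- sweep(Z[, idx, drop = FALSE], 2L, u_hat[idx], `*`)
    cs <- if (m_c == 1L) contrib else t(apply(contrib, 1L, cumsum))
    starts <- seq.int(1L, m_c - w + 1L, by = step)
    ve <- vapply(starts, function(s) {
      a_win <- cs[, s + w - 1L] - if (s > 1L) cs[, s - 1L] else 0
      stats::var(a_win) / sigma2_a * 100
    }, numeric(1))
    out[[chrom]] <- data.frame(
      window_id = idx[starts],
      chromosome = chrom,
      start_bp = map$position_bp[idx[starts]],
      end_bp = map$position_bp[idx[starts + w - 1L]],
      ve_percent = ve,
      stringsAsFactors = FALSE)
  }
  wt <- if (length(out)) do.call(rbind, out) else {
    data.frame(window_id = integer(0), chromosome = character(0),
               start_bp = integer(0), end_bp = integer(0),
               ve_percent = numeric(0))
  }
  rownames(wt) <- NULL
  class(wt) <- c("window_table", "data.frame")
  wt
}

#' Select informative windows
#'
#' Keeps windows explaining no less than `threshold` percent of the genetic
#' variance (inclusive boundary).
#'
#' @param wt a window table.
#' @param threshold VE threshold in percent (default 0.5).
#' @return The filtered window table.
#' @export
informative_windows <- function(wt, threshold = 0.5) {
  stopifnot(threshold >= 0)
  out <- wt[wt$ve_percent >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate windows over a genomic region
#'
#' Selects windows whose start position falls inside `[bp_lo, bp_hi]` on
#' the given chromosome and returns their count and the simple sum of
#' their VE percentages, the convention used when reporting multi-window
#' regions.
#'
#' @param wt a window table.
#' @param chromosome chromosome label.
#' @param bp_lo,bp_hi region bounds (1-based inclusive, on window starts).
#' @return List with `n_windows` and `total_ve_percent`.
#' @export
aggregate_region <- function(wt, chromosome, bp_lo, bp_hi) {
  stopifnot(bp_lo <= bp_hi)
  sel <- wt$chromosome == as.character(chromosome) &
    wt$start_bp >= bp_lo & wt$start_bp <= bp_hi
  list(n_windows = sum(sel),
       total_ve_percent = sum(wt$ve_percent[sel]))
}

#' Read gene coordinates from BED
#'
#' Standard 0-based half-open BED (chrom, start, end, optional name);
#' converted internally to 1-based inclusive coordinates.
#'
#' @param path path to a BED file.
#' @return Data frame with `gene_id`, `chromosome`, `start_bp`, `end_bp`
#'   (1-based inclusive).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(gene_id = character(0), chromosome = character(0),
                      start_bp = integer(0), end_bp = integer(0)))
  }
  parts <- strsplit(lines, "[ \t]+")
  out <- lapply(seq_along(parts), function(i) {
    f <- parts[[i]]
    if (length(f) < 3L) stop("malformed BED line ", i, ": fewer than 3 fields")
    s <- suppressWarnings(as.integer(f[2L]))
    e <- suppressWarnings(as.integer(f[3L]))
    if (is.na(s) || is.na(e) || s < 0L || e < s) {
      stop("malformed BED line ", i, ": bad coordinates")
    }
    data.frame(gene_id = if (length(f) >= 4L) f[4L] else paste0("feature", i),
               chromosome = f[1L], start_bp = s + 1L, end_bp = e,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Annotate windows with overlapping or nearby genes
#'
#' Genes overlapping a window are reported with distance 0 and the overlap
#' length in bp; otherwise the nearest gene on the same chromosome within
#' `max_distance_bp` is reported with a signed gap (positive if the gene is
#' downstream of the window end, negative if upstream of the window start).
#'
#' @param wt a window table.
#' @param genes gene coordinates from [read_bed()] (1-based inclusive).
#' @param max_distance_bp maximum gap for nearest-gene reporting
#'   (default 1 Mbp).
#' @return Data frame with `window_id`, `gene_id`, `overlap_bp`,
#'   `distance_bp`; `distance_bp == 0` iff `overlap_bp > 0`.
#' @export
annotate_windows <- function(wt, genes, max_distance_bp = 1e6) {
  empty <- data.frame(window_id = integer(0), gene_id = character(0),
                      overlap_bp = integer(0), distance_bp = integer(0))
  if (!nrow(wt) || !nrow(genes)) return(empty)
  out <- list()
  for (i in seq_len(nrow(wt))) {
    gi <- genes[genes$chromosome == wt$chromosome[i], , drop = FALSE]
    if (!nrow(gi)) next
    ov <- pmin(gi$end_bp, wt$end_bp[i]) - pmax(gi$start_bp, wt$start_bp[i]) + 1L
    hit <- ov > 0L
    if (any(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        window_id = wt$window_id[i], gene_id = gi$gene_id[hit],
        overlap_bp = ov[hit], distance_bp = 0L, stringsAsFactors = FALSE)
    } else {
      gap <- ifelse(gi$start_bp > wt$end_bp[i],
                    gi$start_bp - wt$end_bp[i],
                    -(wt$start_bp[i] - gi$end_bp))
      j <- which.min(abs(gap))
      if (abs(gap[j]) <= max_distance_bp) {
        out[[length(out) + 1L]] <- data.frame(
          window_id = wt$window_id[i], gene_id = gi$gene_id[j],
          overlap_bp = 0L, distance_bp = gap[j], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Export Manhattan-ready tracks
#'
#' Writes two deterministic TSVs: a per-SNP track of -log10(P) and a
#' per-window track of VE%, both with genome-cumulative coordinates
#' (chromosome offsets = cumulative maxima of positions, in map order).
#' The SNP track carries the genome-wide Bonferroni threshold as a
#' constant column for plotting.
#'
#' @param snp_table data frame with `snp_id`, `chromosome`, `position_bp`,
#'   `minus_log10_p`.
#' @param wt a window table.
#' @param dir output directory (created if needed).
#' @param alpha Bonferroni family-wise rate used for the threshold column.
#' @return Character vector of the two file paths.
#' @export
manhattan_export <- function(snp_table, wt, dir, alpha = 0.01) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chroms <- unique(snp_table$chromosome)
  sizes <- vapply(chroms, function(ch) {
    max(snp_table$position_bp[snp_table$chromosome == ch])
  }, numeric(1))
  offsets <- stats::setNames(cumsum(c(0, utils::head(sizes, -1))), chroms)
  snp_out <- snp_table
  snp_out$cum_bp <- snp_out$position_bp + offsets[snp_out$chromosome]
  snp_out$threshold <- bonferroni_threshold(nrow(snp_table), alpha)
  win_out <- as.data.frame(wt)
  win_out$cum_bp <- win_out$start_bp + offsets[win_out$chromosome]
  snp_path <- file.path(dir, "snp_track.tsv")
  win_path <- file.path(dir, "window_track.tsv")
  utils::write.table(snp_out, snp_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(win_out, win_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  c(snp_path, win_path)
}
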