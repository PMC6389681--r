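#' Numerator relationship matrix (tabular method)
#'
#' Builds the dense pedigree relationship matrix A by the tabular method:
#' `a(i,i) = 1 + a(s_i, d_i)/2` and, for j before i,
#' `a(i,j) = (a(j, s_i) + a(j, d_i)) / 2`, an unknown parent contributing 0.
#' The diagonal is `1 + F`, with F the inbreeding coefficient, so inbreeding
#' is accounted for exactly.
#'
#' @param ped a [pedigree] (topologically ordered by construction).
#' @return Symmetric matrix with animal ids as dimnames.
#' @export
a_matrix <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$animal
  si <- unname(idx[ped$sire])
  di <- unname(idx[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (!is.na(s)) A[j, s] else 0
      ad_ <- if (!is.na(d)) A[j, d] else 0
      v <- 0.5 * (as_ + ad_)
      A[j, i] <- v
      A[i, j] <- v
    }
  }
  A
}

#' Inbreeding coefficients from a pedigree
#'
#' `F = diag(A) - 1`, computed from the tabular [a_matrix()].
#'
#' @param ped a [pedigree].
#' @return Named numeric vector of inbreeding coefficients.
#' @export
inbreeding <- function(ped) diag(a_matrix(ped)) - 1

#' Inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding: for each animal the Mendelian
#' sampling variance is `m_i = 0.5 - 0.25 (F_s + F_d)` (both parents known),
#' `0.75 - 0.25 F_p` (one parent), or 1 (founder), with parental inbreeding
#' taken from the tabular A. The contribution `alpha_i = 1/m_i` is added at
#' (i,i), `-alpha_i/2` at each (i, parent), and `alpha_i/4` at each
#' (parent, parent) cell.
#'
#' @param ped a [pedigree].
#' @return Symmetric matrix, the exact inverse of [a_matrix()].
#' @export
a_inverse <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$animal
  si <- unname(idx[ped$sire])
  di <- unname(idx[ped$dam])
  f <- inbreeding(ped)
  Ainv <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    m <- 1
    if (!is.na(s) && !is.na(d)) m <- 0.5 - 0.25 * (f[s] + f[d])
    else if (!is.na(s)) m <- 0.75 - 0.25 * f[s]
    else if (!is.na(d)) m <- 0.75 - 0.25 * f[d]
    alpha <- 1 / m
    Ainv[i, i] <- Ainv[i, i] + alpha
    for (p in c(s, d)) {
      if (is.na(p)) next
      Ainv[i, p] <- Ainv[i, p] - alpha / 2
      Ainv[p, i] <- Ainv[p, i] - alpha / 2
    }
    for (p in c(s, d)) {
      for (q in c(s, d)) {
        if (is.na(p) || is.na(q)) next
        Ainv[p, q] <- Ainv[p, q] + alpha / 4
      }
    }
  }
  Ainv
}

#' Genotyped-block submatrix A22
#'
#' Principal submatrix of A for the genotyped animals, in the order given
#' (which should match the genotype matrix row order).
#'
#' @param A relationship matrix with dimnames.
#' @param ids animal ids to keep.
#' @return The principal submatrix, dimnames = `ids`.
#' @export
subset_a22 <- function(A, ids) {
  missing_ids <- setdiff(ids, rownames(A))
  if (length(missing_ids)) {
    stop("ids not in relationship matrix: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  A[ids, ids, drop = FALSE]
}
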