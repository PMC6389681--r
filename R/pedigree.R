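#' Construct a pedigree
#'
#' A pedigree is a data frame of (animal, sire, dam) identifier triples in
#' topological order: every parent appears as an animal before its offspring.
#' Unknown parents are stored as `NA`. Parents referenced but never declared
#' as animals are inserted as founders at the front.
#'
#' @param animal character vector of animal ids (unique).
#' @param sire,dam character vectors of parent ids; `NA`, `""` or `"0"` mark
#'   an unknown parent.
#' @return A data frame of class `"pedigree"` with columns `animal`, `sire`,
#'   `dam`, topologically sorted.
#' @export
pedigree <- function(animal, sire, dam) {
  animal <- as.character(animal)
  sire <- clean_parent(sire)
  dam <- clean_parent(dam)
  if (anyDuplicated(animal)) {
    stop("duplicate animal id(s): ",
         paste(unique(animal[duplicated(animal)]), collapse = ", "))
  }
  if (length(sire) != length(animal) || length(dam) != length(animal)) {
    stop("animal, sire and dam must have equal length")
  }
  # auto-insert referenced-but-undeclared parents as founders
  parents <- setdiff(stats::na.omit(c(sire, dam)), animal)
  if (length(parents)) {
    animal <- c(parents, animal)
    sire <- c(rep(NA_character_, length(parents)), sire)
    dam <- c(rep(NA_character_, length(parents)), dam)
  }
  ord <- topo_order(animal, sire, dam)
  ped <- data.frame(animal = animal[ord], sire = sire[ord], dam = dam[ord],
                    stringsAsFactors = FALSE)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

clean_parent <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == "" | x == "0"] <- NA_character_
  x
}

# Kahn's algorithm; errors on a cycle naming one member.
topo_order <- function(animal, sire, dam) {
  n <- length(animal)
  idx <- seq_len(n)
  names(idx) <- animal
  si <- unname(idx[sire])  # NA where unknown
  di <- unname(idx[dam])
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        if (p == i) stop("animal '", animal[i], "' is its own parent (cycle)")
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  out <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != n) {
    bad <- setdiff(seq_len(n), out)[1L]
    stop("pedigree contains a cycle involving animal '", animal[bad], "'")
  }
  out
}

#' Read a pedigree from CSV
#'
#' Expects a header `animal,sire,dam`; `0` or an empty field denotes an
#' unknown parent. Parents that never appear in the animal column are added
#' as founders.
#'
#' @param path path to a CSV file.
#' @return A [pedigree] in topological order.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(df))) {
    stop("pedigree file must have header animal,sire,dam")
  }
  pedigree(df$animal, df$sire, df$dam)
}

#' Write a pedigree to CSV
#'
#' Inverse of [read_pedigree()]; unknown parents are written as `0`.
#'
#' @param ped a [pedigree].
#' @param path output path.
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree with", nrow(x), "animals (",
      sum(is.na(x$sire) & is.na(x$dam)), "founders )\n")
  NextMethod()
}
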