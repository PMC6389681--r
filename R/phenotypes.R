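#' Read a phenotype table
#'
#' Long-format CSV with one row per record: columns `animal`, `trait`,
#' `value`, `farm`, `lactation`, `parity`. Farm, lactation and parity are
#' categorical labels used as fixed effects in the animal model.
#'
#' @param path path to a CSV file.
#' @return A data frame of class `"phenotype_table"`.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal", "trait", "value", "farm", "lactation", "parity")
  if (!all(need %in% names(df))) {
    stop("phenotype file must have columns ", paste(need, collapse = ", "))
  }
  df$value <- as.numeric(df$value)
  for (col in c("animal", "trait", "farm", "lactation", "parity")) {
    df[[col]] <- as.character(df[[col]])
    if (any(is.na(df[[col]]) | df[[col]] == "")) {
      stop("empty level(s) in column '", col, "'")
    }
  }
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Write a phenotype table
#' @param ph a phenotype table.
#' @param path output path.
#' @export
write_phenotypes <- function(ph, path) {
  utils::write.csv(as.data.frame(ph), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Casein index from the six major milk proteins
#'
#' The casein index is the total casein as a percentage of total protein:
#' `100 * (as1 + as2 + b + k) / (as1 + as2 + b + k + ala + blg)`,
#' with the four caseins (alpha-s1, alpha-s2, beta, kappa) in the numerator
#' and the two whey proteins (alpha-lactalbumin, beta-lactoglobulin) added
#' in the denominator. All inputs are weight proportions of total protein
#' (wt/wt%); the index is scale-invariant, so any common unit works.
#'
#' @param as1,as2,b,k casein fractions (wt/wt%), non-negative.
#' @param ala,blg whey protein fractions (wt/wt%), non-negative.
#' @return The casein index in percent (vectorised over inputs).
#' @export
casein_index <- function(as1, as2, b, k, ala, blg) {
  args <- cbind(as1, as2, b, k, ala, blg)
  if (any(args < 0, na.rm = TRUE)) stop("milk protein fractions must be >= 0")
  cas <- as1 + as2 + b + k
  tot <- cas + ala + blg
  if (any(tot == 0, na.rm = TRUE)) {
    stop("casein index undefined when all six proteins are zero")
  }
  100 * cas / tot
}
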