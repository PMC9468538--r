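#' Durum wheat chromosome names
#'
#' The 14 chromosomes of tetraploid (AABB) durum wheat, in canonical order
#' `1A, 1B, ..., 7A, 7B`. All tables handled by the package are validated
#' against this set.
#'
#' @return Character vector of length 14.
#' @export
#' @examples
#' durum_chromosomes()
durum_chromosomes <- function() {
  paste0(rep(1:7, each = 2), rep(c("A", "B"), 7))
}

#' Normalize chromosome names
#'
#' Upper-cases and trims chromosome labels ("1a " -> "1A") and checks them
#' against the durum set.
#'
#' @param x Character vector of chromosome labels.
#' @return Character vector of normalized names.
#' @export
normalize_chromosome <- function(x) {
  out <- toupper(trimws(as.character(x)))
  bad <- !out %in% durum_chromosomes()
  if (any(bad)) {
    stop("unknown durum chromosome name(s): ",
         paste(unique(out[bad]), collapse = ", "))
  }
  out
}

#' Genome (subgenome) of a chromosome
#'
#' @param chromosome Character vector of normalized chromosome names.
#' @return Character vector, `"A"` or `"B"` (the trailing letter).
#' @export
chromosome_genome <- function(chromosome) {
  substr(chromosome, nchar(chromosome), nchar(chromosome))
}

# order chromosomes canonically (1A < 1B < ... < 7B)
chromosome_order <- function(chromosome) {
  order(match(chromosome, durum_chromosomes()))
}
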