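# Genetic vs physical hotspot distribution: each chromosome is cut into
# n_bins segments of equal length on the chosen scale and hotspots are
# counted per bin index pooled across chromosomes. Telomeric enrichment on
# the physical axis shows up as mass in bins 1 and n_bins.

#' Assign a position to an equal-length chromosome bin
#'
#' Bins are `n_bins` segments of equal length; bin `b` covers
#' `[(b-1) L / n_bins, b L / n_bins)`, except that a position exactly at
#' the chromosome end falls in bin `n_bins`.
#'
#' @param position Numeric vector of positions (same scale as
#'   `chrom_length`).
#' @param chrom_length Chromosome length (scalar or vector matching
#'   `position`).
#' @param n_bins Number of bins (default 5).
#' @return Integer vector of 1-based bin indices.
#' @export
assign_bin <- function(position, chrom_length, n_bins = 5L) {
  stopifnot(n_bins >= 1)
  if (any(position < 0 | position > chrom_length)) {
    stop("position outside [0, chromosome length]")
  }
  pmin(as.integer(floor(n_bins * position / chrom_length)) + 1L,
       as.integer(n_bins))
}

#' Hotspot distribution over equal-length chromosome bins
#'
#' Places each hotspot once — by the midpoint of its CI on the chosen
#' scale — into one of `n_bins` equal-length bins of its chromosome, and
#' pools counts across chromosomes.
#'
#' @param hotspots Hotspot data.frame. For `scale = "genetic"` it must
#'   carry `ci_start_cM`/`ci_end_cM`; for `scale = "physical"`, the
#'   physical CI columns of `reference` (see [hotspot_physical_ci()]).
#' @param chrom_lengths Named vector of chromosome lengths on the chosen
#'   scale (cM, or Mb for physical).
#' @param scale `"genetic"` or `"physical"`.
#' @param reference Physical reference name (used when
#'   `scale = "physical"`).
#' @param n_bins Number of bins (default 5).
#' @return Data.frame with `scale`, `bin`, `count`, `percentage`.
#' @export
bin_distribution <- function(hotspots, chrom_lengths,
                             scale = c("genetic", "physical"),
                             reference = "Svevo", n_bins = 5L) {
  scale <- match.arg(scale)
  if (scale == "genetic") {
    mid <- (hotspots$ci_start_cM + hotspots$ci_end_cM) / 2
  } else {
    ref <- tolower(reference)
    s_col <- paste0("ci_", ref, "_start_Mb")
    e_col <- paste0("ci_", ref, "_end_Mb")
    if (!all(c(s_col, e_col) %in% names(hotspots))) {
      stop("hotspots lack physical CI columns for reference '", reference,
           "'")
    }
    mid <- (hotspots[[s_col]] + hotspots[[e_col]]) / 2
  }
  absent <- setdiff(unique(hotspots$chromosome), names(chrom_lengths))
  if (length(absent) > 0) {
    stop("no chromosome length for: ", paste(absent, collapse = ", "))
  }
  L <- unname(chrom_lengths[hotspots$chromosome])
  bins <- assign_bin(mid, L, n_bins)
  counts <- tabulate(bins, nbins = n_bins)
  data.frame(scale = scale, bin = seq_len(n_bins), count = counts,
             percentage = if (sum(counts) > 0) 100 * counts / sum(counts)
                          else rep(0, n_bins),
             stringsAsFactors = FALSE)
}
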