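# Homothetic projection: positions are rescaled between maps linearly
# using the nearest flanking markers shared by both maps; the same local
# ratio rescales the CI width. Coordinates stay continuous reals; the
# overview grid discretizes exactly once downstream.

#' Impute missing confidence intervals from LD decay
#'
#' MTA whose source study reported no confidence interval receive the
#' intra-chromosomal LD-decay distance of their chromosome as a surrogate
#' full CI width. Records with an observed CI are untouched.
#'
#' @param mta Data.frame of MTA records.
#' @param ld_decay Named numeric vector (cM), one entry per chromosome
#'   present in `mta` (see [read_ld_decay()]).
#' @return The input data.frame with `ci_cM` complete and a `ci_source`
#'   column (`"original"` or `"ld_decay"`).
#' @export
impute_ci <- function(mta, ld_decay) {
  absent <- setdiff(unique(mta$chromosome), names(ld_decay))
  if (length(absent) > 0) {
    stop("no LD-decay entry for chromosome(s): ",
         paste(absent, collapse = ", "))
  }
  missing <- is.na(mta$ci_cM)
  mta$ci_source <- ifelse(missing, "ld_decay", "original")
  mta$ci_cM[missing] <- unname(ld_decay[mta$chromosome[missing]])
  mta
}

#' Project a position between maps via flanking shared markers
#'
#' Rescales source-map positions into consensus coordinates using, for each
#' position, the nearest pair of flanking markers shared by both maps
#' (linear interpolation). Positions outside the shared-marker span are
#' extended using the nearest interval's ratio and flagged.
#'
#' @param p Numeric vector of source-map positions (cM).
#' @param source_cM,consensus_cM Positions of the shared markers on the
#'   source and consensus map (same order, >= 2 markers, `source_cM`
#'   strictly increasing).
#' @return Data.frame with `position` (consensus cM), `ratio` (local cM
#'   scaling factor) and `flag` (`"anchored"` or `"extrapolated"`).
#' @export
project_position <- function(p, source_cM, consensus_cM) {
  n <- length(source_cM)
  if (n < 2 || length(consensus_cM) != n) {
    stop("projection requires >= 2 shared markers on the chromosome")
  }
  ord <- order(source_cM)
  source_cM <- source_cM[ord]
  consensus_cM <- consensus_cM[ord]
  if (any(diff(source_cM) == 0)) {
    stop("zero-length source interval between shared markers")
  }
  i <- findInterval(p, source_cM, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), n - 1L)
  s1 <- source_cM[i]; s2 <- source_cM[i + 1L]
  c1 <- consensus_cM[i]; c2 <- consensus_cM[i + 1L]
  ratio <- (c2 - c1) / (s2 - s1)
  data.frame(
    position = c1 + (p - s1) * ratio,
    ratio = ratio,
    flag = ifelse(p >= source_cM[1] & p <= source_cM[n],
                  "anchored", "extrapolated"),
    stringsAsFactors = FALSE)
}

# rescale a CI width by the local ratio and clamp its endpoints to the
# chromosome; returns width, and whether clamping occurred
clamp_ci <- function(position, ci, length_cM) {
  lo <- pmax(position - ci / 2, 0)
  hi <- pmin(position + ci / 2, length_cM)
  list(ci = hi - lo, clamped = (hi - lo) < ci - 1e-12)
}

#' Project an MTA database onto the consensus map
#'
#' Places every MTA (position and CI) in consensus coordinates. Markers
#' that exist by name on the consensus map are placed by direct lookup
#' (identity projection) — the dominant case when the source studies used
#' SNP panels shared with the consensus map. Remaining records are rescaled
#' through the markers shared between their source map and the consensus
#' map; their CI width is multiplied by the same local ratio. When no
#' source map is supplied, positions are taken to be in consensus
#' coordinates already.
#'
#' @param mta Data.frame of MTA records with complete CIs (run
#'   [impute_ci()] first; records with `NA` CI are an error).
#' @param consensus_map A [genetic_map()].
#' @param source_map Optional [genetic_map()] carrying the source
#'   coordinates of `mta`.
#' @return The input with `position_cM` in consensus coordinates, plus
#'   `projection_flag` (`"identity"`, `"anchored"` or `"extrapolated"`) and
#'   `ci_clamped` (logical; CI truncated at a chromosome end).
#' @export
project_mta <- function(mta, consensus_map, source_map = NULL) {
  if (any(is.na(mta$ci_cM))) {
    stop("MTA with missing CI: run impute_ci() before projection")
  }
  if (!"ci_source" %in% names(mta)) mta$ci_source <- "original"
  lengths <- consensus_map$chrom_lengths_cM
  cons <- consensus_map$markers
  mta$projection_flag <- NA_character_
  ratio <- rep(1, nrow(mta))

  # direct lookup for markers named on the consensus map
  idx <- match(mta$marker_id, cons$marker)
  direct <- !is.na(mta$marker_id) & !is.na(idx) &
    cons$chromosome[idx] == mta$chromosome
  mta$position_cM[direct] <- cons$position_cM[idx[direct]]
  mta$projection_flag[direct] <- "identity"

  rest <- which(!direct)
  if (length(rest) > 0) {
    if (is.null(source_map) ||
        identical(source_map$name, consensus_map$name)) {
      mta$projection_flag[rest] <- "identity"
    } else {
      for (chr in unique(mta$chromosome[rest])) {
        rows <- rest[mta$chromosome[rest] == chr]
        src <- source_map$markers[source_map$markers$chromosome == chr, ]
        shared <- intersect(src$marker,
                            cons$marker[cons$chromosome == chr])
        if (length(shared) < 2) {
          stop("fewer than 2 shared markers on chromosome ", chr)
        }
        s <- src$position_cM[match(shared, src$marker)]
        co <- cons$position_cM[match(shared, cons$marker)]
        pr <- project_position(mta$position_cM[rows], s, co)
        mta$position_cM[rows] <- pr$position
        mta$projection_flag[rows] <- pr$flag
        ratio[rows] <- pr$ratio
      }
    }
  }

  L <- unname(lengths[mta$chromosome])
  out_of_range <- mta$position_cM < 0 | mta$position_cM > L
  mta$position_cM <- pmin(pmax(mta$position_cM, 0), L)
  mta$projection_flag[out_of_range] <- "extrapolated"
  mta$ci_cM <- mta$ci_cM * abs(ratio)
  cl <- clamp_ci(mta$position_cM, mta$ci_cM, L)
  mta$ci_cM <- cl$ci
  mta$ci_clamped <- cl$clamped
  mta
}

#' Interpolate a genetic position to physical coordinates
#'
#' Piecewise-linear interpolation of Mb over cM between the flanking
#' anchors of one chromosome. Positions outside the anchor span are
#' extended with the nearest interval's slope and flagged. Locally
#' non-monotone Mb (real maps contain inversions) triggers a warning but is
#' still interpolated.
#'
#' @param x_cM Numeric vector of consensus genetic positions.
#' @param anchors An [anchor_table()].
#' @param chromosome Single chromosome name.
#' @param details If `TRUE`, return a data.frame with an extrapolation
#'   flag; otherwise (default) the numeric Mb vector.
#' @return Numeric vector of Mb positions, or a data.frame when
#'   `details = TRUE`.
#' @export
genetic_to_physical <- function(x_cM, anchors, chromosome, details = FALSE) {
  a <- anchors$anchors[anchors$anchors$chromosome == chromosome, ]
  if (nrow(a) < 2) {
    stop("need >= 2 anchors on chromosome ", chromosome, " for reference ",
         anchors$reference_name)
  }
  if (any(diff(a$Mb) < 0)) {
    warning("non-monotone Mb anchors on ", chromosome,
            " (inversion?); interpolating anyway")
  }
  n <- nrow(a)
  i <- findInterval(x_cM, a$cM, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), n - 1L)
  slope <- (a$Mb[i + 1L] - a$Mb[i]) / (a$cM[i + 1L] - a$cM[i])
  mb <- a$Mb[i] + (x_cM - a$cM[i]) * slope
  if (!details) return(mb)
  data.frame(Mb = mb,
             flag = ifelse(x_cM >= a$cM[1] & x_cM <= a$cM[n],
                           "interpolated", "extrapolated"),
             stringsAsFactors = FALSE)
}
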