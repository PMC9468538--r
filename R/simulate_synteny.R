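# Synthetic synteny inputs: member markers of selected hotspots receive
# planted alignments (SAM, one file per genome and stringency round)
# inside planted target-genome regions, together with decoy hits that the
# filtering and merging rules must remove, and GFF3 gene models planted
# inside the regions. Sequence content is not simulated; CIGAR strings
# carry the length information (soft clips = unaligned marker tail).

default_target_genomes <- function() {
  list(
    bd = list(n_chrom = 5L, chrom_Mb = 75, region_prob = 1.0),
    os = list(n_chrom = 12L, chrom_Mb = 45, region_prob = 0.6),
    zm = list(n_chrom = 10L, chrom_Mb = 230, region_prob = 0.15))
}

sam_header <- function(genome, spec) {
  c("@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s%d\tLN:%d", genome, seq_len(spec$n_chrom),
            as.integer(spec$chrom_Mb * 1e6)))
}

sam_record <- function(marker, chrom, start0, mapq, marker_len, aligned_len,
                       secondary = FALSE) {
  clip <- marker_len - aligned_len
  cigar <- if (clip > 0) sprintf("%dM%dS", aligned_len, clip)
           else sprintf("%dM", aligned_len)
  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
          marker, if (secondary) 256L else 0L, chrom, start0 + 1L,
          as.integer(mapq), cigar)
}

#' Generate synthetic marker-alignment and annotation fixtures
#'
#' Plants syntenic regions for the member markers of the supplied hotspots
#' on up to three target genomes, writes the corresponding SAM files (one
#' per genome and stringency round), decoy hits exercising the filter and
#' ambiguity rules, and GFF3 gene models inside every planted region.
#'
#' @param hotspots Hotspot table (from [merge_peaks()]) with a `members`
#'   list-column.
#' @param mta MTA table mapping `mta_id` to `marker_id`.
#' @param seed Integer seed.
#' @param dir Output directory (created; default a fresh temp directory).
#' @param genomes Target genome spec: named list of
#'   `list(n_chrom, chrom_Mb, region_prob)`.
#' @param marker_fraction Fraction of a hotspot's markers given a planted
#'   hit in each chosen genome (default 0.7, at least 2).
#' @param marker_length Simulated marker length (bp, default 100).
#' @param region_span_bp Span within which planted hits fall (default
#'   2e6, below the clustering gap so each region is called once).
#' @param n_decoys Number of each decoy class (short-alignment, low-MAPQ,
#'   ambiguous tie; default 3).
#' @return List with `sam_files`, `gff_files`, `planted_regions` (ground
#'   truth data.frame), `decoy_markers`, and `dir`.
#' @export
simulate_synteny_fixture <- function(hotspots, mta, seed,
                                     dir = tempfile("synteny"),
                                     genomes = default_target_genomes(),
                                     marker_fraction = 0.7,
                                     marker_length = 100L,
                                     region_span_bp = 2e6,
                                     n_decoys = 3L) {
  set.seed(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rounds <- STRINGENCY_ROUNDS
  recs <- list()  # recs[[genome]][[round]] = character vector of SAM lines
  for (g in names(genomes)) {
    recs[[g]] <- stats::setNames(vector("list", length(rounds)), rounds)
  }
  add_rec <- function(genome, round, line) {
    recs[[genome]][[round]] <<- c(recs[[genome]][[round]], line)
  }
  planted <- list()

  for (i in seq_len(nrow(hotspots))) {
    members <- hotspots$members[[i]]
    mk <- mta$marker_id[match(members, mta$mta_id)]
    mk <- mk[!is.na(mk)]
    if (length(mk) < 2) next
    for (g in names(genomes)) {
      spec <- genomes[[g]]
      if (stats::runif(1) > spec$region_prob) next
      chrom <- sprintf("%s%d", g, sample.int(spec$n_chrom, 1))
      chrom_len <- spec$chrom_Mb * 1e6
      start <- round(stats::runif(1, 0, chrom_len - region_span_bp - 1e4))
      n_hit <- max(2L, round(marker_fraction * length(mk)))
      hit_mk <- sample(mk, min(n_hit, length(mk)))
      offs <- sort(round(stats::runif(length(hit_mk), 0, region_span_bp)))
      for (j in seq_along(hit_mk)) {
        round_j <- sample(rounds, 1, prob = c(0.6, 0.25, 0.15))
        aligned <- round(stats::runif(1, 0.70, 0.98) * marker_length)
        mapq <- sample(20:60, 1)
        add_rec(g, round_j,
                sam_record(hit_mk[j], chrom, start + offs[j], mapq,
                           marker_length, aligned))
        # occasional lower-stringency duplicate elsewhere: the merge must
        # still prefer the planted (higher-round) placement
        if (round_j == "high" && stats::runif(1) < 0.2) {
          other <- sprintf("%s%d", g, sample.int(spec$n_chrom, 1))
          add_rec(g, "low",
                  sam_record(hit_mk[j], other,
                             round(stats::runif(1, 0, chrom_len * 0.9)),
                             sample(20:60, 1), marker_length, aligned))
        }
      }
      planted[[length(planted) + 1]] <- data.frame(
        hotspot_id = hotspots$hotspot_id[i], target_genome = g,
        target_chromosome = chrom, start = start,
        end = start + offs[length(offs)] +
          round(0.98 * marker_length),
        n_markers = length(hit_mk), stringsAsFactors = FALSE)
    }
  }

  # decoys: hits the pipeline must reject
  decoys <- list(short = character(), lowq = character(),
                 ambiguous = character())
  g1 <- names(genomes)[1]
  len1 <- genomes[[g1]]$chrom_Mb * 1e6
  for (d in seq_len(n_decoys)) {
    m_short <- sprintf("decoy_short%02d", d)
    add_rec(g1, "high",
            sam_record(m_short, paste0(g1, "1"),
                       round(stats::runif(1, 0, len1 * 0.9)), 50,
                       marker_length, round(0.60 * marker_length)))
    m_lowq <- sprintf("decoy_lowq%02d", d)
    add_rec(g1, "high",
            sam_record(m_lowq, paste0(g1, "1"),
                       round(stats::runif(1, 0, len1 * 0.9)), 10,
                       marker_length, marker_length))
    m_amb <- sprintf("decoy_amb%02d", d)
    p1 <- round(stats::runif(1, 0, len1 * 0.9))
    p2 <- round(stats::runif(1, 0, len1 * 0.9))
    add_rec(g1, "medium",
            sam_record(m_amb, paste0(g1, "1"), p1, 30, marker_length,
                       marker_length))
    add_rec(g1, "medium",
            sam_record(m_amb, paste0(g1, "2"), p2, 30, marker_length,
                       marker_length))
    decoys$short <- c(decoys$short, m_short)
    decoys$lowq <- c(decoys$lowq, m_lowq)
    decoys$ambiguous <- c(decoys$ambiguous, m_amb)
  }

  sam_files <- character()
  for (g in names(genomes)) {
    for (r in rounds) {
      path <- file.path(dir, sprintf("hits_%s_%s.sam", g, r))
      writeLines(c(sam_header(g, genomes[[g]]),
                   recs[[g]][[r]]), path)
      sam_files <- c(sam_files, path)
    }
  }

  planted_regions <- if (length(planted)) do.call(rbind, planted)
                     else data.frame()
  gff_files <- character()
  for (g in names(genomes)) {
    spec <- genomes[[g]]
    genes <- list()
    k <- 0L
    pr <- planted_regions[planted_regions$target_genome == g, , drop = FALSE]
    for (j in seq_len(nrow(pr))) {
      for (gg in 1:3) {  # three genes per planted region
        k <- k + 1L
        gs <- round(stats::runif(1, pr$start[j],
                                 max(pr$start[j], pr$end[j] - 5e3)))
        genes[[k]] <- data.frame(chrom = pr$target_chromosome[j],
                                 start = gs, end = gs + 3e3,
                                 stringsAsFactors = FALSE)
      }
    }
    for (cc in seq_len(spec$n_chrom)) {  # background genes
      for (gg in 1:5) {
        k <- k + 1L
        gs <- round(stats::runif(1, 0, spec$chrom_Mb * 1e6 - 1e4))
        genes[[k]] <- data.frame(chrom = sprintf("%s%d", g, cc),
                                 start = gs, end = gs + 3e3,
                                 stringsAsFactors = FALSE)
      }
    }
    gdf <- do.call(rbind, genes)
    gr <- GenomicRanges::GRanges(
      gdf$chrom, IRanges::IRanges(gdf$start + 1L, gdf$end),
      strand = sample(c("+", "-"), nrow(gdf), replace = TRUE))
    gr$source <- "qtlhotspots-sim"
    gr$type <- "gene"
    gr$ID <- sprintf("gene_%s_%04d", g, seq_along(gr))
    gr$Name <- gr$ID
    gr$description <- "synthetic gene model"
    path <- file.path(dir, sprintf("genes_%s.gff3", g))
    rtracklayer::export(sort(gr), path, format = "gff3")
    gff_files <- c(gff_files, path)
  }

  list(sam_files = sam_files, gff_files = gff_files,
       planted_regions = planted_regions, decoy_markers = decoys,
       dir = dir)
}
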