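# Ortho-MQTL calling: marker sequences of hotspot members are aligned
# (externally, e.g. bwa-mem) against other grass genomes at three
# stringency rounds; this module consumes the SAM output, filters and
# deduplicates the hits, and clusters them into syntenic intervals.
# Internal coordinates are 0-based half-open; SAM's 1-based input is
# converted at the boundary.

STRINGENCY_ROUNDS <- c("high", "medium", "low")

#' Read marker alignments from a SAM file
#'
#' Parses one SAM file (markers vs one target genome at one stringency
#' round) into a hit table. Unmapped records are skipped. Marker and
#' aligned lengths are derived from the CIGAR string (soft-clipped bases
#' count toward marker length, not aligned length).
#'
#' @param path SAM file path.
#' @param genome Target genome label; defaults to parsing a
#'   `hits_<genome>_<round>.sam` file name.
#' @param round Stringency round (`"high"`, `"medium"` or `"low"`);
#'   defaults to the file name as for `genome`.
#' @return Data.frame with one row per mapped record: `marker_id`,
#'   `target_genome`, `target_chromosome`, `target_start`, `target_end`
#'   (0-based half-open bp), `marker_length`, `aligned_length`,
#'   `mapping_quality`, `stringency_round`, `is_secondary`.
#' @export
read_alignments <- function(path, genome = NULL, round = NULL) {
  base <- sub("\\.sam$", "", basename(path))
  parts <- strsplit(base, "_", fixed = TRUE)[[1]]
  if (is.null(genome) || is.null(round)) {
    if (length(parts) < 3 || parts[1] != "hits") {
      stop("cannot infer genome/round from file name '", basename(path),
           "'; pass them explicitly")
    }
    if (is.null(genome)) genome <- parts[2]
    if (is.null(round)) round <- parts[3]
  }
  round <- match.arg(round, STRINGENCY_ROUNDS)
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam))
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"))
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  mapped <- bitwAnd(x$flag, 4L) == 0L & !is.na(x$pos)
  cigar <- x$cigar[mapped]
  refw <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  qlen <- GenomicAlignments::cigarWidthAlongQuerySpace(
    cigar, after.soft.clipping = FALSE)
  alen <- GenomicAlignments::cigarWidthAlongQuerySpace(
    cigar, after.soft.clipping = TRUE)
  data.frame(
    marker_id = x$qname[mapped],
    target_genome = rep(genome, sum(mapped)),
    target_chromosome = as.character(x$rname[mapped]),
    target_start = x$pos[mapped] - 1L,
    target_end = x$pos[mapped] - 1L + refw,
    marker_length = qlen,
    aligned_length = alen,
    mapping_quality = x$mapq[mapped],
    stringency_round = rep(round, sum(mapped)),
    is_secondary = bitwAnd(x$flag[mapped], 256L) > 0L |
      bitwAnd(x$flag[mapped], 2048L) > 0L,
    stringsAsFactors = FALSE)
}

#' Read a set of alignment files
#'
#' @param paths Character vector of SAM paths named
#'   `hits_<genome>_<round>.sam`.
#' @return Row-bound hit table (see [read_alignments()]).
#' @export
read_alignment_set <- function(paths) {
  do.call(rbind, lapply(paths, read_alignments))
}

#' Filter alignment hits by length fraction and mapping quality
#'
#' Keeps hits whose aligned length exceeds `min_len_frac` of the marker
#' length and whose mapping quality exceeds `min_mapq`. Both inequalities
#' are strict: a hit at exactly 60% length or MAPQ 10 is dropped. Records
#' with zero marker length are rejected with a warning.
#'
#' @param hits Hit table from [read_alignments()].
#' @param min_len_frac Minimum aligned-length fraction (default 0.60).
#' @param min_mapq Minimum mapping quality (default 10; MAPQ is
#'   `-10 log10` of the posterior probability the placement is wrong).
#' @return The filtered hit table.
#' @export
filter_hits <- function(hits, min_len_frac = 0.60, min_mapq = 10) {
  zero <- hits$marker_length == 0
  if (any(zero)) {
    warning(sum(zero), " hit(s) with zero marker length rejected")
    hits <- hits[!zero, , drop = FALSE]
  }
  keep <- hits$aligned_length / hits$marker_length > min_len_frac &
    hits$mapping_quality > min_mapq
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge multi-stringency hits to one placement per marker and genome
#'
#' For each (marker, genome) pair, the highest stringency round with any
#' surviving hit wins; within that round the unique highest-MAPQ primary
#' hit is kept. If the top MAPQ is tied between hits at different loci the
#' marker is ambiguous for that genome and is dropped entirely.
#'
#' @param hits Filtered hit table (see [filter_hits()]).
#' @return Hit table with at most one row per (marker, genome).
#' @export
merge_rounds <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  rank <- match(hits$stringency_round, STRINGENCY_ROUNDS)
  key <- paste(hits$marker_id, hits$target_genome, sep = "\r")
  picked <- lapply(split(seq_len(nrow(hits)), key), function(idx) {
    r <- idx[rank[idx] == min(rank[idx])]
    prim <- r[!hits$is_secondary[r]]
    if (length(prim) > 0) r <- prim
    top <- r[hits$mapping_quality[r] == max(hits$mapping_quality[r])]
    loci <- unique(paste(hits$target_chromosome[top],
                         hits$target_start[top]))
    if (length(loci) > 1) return(NULL)  # ambiguous placement
    top[1]
  })
  rows <- unlist(picked[!vapply(picked, is.null, TRUE)], use.names = FALSE)
  out <- hits[sort(rows), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call syntenic (ortho-MQTL) regions for a hotspot
#'
#' Clusters the merged hits of one hotspot's member markers per target
#' genome and chromosome by single linkage at `max_gap_bp`; clusters
#' supported by at least `min_markers` distinct markers become ortho
#' regions.
#'
#' @param hotspot_id Hotspot identifier (copied to the output).
#' @param member_markers Character vector of the hotspot's marker ids.
#' @param merged_hits Hit table from [merge_rounds()].
#' @param min_markers Minimum distinct supporting markers per region
#'   (default 2).
#' @param max_gap_bp Single-linkage gap (default 5e6 bp).
#' @return Data.frame with `hotspot_id`, `target_genome`,
#'   `target_chromosome`, `start`, `end` (0-based half-open, covering all
#'   supporting hits), `n_markers`, and a `supporting_markers` list-column.
#' @export
call_ortho_regions <- function(hotspot_id, member_markers, merged_hits,
                               min_markers = 2L, max_gap_bp = 5e6) {
  empty <- data.frame(hotspot_id = character(), target_genome = character(),
                      target_chromosome = character(), start = numeric(),
                      end = numeric(), n_markers = integer(),
                      stringsAsFactors = FALSE)
  empty$supporting_markers <- list()
  h <- merged_hits[merged_hits$marker_id %in% member_markers, , drop = FALSE]
  if (nrow(h) == 0) return(empty)
  out <- list()
  for (gen in sort(unique(h$target_genome))) {
    for (chr in sort(unique(h$target_chromosome[h$target_genome == gen]))) {
      hh <- h[h$target_genome == gen & h$target_chromosome == chr, ]
      ir <- IRanges::IRanges(start = hh$target_start + 1L,
                             end = hh$target_end)
      red <- IRanges::reduce(ir, min.gapwidth = max_gap_bp + 1,
                             with.revmap = TRUE)
      revmap <- S4Vectors::mcols(red)$revmap
      for (j in seq_along(red)) {
        mk <- unique(hh$marker_id[revmap[[j]]])
        if (length(mk) < min_markers) next
        reg <- data.frame(hotspot_id = hotspot_id, target_genome = gen,
                          target_chromosome = chr,
                          start = IRanges::start(red)[j] - 1L,
                          end = IRanges::end(red)[j],
                          n_markers = length(mk),
                          stringsAsFactors = FALSE)
        reg$supporting_markers <- list(mk)
        out[[length(out) + 1]] <- reg
      }
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-hotspot synteny profile
#'
#' Collapses an ortho-region table into one row per hotspot listing its
#' syntenic target chromosomes.
#'
#' @param regions Row-bound output of [call_ortho_regions()].
#' @return Data.frame with `hotspot_id`, `target_chromosomes` (comma
#'   string, genomes interleaved in sorted order) and `n_regions`.
#' @export
ortho_summary <- function(regions) {
  if (nrow(regions) == 0) {
    return(data.frame(hotspot_id = character(),
                      target_chromosomes = character(),
                      n_regions = integer(), stringsAsFactors = FALSE))
  }
  sp <- split(regions, regions$hotspot_id)
  out <- do.call(rbind, lapply(sp, function(r) {
    data.frame(hotspot_id = r$hotspot_id[1],
               target_chromosomes = paste(sort(unique(r$target_chromosome)),
                                          collapse = ","),
               n_regions = nrow(r), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Genes overlapping an interval
#'
#' Returns the gene models of a GFF3 annotation whose span intersects a
#' query interval (half-open overlap), sorted by start.
#'
#' @param gff Path to a GFF3 file, or a `GRanges` already imported.
#' @param chromosome Chromosome (sequence) name.
#' @param start,end Query interval, 0-based half-open bp.
#' @return Data.frame with `gene_id`, `chromosome`, `start`, `end`
#'   (0-based half-open), `strand`, `description`.
#' @export
genes_in_interval <- function(gff, chromosome, start, end) {
  gr <- if (is.character(gff)) rtracklayer::import(gff, format = "gff3")
        else gff
  gr <- gr[gr$type == "gene"]
  if (!chromosome %in% unique(as.character(GenomicRanges::seqnames(gr)))) {
    warning("chromosome '", chromosome, "' not present in annotation")
    return(data.frame(gene_id = character(), chromosome = character(),
                      start = numeric(), end = numeric(),
                      strand = character(), description = character(),
                      stringsAsFactors = FALSE))
  }
  q <- GenomicRanges::GRanges(chromosome,
                              IRanges::IRanges(start + 1L, end))
  hit <- IRanges::subsetByOverlaps(gr, q)
  hit <- hit[order(GenomicRanges::start(hit))]
  desc <- if (!is.null(hit$description)) as.character(hit$description)
          else rep(NA_character_, length(hit))
  ids <- if (!is.null(hit$ID)) as.character(hit$ID)
         else as.character(hit$Name)
  data.frame(gene_id = ids,
             chromosome = as.character(GenomicRanges::seqnames(hit)),
             start = GenomicRanges::start(hit) - 1L,
             end = GenomicRanges::end(hit),
             strand = as.character(GenomicRanges::strand(hit)),
             description = desc,
             stringsAsFactors = FALSE)
}
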