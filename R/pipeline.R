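# End-to-end orchestration: database -> projection -> overview index ->
# peaks -> hotspots -> breeding selection -> bin distributions ->
# (optional) synteny. Machine-readable outputs are written once per run
# directory; summary.json echoes every threshold actually applied.

drop_list_cols <- function(df) {
  is_list <- vapply(df, is.list, TRUE)
  for (col in names(df)[is_list]) {
    df[[col]] <- vapply(df[[col]], paste, "", collapse = ",")
  }
  df
}

# physical chromosome lengths implied by an anchor table (Mb at the last
# anchor of each chromosome)
physical_lengths <- function(anchors) {
  a <- anchors$anchors
  stats::setNames(
    vapply(split(a$Mb, a$chromosome), max, 0),
    names(split(a$Mb, a$chromosome)))
}

#' Run the full QTL-hotspot pipeline
#'
#' Executes every stage on one input set: validation and descriptive
#' summaries, CI imputation, consensus projection, CI standardization,
#' overview index, thresholding, peak detection at the mean and stringent
#' thresholds, hotspot merging, physical CIs, breeding selection, bin
#' distributions, and (when alignment files are supplied) ortho-region
#' calling. All result tables are written to `output_dir` together with a
#' `summary.json`; a rerun on the same inputs and parameters reproduces
#' the outputs exactly.
#'
#' @param data A list as returned by [simulate_mta_database()] (fields
#'   `studies`, `mta`, `map`, `ld_decay`, `anchors`), or `NULL` to read
#'   from `input_dir`.
#' @param input_dir Directory holding `studies.tsv`, `mta.tsv`, `map.tsv`,
#'   `chrom_lengths.tsv`, `ld_decay.tsv` and `anchors_<ref>.tsv`.
#' @param output_dir Output directory (created).
#' @param merge_gap_cM Peak-run merge gap (cM, default 2).
#' @param high_factor Stringent threshold as a multiple of the mean
#'   (default 5).
#' @param primary_reference Physical reference for breeding selection
#'   (default `"Svevo"`).
#' @param n_bins Bins per chromosome for the distribution comparison
#'   (default 5).
#' @param synteny_dir Optional directory of `hits_<genome>_<round>.sam`
#'   files (plus optional `genes_<genome>.gff3`).
#' @param min_len_frac,min_mapq Alignment filters (defaults 0.60, 10).
#' @param min_markers,max_gap_bp Ortho-region clustering parameters
#'   (defaults 2 and 5e6).
#' @param ... Passed to [breeding_rule()] via [select_breeding()].
#' @return (Invisibly) a list with every intermediate and final table and
#'   the `summary` list mirrored in `summary.json`.
#' @export
run_pipeline <- function(data = NULL, input_dir = NULL, output_dir,
                         merge_gap_cM = 2, high_factor = 5,
                         primary_reference = "Svevo", n_bins = 5L,
                         synteny_dir = NULL, min_len_frac = 0.60,
                         min_mapq = 10, min_markers = 2L,
                         max_gap_bp = 5e6, ...) {
  if (is.null(data)) {
    if (is.null(input_dir)) stop("supply either data or input_dir")
    anchor_files <- list.files(input_dir, "^anchors_.*\\.tsv$",
                               full.names = TRUE)
    data <- list(
      studies = read_studies(file.path(input_dir, "studies.tsv")),
      mta = read_mta(file.path(input_dir, "mta.tsv")),
      map = read_genetic_map(file.path(input_dir, "map.tsv"),
                             file.path(input_dir, "chrom_lengths.tsv"),
                             name = "consensus"),
      ld_decay = read_ld_decay(file.path(input_dir, "ld_decay.tsv")),
      anchors = lapply(anchor_files, read_anchors))
    names(data$anchors) <- vapply(data$anchors,
                                  function(a) a$reference_name, "")
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  db_summary <- summarize_database(data$mta, data$studies)
  projected <- project_mta(impute_ci(data$mta, data$ld_decay), data$map)
  std <- standardize_mta(projected)
  profile <- overview_index(std, data$map)
  mean_thr <- overview_mean_threshold(profile)
  high_thr <- overview_high_threshold(mean_thr, high_factor)
  peaks_mean <- detect_peaks(profile, mean_thr)
  peaks_high <- detect_peaks(profile, high_thr)
  hotspots <- merge_peaks(peaks_high, std, merge_gap_cM = merge_gap_cM)
  hotspots <- hotspot_physical_ci(hotspots, data$anchors)
  hotspots <- select_breeding(hotspots, reference = primary_reference, ...)

  bins_gen <- bin_distribution(hotspots, data$map$chrom_lengths_cM,
                               scale = "genetic", n_bins = n_bins)
  primary <- data$anchors[[match(tolower(primary_reference),
                                 tolower(names(data$anchors)))]]
  bins_phys <- bin_distribution(hotspots, physical_lengths(primary),
                                scale = "physical",
                                reference = primary_reference,
                                n_bins = n_bins)

  ortho_regions <- NULL
  ortho_sum <- NULL
  if (!is.null(synteny_dir)) {
    sams <- list.files(synteny_dir, "^hits_.*\\.sam$", full.names = TRUE)
    hits <- merge_rounds(filter_hits(read_alignment_set(sams),
                                     min_len_frac = min_len_frac,
                                     min_mapq = min_mapq))
    breeding <- hotspots[hotspots$is_breeding, , drop = FALSE]
    reg <- lapply(seq_len(nrow(breeding)), function(i) {
      mk <- data$mta$marker_id[match(breeding$members[[i]],
                                     data$mta$mta_id)]
      call_ortho_regions(breeding$hotspot_id[i], mk[!is.na(mk)], hits,
                         min_markers = min_markers,
                         max_gap_bp = max_gap_bp)
    })
    ortho_regions <- do.call(rbind, reg)
    ortho_sum <- ortho_summary(ortho_regions)
  }

  # outputs
  write_mta(std, file.path(output_dir, "projected_mta.tsv"))
  write_tsv_file(profile, file.path(output_dir, "overview.tsv"))
  write_tsv_file(peaks_high, file.path(output_dir, "peaks.tsv"))
  write_tsv_file(drop_list_cols(hotspots),
                 file.path(output_dir, "hotspots.tsv"))
  write_tsv_file(rbind(bins_gen, bins_phys),
                 file.path(output_dir, "bins.tsv"))
  for (ref in names(data$anchors)) {
    s_col <- paste0("ci_", tolower(ref), "_start_Mb")
    e_col <- paste0("ci_", tolower(ref), "_end_Mb")
    if (!s_col %in% names(hotspots)) next
    bed <- data.frame(chrom = hotspots$chromosome,
                      start = format(round(hotspots[[s_col]] * 1e6),
                                     scientific = FALSE, trim = TRUE),
                      end = format(round(hotspots[[e_col]] * 1e6),
                                   scientific = FALSE, trim = TRUE),
                      name = paste0("qhotspot", hotspots$hotspot_id))
    utils::write.table(bed,
                       file.path(output_dir,
                                 paste0("hotspots_", ref, ".bed")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  if (!is.null(ortho_regions)) {
    write_tsv_file(drop_list_cols(ortho_regions),
                   file.path(output_dir, "ortho_regions.tsv"))
    write_tsv_file(ortho_sum, file.path(output_dir, "ortho_summary.tsv"))
  }

  genome_counts <- table(chromosome_genome(hotspots$chromosome))
  summary <- list(
    n_studies = db_summary$n_studies,
    n_genotypes = db_summary$n_genotypes,
    n_mta = db_summary$n_mta,
    mean_mta_per_chromosome = db_summary$mean_mta_per_chromosome,
    genome_share_pct = as.list(db_summary$genome_share_pct),
    n_ci_missing = db_summary$n_ci_missing,
    ci_histogram = as.list(db_summary$ci_histogram),
    pve_histogram = as.list(db_summary$pve_histogram),
    mean_threshold = mean_thr,
    high_threshold = high_thr,
    n_peaks_mean_threshold = nrow(peaks_mean),
    n_peaks_high_threshold = nrow(peaks_high),
    n_hotspots = nrow(hotspots),
    n_hotspots_per_genome = as.list(genome_counts),
    n_breeding_hotspots = sum(hotspots$is_breeding),
    n_breeding_member_mta = sum(hotspots$n_mta[hotspots$is_breeding]),
    bins = list(genetic = bins_gen, physical = bins_phys),
    ortho = if (!is.null(ortho_regions)) list(
      n_regions = nrow(ortho_regions),
      n_markers_per_genome = as.list(
        tapply(ortho_regions$n_markers, ortho_regions$target_genome, sum)),
      n_markers_total = sum(ortho_regions$n_markers)) else NULL,
    parameters = list(merge_gap_cM = merge_gap_cM,
                      high_factor = high_factor,
                      primary_reference = primary_reference,
                      n_bins = n_bins, min_len_frac = min_len_frac,
                      min_mapq = min_mapq, min_markers = min_markers,
                      max_gap_bp = max_gap_bp))
  jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       dataframe = "columns", na = "null")
  invisible(list(db_summary = db_summary, projected = std,
                 profile = profile, mean_threshold = mean_thr,
                 high_threshold = high_thr, peaks_mean = peaks_mean,
                 peaks_high = peaks_high, hotspots = hotspots,
                 bins = list(genetic = bins_gen, physical = bins_phys),
                 ortho_regions = ortho_regions, ortho_summary = ortho_sum,
                 summary = summary))
}
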