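# Canonical interchange format: headered TSV, '#' lines are comments,
# "NA" denotes missing. All readers/writers round-trip exactly.

read_tsv_file <- function(path, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          na.strings = "NA", stringsAsFactors = FALSE,
                          check.names = FALSE, quote = "")
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0) {
    stop("malformed header in ", basename(path), ": missing column(s) ",
         paste(missing, collapse = ", "))
  }
  df
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

split_codes <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ","), trimws)
}

#' Read a study metadata table
#'
#' Reads the per-study summary of a GWAS compilation: association panel,
#' panel size (number of genotypes), declared number of marker-trait
#' associations and the trait codes analyzed.
#'
#' @param path Path to a TSV file with columns
#'   `study_id`, `panel`, `size`, `n_mta`, `traits` (comma-separated codes).
#' @return A data.frame with those columns plus a `trait_codes` list-column.
#' @export
read_studies <- function(path) {
  df <- read_tsv_file(path, c("study_id", "panel", "size", "n_mta", "traits"))
  if (nrow(df) == 0) {
    df$trait_codes <- list()
    return(df)
  }
  bad <- which(is.na(df$study_id) | is.na(df$size) | is.na(df$n_mta))
  if (length(bad) > 0) {
    stop("malformed study row(s) at line(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(df$study_id)) {
    stop("duplicate study_id: ",
         paste(unique(df$study_id[duplicated(df$study_id)]), collapse = ", "))
  }
  if (any(df$size < 1)) stop("study size must be >= 1")
  if (any(df$n_mta < 0)) stop("n_mta must be non-negative")
  df$trait_codes <- split_codes(df$traits)
  if (any(lengths(df$trait_codes) == 0)) {
    stop("every study must declare at least one trait code")
  }
  df
}

#' Write a study metadata table
#'
#' @param studies Data.frame as returned by [read_studies()].
#' @param path Output TSV path.
#' @export
write_studies <- function(studies, path) {
  out <- studies[, c("study_id", "panel", "size", "n_mta")]
  codes <- if ("trait_codes" %in% names(studies)) {
    vapply(studies$trait_codes, paste, "", collapse = ",")
  } else {
    studies$traits
  }
  out$traits <- codes
  write_tsv_file(out, path)
}

#' Read a marker-trait association (MTA) table
#'
#' One row per MTA: study of origin, trait code, chromosome, genetic
#' position, optional confidence interval (full width, cM), optional
#' proportion of phenotypic variance explained (PVE), optional marker name.
#' Missing CI and PVE are preserved as `NA`, never coerced to zero.
#'
#' @param path Path to a TSV file with columns `mta_id`, `study_id`,
#'   `trait_code`, `chromosome`, `position_cM`, `ci_cM`, `pve`, `marker_id`.
#' @param pve_scale Either `"fraction"` (PVE already in `[0,1]`) or
#'   `"percent"` (values like `6` meaning 6%, divided by 100 on read).
#'   Source GWAS papers differ; PVE is always stored as a fraction.
#' @return A validated data.frame of MTA records.
#' @export
read_mta <- function(path, pve_scale = c("fraction", "percent")) {
  pve_scale <- match.arg(pve_scale)
  df <- read_tsv_file(path, c("mta_id", "study_id", "trait_code",
                              "chromosome", "position_cM", "ci_cM", "pve",
                              "marker_id"))
  for (col in c("mta_id", "study_id", "trait_code", "chromosome",
                "marker_id")) {
    df[[col]] <- as.character(df[[col]])
  }
  if (nrow(df) == 0) return(df)
  if (pve_scale == "percent") df$pve <- df$pve / 100
  validate_mta(df)
}

#' Validate an MTA table
#'
#' Checks chromosome names against the 14 durum chromosomes, positivity of
#' positions and CIs, the PVE range, and `mta_id` uniqueness.
#'
#' @param mta Data.frame of MTA records.
#' @return The input, with chromosomes normalized, invisibly validated.
#' @export
validate_mta <- function(mta) {
  bad <- which(is.na(mta$mta_id) | is.na(mta$chromosome) |
                 is.na(mta$position_cM))
  if (length(bad) > 0) {
    stop("malformed MTA row(s) at line(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(mta$mta_id)) {
    stop("duplicate mta_id: ",
         paste(unique(mta$mta_id[duplicated(mta$mta_id)]), collapse = ", "))
  }
  mta$chromosome <- normalize_chromosome(mta$chromosome)
  if (any(mta$position_cM < 0)) stop("position_cM must be non-negative")
  if (any(!is.na(mta$ci_cM) & mta$ci_cM <= 0)) {
    stop("ci_cM must be positive where present")
  }
  if (any(!is.na(mta$pve) & (mta$pve < 0 | mta$pve > 1))) {
    stop("pve must lie in [0, 1]")
  }
  mta
}

#' Write an MTA table
#'
#' @param mta Data.frame of MTA records.
#' @param path Output TSV path.
#' @export
write_mta <- function(mta, path) {
  cols <- c("mta_id", "study_id", "trait_code", "chromosome", "position_cM",
            "ci_cM", "pve", "marker_id")
  extra <- setdiff(names(mta), cols)
  write_tsv_file(mta[, c(cols, extra)], path)
}

#' Read a genetic map
#'
#' @param path TSV with columns `marker`, `chromosome`, `position_cM`.
#' @param lengths_path Optional TSV with columns `chromosome`, `length_cM`.
#'   When absent, chromosome lengths default to the ceiling of the last
#'   marker position.
#' @param name Map name (free text).
#' @return An object of class `genetic_map`: a list with `name`, `markers`
#'   (data.frame) and `chrom_lengths_cM` (named numeric).
#' @export
read_genetic_map <- function(path, lengths_path = NULL, name = basename(path)) {
  mk <- read_tsv_file(path, c("marker", "chromosome", "position_cM"))
  mk$chromosome <- normalize_chromosome(mk$chromosome)
  if (!is.null(lengths_path)) {
    len <- read_tsv_file(lengths_path, c("chromosome", "length_cM"))
    lengths <- stats::setNames(len$length_cM,
                               normalize_chromosome(len$chromosome))
  } else {
    lengths <- ceiling(tapply(mk$position_cM, mk$chromosome, max))
    lengths <- stats::setNames(as.numeric(lengths), names(lengths))
  }
  genetic_map(mk, lengths, name = name)
}

#' Construct a genetic map object
#'
#' @param markers Data.frame with `marker`, `chromosome`, `position_cM`.
#' @param chrom_lengths_cM Named numeric vector of chromosome lengths (cM).
#' @param name Map name.
#' @return An object of class `genetic_map`.
#' @export
genetic_map <- function(markers, chrom_lengths_cM, name = "map") {
  if (any(chrom_lengths_cM <= 0)) stop("chromosome lengths must be positive")
  over <- markers$position_cM >
    chrom_lengths_cM[markers$chromosome] + 1e-9
  if (any(over)) {
    stop("marker position beyond declared chromosome length: ",
         paste(utils::head(markers$marker[over], 5), collapse = ", "))
  }
  structure(list(name = name, markers = markers,
                 chrom_lengths_cM = chrom_lengths_cM),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("genetic_map '", x$name, "': ", nrow(x$markers), " markers on ",
      length(x$chrom_lengths_cM), " chromosomes, ",
      round(sum(x$chrom_lengths_cM), 1), " cM total\n", sep = "")
  invisible(x)
}

#' Read a per-chromosome LD-decay table
#'
#' The intra-chromosomal linkage-disequilibrium decay distance is used as a
#' surrogate confidence-interval width for MTA whose source study reported
#' none.
#'
#' @param path TSV with columns `chromosome`, `decay_cM`.
#' @return Named numeric vector (cM per chromosome).
#' @export
read_ld_decay <- function(path) {
  df <- read_tsv_file(path, c("chromosome", "decay_cM"))
  if (any(df$decay_cM <= 0)) stop("LD decay distances must be positive")
  stats::setNames(df$decay_cM, normalize_chromosome(df$chromosome))
}

#' Read a genetic-to-physical anchor table
#'
#' Anchors tie consensus-map genetic positions (cM) to physical coordinates
#' (Mb) on one reference assembly; physical positions of arbitrary genetic
#' coordinates are obtained by piecewise-linear interpolation between them.
#'
#' @param path TSV with columns `chromosome`, `marker`, `cM`, `Mb`.
#' @param reference_name Name of the physical reference (e.g. `"Svevo"`,
#'   `"CS"`). Defaults to the file name stripped of `anchors_` and `.tsv`.
#' @return An object of class `anchor_table`.
#' @export
read_anchors <- function(path, reference_name = NULL) {
  if (is.null(reference_name)) {
    reference_name <- sub("^anchors_", "",
                          sub("\\.tsv$", "", basename(path)))
  }
  df <- read_tsv_file(path, c("chromosome", "marker", "cM", "Mb"))
  df$chromosome <- normalize_chromosome(df$chromosome)
  anchor_table(df, reference_name)
}

#' Construct an anchor table object
#'
#' @param anchors Data.frame with `chromosome`, `marker`, `cM`, `Mb`.
#' @param reference_name Name of the physical reference.
#' @return An object of class `anchor_table`.
#' @export
anchor_table <- function(anchors, reference_name) {
  anchors <- anchors[order(match(anchors$chromosome, durum_chromosomes()),
                           anchors$cM), , drop = FALSE]
  rownames(anchors) <- NULL
  for (chr in unique(anchors$chromosome)) {
    a <- anchors[anchors$chromosome == chr, ]
    if (nrow(a) < 2) stop("need >= 2 anchors on chromosome ", chr)
    if (any(diff(a$cM) <= 0)) {
      stop("anchor cM positions must be strictly increasing on ", chr)
    }
    if (any(a$Mb < 0)) stop("anchor Mb positions must be non-negative")
  }
  structure(list(reference_name = reference_name, anchors = anchors),
            class = "anchor_table")
}

#' Read a trait dictionary
#'
#' @param path TSV with columns `code`, `description`. Codes may repeat with
#'   distinct descriptions (e.g. several flavors of yellow-pigment scoring
#'   all coded YPC); every (code, description) entry counts.
#' @return Data.frame with columns `code`, `description`.
#' @export
read_trait_dictionary <- function(path) {
  read_tsv_file(path, c("code", "description"))
}

#' Number of entries in a trait dictionary
#'
#' @param dict Data.frame from [read_trait_dictionary()].
#' @return Integer count of (code, description) entries.
#' @export
count_trait_entries <- function(dict) {
  nrow(dict)
}

#' Descriptive summaries of an MTA database
#'
#' Computes the descriptive statistics usually reported for a GWAS
#' compilation: MTA counts per chromosome and subgenome, trait shares,
#' confidence-interval and PVE histograms, and missing-CI counts.
#'
#' @param mta Data.frame of MTA records (validated).
#' @param studies Optional data.frame of studies, to include genotype and
#'   study totals.
#' @return A list of summary tables; see Details.
#' @details
#' The CI histogram uses the conventional bins `<=5`, `(5,10]` and `>10` cM
#' over records with an observed CI; the PVE histogram uses `<0.1`,
#' `[0.1,0.2)` and `>=0.2` over records with an observed PVE. The mean
#' MTA-per-chromosome figure divides the total by all 14 durum chromosomes.
#' @export
summarize_database <- function(mta, studies = NULL) {
  chroms <- durum_chromosomes()
  n <- nrow(mta)
  per_chrom <- data.frame(
    chromosome = chroms,
    n_mta = as.integer(vapply(chroms, function(ch) sum(mta$chromosome == ch),
                              0L)),
    stringsAsFactors = FALSE)
  genome <- chromosome_genome(mta$chromosome)
  genome_share <- c(A = 0, B = 0)
  if (n > 0) {
    genome_share <- 100 * c(A = sum(genome == "A"), B = sum(genome == "B")) / n
  }
  if (n > 0) {
    per_trait <- as.data.frame(table(trait_code = mta$trait_code),
                               stringsAsFactors = FALSE)
    names(per_trait)[2] <- "n_mta"
    per_trait$share <- per_trait$n_mta / n
    per_trait <- per_trait[order(-per_trait$n_mta), , drop = FALSE]
    rownames(per_trait) <- NULL
  } else {
    per_trait <- data.frame(trait_code = character(), n_mta = integer(),
                            share = numeric(), stringsAsFactors = FALSE)
  }
  ci <- mta$ci_cM[!is.na(mta$ci_cM)]
  ci_hist <- c(le_5 = sum(ci <= 5), le_10 = sum(ci <= 10),
               gt_10 = sum(ci > 10))
  pve <- mta$pve[!is.na(mta$pve)]
  pve_hist <- c(lt_0.1 = sum(pve < 0.1), lt_0.2 = sum(pve < 0.2),
                ge_0.2 = sum(pve >= 0.2))
  out <- list(
    n_mta = n,
    per_chromosome = per_chrom,
    mean_mta_per_chromosome = n / length(chroms),
    genome_share_pct = genome_share,
    per_trait = per_trait,
    ci_histogram = ci_hist,
    n_ci_observed = length(ci),
    n_ci_missing = sum(is.na(mta$ci_cM)),
    pve_histogram = pve_hist,
    n_pve_observed = length(pve))
  if (!is.null(studies)) {
    out$n_studies <- nrow(studies)
    out$n_genotypes <- sum(studies$size)
    out$n_mta_declared <- sum(studies$n_mta)
  }
  out
}
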