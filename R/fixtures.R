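# Curated summary tables of the published durum wheat quality GWAS
# compilation, shipped as plain TSV under inst/extdata. They provide
# desk-scale reference inputs for examples and validation of the
# breeding-selection and synteny-summary rules.

qh_extdata <- function(file) {
  path <- system.file("extdata", file, package = "qtlhotspots")
  if (path == "") stop("fixture not found: ", file)
  path
}

#' Reference table: the ten durum quality GWAS
#'
#' Study metadata for the ten published durum wheat quality GWAS that the
#' hotspot meta-analysis compiles: panel, panel size, number of declared
#' MTA and trait codes. Panel sizes sum to 1,598 genotypes and declared MTA
#' to 395.
#'
#' @return Data.frame as returned by [read_studies()].
#' @export
durum_studies <- function() {
  read_studies(qh_extdata("durum_studies.tsv"))
}

#' Reference table: trait dictionary
#'
#' The 57 (code, description) trait entries of the durum quality
#' compilation. Codes may repeat with distinct descriptions.
#'
#' @return Data.frame as returned by [read_trait_dictionary()].
#' @export
durum_trait_dictionary <- function() {
  read_trait_dictionary(qh_extdata("durum_traits.tsv"))
}

#' Reference table: selected breeding QTL hotspots
#'
#' The 20 selected breeding hotspots of the durum quality meta-analysis,
#' with genetic CIs on the consensus map and physical CIs on the Svevo and
#' Chinese Spring assemblies, member-MTA counts, and mean PVE.
#'
#' @return Data.frame with one row per hotspot.
#' @export
durum_breeding_hotspots <- function() {
  df <- read_tsv_file(qh_extdata("durum_breeding_hotspots.tsv"),
                      c("hotspot_id", "chromosome", "ci_start_cM",
                        "ci_end_cM", "ci_svevo_start_Mb", "ci_svevo_end_Mb",
                        "ci_cs_start_Mb", "ci_cs_end_Mb", "n_mta",
                        "pve_mean", "traits"))
  df$chromosome <- normalize_chromosome(df$chromosome)
  df
}

#' Reference table: per-hotspot syntenic chromosomes
#'
#' Target chromosomes (Brachypodium `bd*`, rice `os*`, maize `zm*`) with
#' syntenic support for each breeding hotspot.
#'
#' @return Data.frame with `hotspot_id`, `chromosome`, `target_chromosomes`
#'   (comma string) and a `targets` list-column.
#' @export
durum_synteny_summary <- function() {
  df <- read_tsv_file(qh_extdata("durum_synteny_summary.tsv"),
                      c("hotspot_id", "chromosome", "target_chromosomes"))
  df$chromosome <- normalize_chromosome(df$chromosome)
  df$targets <- split_codes(df$target_chromosomes)
  df
}
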