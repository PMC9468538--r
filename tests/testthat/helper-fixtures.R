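# In-code fixtures shared across the suite.

# minimal MTA table; defaults give one interior record per chromosome given
make_mta <- function(chromosome, position_cM, ci_cM = 3.92, pve = 0.05,
                     study_id = "s01", trait_code = "YPC",
                     marker_id = NA_character_) {
  n <- length(position_cM)
  data.frame(
    mta_id = sprintf("m%03d", seq_len(n)),
    study_id = rep_len(study_id, n),
    trait_code = rep_len(trait_code, n),
    chromosome = rep_len(chromosome, n),
    position_cM = position_cM,
    ci_cM = rep_len(ci_cM, n),
    pve = rep_len(pve, n),
    marker_id = rep_len(marker_id, n),
    stringsAsFactors = FALSE)
}

# one-chromosome map with no markers needed beyond the length
tiny_map <- function(chromosome = "1A", length_cM = 100) {
  genetic_map(
    data.frame(marker = c("a", "b"), chromosome = chromosome,
               position_cM = c(0, length_cM), stringsAsFactors = FALSE),
    stats::setNames(length_cM, chromosome), name = "tiny")
}

# independent numerical-integration oracle for the per-bin Gaussian mass:
# Riemann sum of the normal density on a fine grid, no pnorm involved
oracle_bin_mass <- function(mu, s, n_bins, dx = 1e-3) {
  vapply(seq_len(n_bins) - 1, function(k) {
    grid <- seq(k + dx / 2, k + 1 - dx / 2, by = dx)
    sum(vapply(seq_along(mu), function(i) {
      sum(stats::dnorm(grid, mu[i], s[i])) * dx
    }, 0))
  }, 0)
}

# hand-rolled alignment-hit rows for filter/merge rule tests
make_hit <- function(marker_id, genome = "bd", chrom = "bd1", start = 1000L,
                     marker_length = 100L, aligned_length = 90L,
                     mapq = 40L, round = "high", secondary = FALSE) {
  data.frame(marker_id = marker_id, target_genome = genome,
             target_chromosome = chrom, target_start = start,
             target_end = start + aligned_length,
             marker_length = marker_length,
             aligned_length = aligned_length, mapping_quality = mapq,
             stringency_round = round, is_secondary = secondary,
             stringsAsFactors = FALSE)
}
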