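# Synthetic-data generator: produces a complete, ground-truth-annotated
# input set (studies, MTA, consensus map, LD decay, anchors, alignments,
# annotation) so that every pipeline stage is testable without any
# external download. Distributions are calibrated to the descriptive
# statistics of the durum quality compilation: CI quantiles (83% <= 5 cM,
# 97% <= 10 cM), PVE quantiles (79% < 0.1, 95% < 0.2), 203/395 missing
# CIs, trait shares (YPC 24%), and telomere-enriched physical positions.

#' Fit a log-normal to two CI quantiles
#'
#' Solves exactly for the log-normal whose CDF passes through two stated
#' quantile points (default: 83% at 5 cM, 97% at 10 cM).
#'
#' @param q1,p1 First quantile point (value, probability).
#' @param q2,p2 Second quantile point.
#' @return List with `meanlog`, `sdlog` and the implied `mean`.
#' @export
fit_ci_lognormal <- function(q1 = 5, p1 = 0.83, q2 = 10, p2 = 0.97) {
  z1 <- stats::qnorm(p1); z2 <- stats::qnorm(p2)
  sdlog <- (log(q2) - log(q1)) / (z2 - z1)
  if (sdlog <= 0) stop("inconsistent CI quantile targets")
  meanlog <- log(q1) - sdlog * z1
  list(meanlog = meanlog, sdlog = sdlog,
       mean = exp(meanlog + sdlog^2 / 2))
}

#' Fit a Beta to two PVE quantiles
#'
#' Least-squares fit of a Beta CDF through two stated quantile points
#' (default: 79% below 0.1, 95% below 0.2). Deterministic (Nelder-Mead
#' from a fixed start).
#'
#' @param q1,p1 First quantile point.
#' @param q2,p2 Second quantile point.
#' @return List with `shape1`, `shape2`.
#' @export
fit_pve_beta <- function(q1 = 0.1, p1 = 0.79, q2 = 0.2, p2 = 0.95) {
  obj <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    (stats::pbeta(q1, a, b) - p1)^2 + (stats::pbeta(q2, a, b) - p2)^2
  }
  fit <- stats::optim(c(0, log(15)), obj)
  if (fit$value > 1e-4) stop("PVE quantile targets cannot be met by a Beta")
  list(shape1 = exp(fit$par[1]), shape2 = exp(fit$par[2]))
}

default_chrom_lengths_cM <- function() {
  stats::setNames(
    c(170, 180, 200, 210, 190, 200, 180, 160, 190, 180, 170, 180, 220, 200),
    durum_chromosomes())
}

default_chrom_lengths_Mb <- function(reference = c("Svevo", "CS")) {
  reference <- match.arg(reference)
  sv <- stats::setNames(
    c(594, 689, 780, 801, 754, 830, 744, 673, 709, 713, 618, 731, 737, 750),
    durum_chromosomes())
  if (reference == "Svevo") sv else round(sv * 1.03)
}

default_ld_decay <- function() {
  stats::setNames(
    c(2.5, 3.0, 3.5, 4.0, 2.8, 3.2, 3.8, 4.2, 2.6, 3.4, 3.6, 4.4, 3.1, 2.9),
    durum_chromosomes())
}

default_trait_frequencies <- function() {
  c(YPC = 0.24, GPC = 0.08, GS = 0.06, PLOSS = 0.05, CWT = 0.04,
    FIRM = 0.04, Color = 0.04, DOE = 0.03, DEE = 0.03, "b*" = 0.03,
    dif = 0.03, SV = 0.03, MIXO = 0.02, WG = 0.02, VIT = 0.02, AX = 0.02,
    BG = 0.02, TW = 0.02, IP = 0.02, GLUT = 0.02, "a*" = 0.02,
    "L*" = 0.02, GL = 0.02, GW = 0.02, Gli = 0.02, TPT = 0.02, PPO = 0.02)
}

#' Generator configuration
#'
#' Bundles every tunable of the synthetic-data generator with defaults
#' calibrated to the durum quality compilation: 10 studies, 395 MTA on a
#' 14-chromosome consensus map of 2,630 cM, CI distribution hitting the
#' 83%/97% quantile targets with 203/395 CIs missing, PVE hitting the
#' 79%/95% targets, YPC carrying 24% of MTA, and a sigmoidal cM-Mb
#' relation (recombination suppressed mid-chromosome) that makes
#' genetically uniform positions physically telomere-enriched.
#'
#' @param seed Integer seed; mandatory for reproducibility.
#' @param n_studies,n_mta Database size.
#' @param chrom_lengths_cM Named numeric, consensus genetic lengths.
#' @param chrom_lengths_Mb_svevo,chrom_lengths_Mb_cs Physical lengths per
#'   reference.
#' @param n_planted_hotspots Number of planted MTA clusters.
#' @param hotspot_sd_cM Positional sd of cluster members around their
#'   planted center (cM).
#' @param clustered_fraction Fraction of MTA belonging to planted clusters
#'   (the rest is uniform background).
#' @param fraction_ci_missing Share of MTA whose CI is withheld (default
#'   203/395).
#' @param ci_quantiles,pve_quantiles Calibration targets, as
#'   `c(value1, prob1, value2, prob2)`.
#' @param ci_range CI truncation range (cM).
#' @param trait_frequencies Named probabilities of trait codes.
#' @param telomere_skew Steepness of the tanh cM-Mb sigmoid (higher =
#'   stronger telomeric compression; default 8).
#' @param ld_decay Named per-chromosome LD-decay distances (cM).
#' @param study_sizes Panel sizes of the generated studies.
#' @param study_weights Relative expected MTA counts per study.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed,
                             n_studies = 10L,
                             n_mta = 395L,
                             chrom_lengths_cM = default_chrom_lengths_cM(),
                             chrom_lengths_Mb_svevo = default_chrom_lengths_Mb("Svevo"),
                             chrom_lengths_Mb_cs = default_chrom_lengths_Mb("CS"),
                             n_planted_hotspots = 20L,
                             hotspot_sd_cM = 1.5,
                             clustered_fraction = 0.8,
                             fraction_ci_missing = 203 / 395,
                             ci_quantiles = c(5, 0.83, 10, 0.97),
                             ci_range = c(0.1, 43),
                             pve_quantiles = c(0.1, 0.79, 0.2, 0.95),
                             trait_frequencies = default_trait_frequencies(),
                             telomere_skew = 8,
                             ld_decay = default_ld_decay(),
                             study_sizes = c(104, 230, 124, 93, 172, 243,
                                             79, 192, 192, 169),
                             study_weights = c(19, 7, 6, 20, 14, 163, 44,
                                               20, 80, 22)) {
  if (missing(seed)) stop("a seed is mandatory")
  fracs <- c(clustered_fraction, fraction_ci_missing)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  ci_fit <- fit_ci_lognormal(ci_quantiles[1], ci_quantiles[2],
                             ci_quantiles[3], ci_quantiles[4])
  pve_fit <- fit_pve_beta(pve_quantiles[1], pve_quantiles[2],
                          pve_quantiles[3], pve_quantiles[4])
  structure(list(
    seed = as.integer(seed), n_studies = n_studies, n_mta = n_mta,
    chrom_lengths_cM = chrom_lengths_cM,
    chrom_lengths_Mb_svevo = chrom_lengths_Mb_svevo,
    chrom_lengths_Mb_cs = chrom_lengths_Mb_cs,
    n_planted_hotspots = n_planted_hotspots,
    hotspot_sd_cM = hotspot_sd_cM,
    clustered_fraction = clustered_fraction,
    fraction_ci_missing = fraction_ci_missing,
    ci_fit = ci_fit, ci_range = ci_range, pve_fit = pve_fit,
    trait_frequencies = trait_frequencies / sum(trait_frequencies),
    telomere_skew = telomere_skew, ld_decay = ld_decay,
    study_sizes = study_sizes,
    study_weights = study_weights / sum(study_weights)),
    class = "generator_config")
}

# monotone sigmoid mapping relative genetic position to relative physical
# position: steep mid-chromosome (recombination suppression), flat at the
# telomeres, f(0)=0, f(1)=1
cm_mb_sigmoid <- function(x, k) {
  0.5 * (1 + tanh(k * (x - 0.5)) / tanh(k / 2))
}

build_anchor_table <- function(chrom_lengths_cM, chrom_lengths_Mb, k,
                               reference_name, n_anchors = 21L) {
  rows <- lapply(names(chrom_lengths_cM), function(chr) {
    L <- chrom_lengths_cM[[chr]]
    cm <- seq(0, L, length.out = n_anchors)
    data.frame(chromosome = chr,
               marker = sprintf("anc_%s_%02d", chr, seq_len(n_anchors)),
               cM = cm,
               Mb = chrom_lengths_Mb[[chr]] * cm_mb_sigmoid(cm / L, k),
               stringsAsFactors = FALSE)
  })
  anchor_table(do.call(rbind, rows), reference_name)
}

# planted cluster centers: uniform in [margin, L - margin], >= min_sep
# apart on the same chromosome; chromosomes sampled in proportion to length
plant_centers <- function(n, chrom_lengths, margin = 10, min_sep = 30) {
  chroms <- names(chrom_lengths)
  out <- data.frame(chromosome = character(), center_cM = numeric(),
                    stringsAsFactors = FALSE)
  tries <- 0
  while (nrow(out) < n) {
    tries <- tries + 1
    if (tries > 1000 * n) stop("cannot place planted hotspots: relax margins")
    chr <- sample(chroms, 1, prob = chrom_lengths)
    pos <- stats::runif(1, margin, chrom_lengths[[chr]] - margin)
    same <- out$center_cM[out$chromosome == chr]
    if (all(abs(same - pos) >= min_sep)) {
      out <- rbind(out, data.frame(chromosome = chr, center_cM = pos,
                                   stringsAsFactors = FALSE))
    }
  }
  out <- out[order(match(out$chromosome, durum_chromosomes()),
                   out$center_cM), ]
  out$planted_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Generate a synthetic MTA database
#'
#' Draws a complete input set for the pipeline: study table, MTA table
#' (mixture of planted Gaussian clusters and uniform background), the
#' consensus map with chromosome lengths, per-chromosome LD decay, and
#' genetic-physical anchor tables for two references. The same seed
#' produces byte-identical files.
#'
#' @param config A [generator_config()].
#' @param dir Optional output directory; when given, all tables are
#'   written as TSV (plus `ground_truth.json`) and the paths returned in
#'   the result.
#' @return A list with `studies`, `mta`, `map` (a [genetic_map()]),
#'   `ld_decay`, `anchors` (list of two [anchor_table()]s),
#'   `ground_truth` (planted centers and per-MTA membership) and `config`.
#' @export
simulate_mta_database <- function(config, dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  lens <- config$chrom_lengths_cM
  n <- config$n_mta

  # consensus map scaffold: one marker every ~2 cM
  markers <- do.call(rbind, lapply(names(lens), function(chr) {
    pos <- seq(0, lens[[chr]], by = 2)
    data.frame(marker = sprintf("cons_%s_%03d", chr, seq_along(pos)),
               chromosome = chr, position_cM = pos,
               stringsAsFactors = FALSE)
  }))
  map <- genetic_map(markers, lens, name = "consensus")

  centers <- plant_centers(config$n_planted_hotspots, lens)
  n_clustered <- round(config$clustered_fraction * n)
  base <- 5L  # guaranteed minimum support per planted cluster
  if (n_clustered < base * nrow(centers)) {
    stop("clustered_fraction too small for ", nrow(centers),
         " planted hotspots")
  }
  extra <- stats::rmultinom(1, n_clustered - base * nrow(centers),
                            rep(1, nrow(centers)))[, 1]
  sizes <- base + extra
  member_of <- c(rep(centers$planted_id, sizes),
                 rep(NA_integer_, n - n_clustered))
  chrom <- character(n)
  pos <- numeric(n)
  clustered <- !is.na(member_of)
  chrom[clustered] <- centers$chromosome[member_of[clustered]]
  pos[clustered] <- stats::rnorm(sum(clustered),
                                 centers$center_cM[member_of[clustered]],
                                 config$hotspot_sd_cM)
  bg <- which(!clustered)
  chrom[bg] <- sample(names(lens), length(bg), replace = TRUE, prob = lens)
  pos[bg] <- stats::runif(length(bg), 0, lens[chrom[bg]])
  pos <- pmin(pmax(pos, 0), lens[chrom])

  ci <- stats::rlnorm(n, config$ci_fit$meanlog, config$ci_fit$sdlog)
  ci <- pmin(pmax(ci, config$ci_range[1]), config$ci_range[2])
  n_missing <- round(config$fraction_ci_missing * n)
  ci[sample.int(n, n_missing)] <- NA_real_
  pve <- stats::rbeta(n, config$pve_fit$shape1, config$pve_fit$shape2)

  trait <- sample(names(config$trait_frequencies), n, replace = TRUE,
                  prob = config$trait_frequencies)
  study_ids <- sprintf("s%02d", seq_len(config$n_studies))
  study <- sample(study_ids, n, replace = TRUE, prob = config$study_weights)

  ord <- order(match(chrom, durum_chromosomes()), pos)
  mta <- data.frame(
    mta_id = sprintf("mta%04d", seq_len(n)),
    study_id = study[ord], trait_code = trait[ord],
    chromosome = chrom[ord], position_cM = round(pos[ord], 4),
    ci_cM = round(ci[ord], 4), pve = round(pve[ord], 4),
    marker_id = sprintf("mrk%04d", seq_len(n)),
    stringsAsFactors = FALSE)
  membership <- data.frame(mta_id = mta$mta_id,
                           planted_id = member_of[ord],
                           stringsAsFactors = FALSE)

  counts <- table(factor(mta$study_id, levels = study_ids))
  studies <- data.frame(
    study_id = study_ids,
    panel = sprintf("synthetic panel %02d", seq_len(config$n_studies)),
    size = config$study_sizes[seq_len(config$n_studies)],
    n_mta = as.integer(counts),
    traits = vapply(study_ids, function(s) {
      paste(sort(unique(mta$trait_code[mta$study_id == s])), collapse = ",")
    }, ""),
    stringsAsFactors = FALSE)
  studies$trait_codes <- split_codes(studies$traits)

  anchors <- list(
    Svevo = build_anchor_table(lens, config$chrom_lengths_Mb_svevo,
                               config$telomere_skew, "Svevo"),
    CS = build_anchor_table(lens, config$chrom_lengths_Mb_cs,
                            config$telomere_skew, "CS"))
  centers$n_planted <- as.integer(sizes)
  truth <- list(planted = centers, membership = membership)

  out <- list(studies = studies, mta = mta, map = map,
              ld_decay = config$ld_decay, anchors = anchors,
              ground_truth = truth, config = config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_studies(studies, file.path(dir, "studies.tsv"))
    write_mta(mta, file.path(dir, "mta.tsv"))
    write_tsv_file(map$markers, file.path(dir, "map.tsv"))
    write_tsv_file(data.frame(chromosome = names(lens),
                              length_cM = unname(lens)),
                   file.path(dir, "chrom_lengths.tsv"))
    write_tsv_file(data.frame(chromosome = names(config$ld_decay),
                              decay_cM = unname(config$ld_decay)),
                   file.path(dir, "ld_decay.tsv"))
    for (ref in names(anchors)) {
      write_tsv_file(anchors[[ref]]$anchors,
                     file.path(dir, paste0("anchors_", ref, ".tsv")))
    }
    jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                         dataframe = "columns", na = "null", digits = 8)
    out$dir <- dir
  }
  out
}

#' Compare called hotspots against the planted ground truth
#'
#' A planted cluster counts as recovered when some called hotspot CI
#' overlaps its `center +/- 3 sd` extent (sensitivity = recovered fraction
#' of planted clusters). Precision is judged over the calls that qualify
#' as clusters — at least `min_support` member MTAs, the conventional
#' minimum for a meta-QTL — since a single precisely-located MTA can
#' legitimately exceed the density threshold without being a cluster; a
#' qualifying call is a true positive when it overlaps some planted
#' extent.
#'
#' @param hotspots Hotspot table from [merge_peaks()].
#' @param truth Ground truth from [simulate_mta_database()].
#' @param sd_cM Planted cluster sd used for the extent (default 1.5).
#' @param min_support Minimum member count for a call to enter the
#'   precision denominator (default 3).
#' @return List with `sensitivity`, `precision`, `n_called`, `n_planted`.
#' @export
planted_recovery <- function(hotspots, truth, sd_cM = 1.5,
                             min_support = 3L) {
  planted <- truth$planted
  ext_lo <- planted$center_cM - 3 * sd_cM
  ext_hi <- planted$center_cM + 3 * sd_cM
  recovered <- vapply(seq_len(nrow(planted)), function(i) {
    same <- hotspots$chromosome == planted$chromosome[i]
    any(same & hotspots$ci_end_cM >= ext_lo[i] &
          hotspots$ci_start_cM <= ext_hi[i])
  }, TRUE)
  calls <- which(hotspots$n_mta >= min_support)
  tp <- vapply(calls, function(j) {
    same <- planted$chromosome == hotspots$chromosome[j]
    any(same & ext_hi >= hotspots$ci_start_cM[j] &
          ext_lo <= hotspots$ci_end_cM[j])
  }, TRUE)
  list(sensitivity = mean(recovered),
       precision = if (length(calls)) mean(tp) else NA_real_,
       n_called = nrow(hotspots), n_planted = nrow(planted))
}
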