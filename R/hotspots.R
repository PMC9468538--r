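# The overview density index: each projected MTA contributes a Gaussian
# positional distribution with sd s = CI/3.92 (a 95% interval spans
# 2 * 1.96 sd), and u(bin) sums the probability mass the MTAs place in
# each 1-cM bin [k, k+1). Gaussian tails are truncated at chromosome ends
# without renormalization.

#' Standardize MTA confidence intervals
#'
#' Converts each MTA's 95% confidence-interval width into the standard
#' deviation of a Gaussian positional uncertainty, `s = CI / 3.92`
#' (3.92 = 2 x 1.96), and its variance `s_squared`.
#'
#' @param mta Data.frame of projected MTA records with complete, positive
#'   `ci_cM`.
#' @return The input with columns `s` and `s_squared` appended.
#' @export
standardize_mta <- function(mta) {
  if (any(is.na(mta$ci_cM)) || any(mta$ci_cM <= 0)) {
    stop("all MTA must carry a positive CI before standardization ",
         "(run impute_ci first)")
  }
  mta$s <- mta$ci_cM / 3.92
  mta$s_squared <- mta$s^2
  mta
}

#' Per-centimorgan QTL overview density index
#'
#' For every 1-cM bin `[k, k+1)` of every chromosome, sums over the MTAs of
#' that chromosome the probability mass of their standardized Gaussian
#' positional distribution falling in the bin:
#' `u(k) = sum_i Phi((k+1-mu_i)/s_i) - Phi((k-mu_i)/s_i)`.
#' Each MTA contributes total mass at most 1; mass beyond the chromosome
#' ends is truncated, not renormalized.
#'
#' @param mta Standardized MTA data.frame (see [standardize_mta()]).
#' @param map A [genetic_map()]; bins span `0 .. ceiling(length)` per
#'   chromosome.
#' @return Data.frame with columns `chromosome`, `bin_start` (cM, the bin
#'   covers `[bin_start, bin_start + 1)`) and `u`.
#' @export
overview_index <- function(mta, map) {
  if (!all(c("s") %in% names(mta))) {
    stop("MTA must be standardized (standardize_mta) first")
  }
  lengths <- map$chrom_lengths_cM
  absent <- setdiff(unique(mta$chromosome), names(lengths))
  if (length(absent) > 0) {
    stop("MTA on chromosome(s) absent from the map: ",
         paste(absent, collapse = ", "))
  }
  chroms <- names(lengths)[chromosome_order(names(lengths))]
  out <- lapply(chroms, function(chr) {
    nb <- ceiling(lengths[[chr]])
    edges <- 0:nb
    rows <- mta$chromosome == chr
    u <- numeric(nb)
    if (any(rows)) {
      mu <- mta$position_cM[rows]
      s <- mta$s[rows]
      p <- stats::pnorm(outer(edges, mu, "-") / rep(s, each = nb + 1))
      u <- rowSums(p[-1, , drop = FALSE] - p[-(nb + 1), , drop = FALSE])
    }
    data.frame(chromosome = chr, bin_start = 0:(nb - 1), u = u,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Overview-index thresholds
#'
#' `overview_mean_threshold()` is the arithmetic mean of the overview index
#' over every bin of every chromosome — the base hotspot threshold.
#' `overview_high_threshold()` is a fixed multiple of it (5 by default),
#' the stringent threshold used to call hotspots.
#'
#' @param profile Overview profile from [overview_index()].
#' @return A single numeric threshold.
#' @export
overview_mean_threshold <- function(profile) {
  if (is.null(profile) || nrow(profile) == 0) {
    stop("empty overview profile")
  }
  mean(profile$u)
}

#' @rdname overview_mean_threshold
#' @param mean_threshold Value returned by [overview_mean_threshold()].
#' @param factor Multiplier for the stringent threshold (default 5).
#' @export
overview_high_threshold <- function(mean_threshold, factor = 5) {
  factor * mean_threshold
}

# leftmost bins of the local-maximum plateaus of v (run-interior rule:
# boundaries count as -Inf neighbours is NOT used; a run edge can be a peak)
plateau_peaks <- function(v) {
  r <- rle(v)
  k <- length(r$values)
  starts <- cumsum(c(1L, r$lengths[-k]))
  left <- c(-Inf, r$values[-k])
  right <- c(r$values[-1], -Inf)
  starts[r$values > left & r$values > right]
}

#' Detect supra-threshold peaks of the overview profile
#'
#' A peak is a local maximum of `u` restricted to bins with
#' `u >= threshold`; a plateau of equal values yields one peak at its
#' leftmost bin. Each peak carries its contiguous supra-threshold run.
#'
#' @param profile Overview profile from [overview_index()].
#' @param threshold Positive threshold on `u`.
#' @return Data.frame with `chromosome`, `peak_bin` (bin start, cM), `u`,
#'   and the run interval `run_start`, `run_end` (inclusive bin starts).
#' @export
detect_peaks <- function(profile, threshold) {
  stopifnot(threshold > 0)
  res <- lapply(split(profile, profile$chromosome), function(pr) {
    pr <- pr[order(pr$bin_start), ]
    above <- pr$u >= threshold
    if (!any(above)) return(NULL)
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- which(runs$values)
    out <- lapply(keep, function(j) {
      i1 <- starts[j]; i2 <- ends[j]
      pk <- plateau_peaks(pr$u[i1:i2]) + i1 - 1L
      data.frame(chromosome = pr$chromosome[1],
                 peak_bin = pr$bin_start[pk],
                 u = pr$u[pk],
                 run_start = pr$bin_start[i1],
                 run_end = pr$bin_start[i2],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
  res <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(res)) {
    res <- data.frame(chromosome = character(), peak_bin = numeric(),
                      u = numeric(), run_start = numeric(),
                      run_end = numeric(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res[chromosome_order(res$chromosome), , drop = FALSE]
}

#' Merge supra-threshold peaks into QTL hotspots
#'
#' Peaks whose supra-threshold runs touch, overlap, or are separated by at
#' most `merge_gap_cM` are merged into one hotspot. The hotspot genetic CI
#' is the `[min, max]` span of the merged runs; its members are the MTAs
#' whose own CI interval (`position +/- ci/2`) overlaps the hotspot CI.
#' Hotspots are numbered left-to-right per chromosome, sequentially
#' genome-wide.
#'
#' @param peaks Peaks from [detect_peaks()] (at the stringent threshold).
#' @param mta Standardized, projected MTA data.frame.
#' @param merge_gap_cM Maximum gap (cM) between runs that still merges
#'   (default 2).
#' @return Data.frame with one row per hotspot: `hotspot_id`,
#'   `chromosome`, `ci_start_cM`, `ci_end_cM`, `n_mta`, `pve_mean`,
#'   `max_u`, `traits` (comma string) and a `members` list-column of MTA
#'   ids. `pve_mean` averages members with observed PVE only.
#' @export
merge_peaks <- function(peaks, mta, merge_gap_cM = 2) {
  empty <- data.frame(hotspot_id = integer(), chromosome = character(),
                      ci_start_cM = numeric(), ci_end_cM = numeric(),
                      n_mta = integer(), pve_mean = numeric(),
                      max_u = numeric(), traits = character(),
                      stringsAsFactors = FALSE)
  empty$members <- list()
  if (nrow(peaks) == 0) return(empty)
  out <- list()
  for (chr in unique(peaks$chromosome)) {
    pk <- peaks[peaks$chromosome == chr, ]
    runs <- unique(pk[, c("run_start", "run_end")])
    runs <- runs[order(runs$run_start), , drop = FALSE]
    # single-linkage merge of runs along the chromosome
    grp <- cumsum(c(1, as.integer(
      runs$run_start[-1] - (runs$run_end[-nrow(runs)] + 1) > merge_gap_cM)))
    for (g in unique(grp)) {
      r <- runs[grp == g, , drop = FALSE]
      ci_start <- min(r$run_start)
      ci_end <- max(r$run_end) + 1  # runs are bins [k, k+1)
      on_chr <- mta$chromosome == chr
      lo <- mta$position_cM - mta$ci_cM / 2
      hi <- mta$position_cM + mta$ci_cM / 2
      member <- on_chr & hi >= ci_start & lo <= ci_end
      ids <- mta$mta_id[member]
      pve <- mta$pve[member]
      pve <- pve[!is.na(pve)]
      in_span <- pk$peak_bin >= ci_start - 1e-9 & pk$peak_bin <= ci_end
      h <- data.frame(hotspot_id = NA_integer_, chromosome = chr,
                      ci_start_cM = ci_start, ci_end_cM = ci_end,
                      n_mta = length(ids),
                      pve_mean = if (length(pve)) mean(pve) else NA_real_,
                      max_u = max(pk$u[in_span]),
                      traits = paste(sort(unique(mta$trait_code[member])),
                                     collapse = ","),
                      stringsAsFactors = FALSE)
      h$members <- list(ids)
      out[[length(out) + 1]] <- h
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$chromosome, durum_chromosomes()),
                   res$ci_start_cM), , drop = FALSE]
  res$hotspot_id <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Attach physical CIs to hotspots
#'
#' Interpolates each hotspot's genetic CI endpoints to physical
#' coordinates on one or more reference assemblies (see
#' [genetic_to_physical()]). Adds columns
#' `ci_<reference>_start_Mb` / `ci_<reference>_end_Mb` per reference, with
#' endpoints ordered so start <= end.
#'
#' @param hotspots Data.frame from [merge_peaks()].
#' @param anchor_tables A single [anchor_table()] or a list of them.
#' @return The input with physical CI columns appended.
#' @export
hotspot_physical_ci <- function(hotspots, anchor_tables) {
  if (inherits(anchor_tables, "anchor_table")) {
    anchor_tables <- list(anchor_tables)
  }
  for (at in anchor_tables) {
    ref <- tolower(at$reference_name)
    s_col <- paste0("ci_", ref, "_start_Mb")
    e_col <- paste0("ci_", ref, "_end_Mb")
    hotspots[[s_col]] <- NA_real_
    hotspots[[e_col]] <- NA_real_
    for (i in seq_len(nrow(hotspots))) {
      mb <- genetic_to_physical(
        c(hotspots$ci_start_cM[i], hotspots$ci_end_cM[i]),
        at, hotspots$chromosome[i])
      hotspots[[s_col]][i] <- min(mb)
      hotspots[[e_col]][i] <- max(mb)
    }
  }
  hotspots
}

#' Breeding-hotspot selection rule
#'
#' A hotspot qualifies as a breeding QTL when its physical CI is narrow
#' (width below `max_width_Mb`) and it is well supported: at least
#' `n_large` member MTAs with mean PVE at least `pve_large`, or between
#' `n_small` and `n_large - 1` members with mean PVE above `pve_small`.
#' Hotspots with fewer than `n_small` members, or with no observed PVE,
#' are never selected.
#'
#' @param width_Mb Numeric vector of physical CI widths (Mb).
#' @param n_mta Integer vector of member counts.
#' @param pve_mean Numeric vector of member mean PVE (NA allowed).
#' @param max_width_Mb Width cutoff (strict `<`; default 20 Mb).
#' @param n_large,pve_large Member count and mean-PVE cutoffs for the
#'   well-supported branch (defaults 5 and 0.04; PVE compared with `>=`).
#' @param n_small,pve_small Cutoffs for the small branch (defaults 3 and
#'   0.1; PVE compared with strict `>`).
#' @return Logical vector.
#' @export
breeding_rule <- function(width_Mb, n_mta, pve_mean, max_width_Mb = 20,
                          n_large = 5, pve_large = 0.04,
                          n_small = 3, pve_small = 0.1) {
  ok_pve <- !is.na(pve_mean)
  narrow <- width_Mb < max_width_Mb
  large <- n_mta >= n_large & ok_pve & pve_mean >= pve_large
  small <- n_mta >= n_small & n_mta < n_large & ok_pve & pve_mean > pve_small
  narrow & (large | small)
}

#' Flag breeding hotspots
#'
#' Applies [breeding_rule()] to a hotspot table using the physical CI on
#' the primary reference assembly.
#'
#' @param hotspots Data.frame with physical CI columns (see
#'   [hotspot_physical_ci()]) and `n_mta`, `pve_mean`.
#' @param reference Name of the primary physical reference (default
#'   `"Svevo"`; matched case-insensitively against the CI columns).
#' @param ... Passed to [breeding_rule()].
#' @return The input with a logical `is_breeding` column.
#' @export
select_breeding <- function(hotspots, reference = "Svevo", ...) {
  ref <- tolower(reference)
  s_col <- paste0("ci_", ref, "_start_Mb")
  e_col <- paste0("ci_", ref, "_end_Mb")
  if (!all(c(s_col, e_col) %in% names(hotspots))) {
    stop("no physical CI columns for reference '", reference,
         "'; run hotspot_physical_ci() first")
  }
  width <- hotspots[[e_col]] - hotspots[[s_col]]
  hotspots$is_breeding <- breeding_rule(width, hotspots$n_mta,
                                        hotspots$pve_mean, ...)
  hotspots
}
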