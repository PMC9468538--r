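---
title: "QTL hotspot meta-analysis: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QTL hotspot meta-analysis: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtlhotspots)
```

## The problem

Individual GWAS of durum wheat quality traits each report a handful of
marker-trait associations (MTA) with limited resolution and
panel-specific coordinates. Combining many studies on a single consensus
genetic map reveals *QTL hotspots*: regions where associations from
independent panels, traits and environments accumulate, and which are
therefore the most reliable targets for marker-assisted selection.
`qtlhotspots` implements that combination end to end for a compilation
of ten durum wheat quality GWAS (395 MTA, 57 trait entries, 1,598
genotypes): projection onto one consensus map, density-based hotspot
calling, breeding-oriented selection, genetic-versus-physical
distribution, and cross-species (ortho-MQTL) synteny.

## Positional model

Each MTA carries a position $\mu_i$ (cM, consensus coordinates) and a
95% confidence interval of width $CI_i$ (cM). The CI is converted into
the standard deviation of a Gaussian positional uncertainty,

$$ s_i = \frac{CI_i}{3.92}, \qquad s_i^2 = \left(\frac{CI_i}{3.92}\right)^2, $$

because a 95% normal interval spans $2 \times 1.96$ standard deviations.
MTA whose source study reported no CI — 203 of the 395 in the
compilation — receive the intra-chromosomal LD-decay distance of their
chromosome as a surrogate *full width* (not half-width: the width is the
quantity the standardization consumes). The Gaussian is centred
symmetrically on the MTA position; output metadata flags these imputed
records (`ci_source = "ld_decay"`).

### The overview density index

For every 1-cM bin $[k, k+1)$ of every chromosome, the overview index
sums the probability mass that the MTAs of the chromosome place in the
bin:

$$ U(k) = \sum_i \Phi\!\left(\frac{k+1-\mu_i}{s_i}\right) -
          \Phi\!\left(\frac{k-\mu_i}{s_i}\right). $$

Each MTA contributes total mass at most 1, so the sum of $U$ over the
genome is at most the number of MTA and the *mean* of $U$ over all bins
is approximately $N / L$ for $N$ MTA on a map of total length $L$ —
0.150 for 395 MTA on the 2,630-cM consensus map. Mass falling beyond a
chromosome end is truncated, not renormalized: this is the simplest
defensible convention, it only affects MTA within a few $s$ of an end,
and the truncation is what makes the genome-wide mean fall marginally
below $N/L$ rather than above it.

Two thresholds are derived from the profile itself: the **mean
threshold**, the empirical mean of $U$ over every bin of the 14
chromosomes, and the **high threshold**, five times the mean. At
compilation scale these evaluate to 0.15 and 0.75. We compute the mean
empirically rather than from the closed form $N/L$: the two agree for
interior MTA, and the empirical mean is the quantity that actually
controls how many bins are supra-threshold. The number of contributing
studies is reported in the run summary but does not scale $U$.

### Peaks, merging, hotspots

A *peak* is a local maximum of $U$ restricted to bins at or above the
threshold; a plateau of equal values counts once, at its leftmost bin
(ties must be broken somewhere, and leftmost is reproducible). Each peak
carries its contiguous supra-threshold run. Runs that touch, overlap, or
are separated by at most `merge_gap_cM` (default 2 cM) merge into one
**hotspot** whose genetic CI is the span of the merged runs. Members are
the MTAs whose own CI interval ($\mu \pm CI/2$) overlaps the hotspot CI;
`pve_mean` averages the members with an observed PVE (a hotspot whose
members all lack PVE can never be selected for breeding). Hotspots are
numbered left-to-right per chromosome, sequentially genome-wide. The
merge gap is configuration-exposed because the underlying data sets
differ in marker density; 2 cM is of the order of the median CI and
merges only runs separated by a single sub-threshold bin or two.

### Breeding selection

A hotspot qualifies as a **breeding QTL** when its physical CI on the
primary reference assembly (Svevo) is narrower than 20 Mb *and* it is
well supported: at least 5 member MTAs with mean PVE $\ge$ 0.04, or 3–4
members with mean PVE $>$ 0.1. Hotspots with fewer than 3 members never
qualify. The width inequality is strict; the 0.04 branch is inclusive
(the published selected-hotspot table contains a hotspot with mean PVE
exactly 0.04, so an exclusive reading would be inconsistent with the
selection it documents) and the 0.1 branch exclusive. Applied to the
20-row selected-hotspot reference table shipped with the package, the
rule retains all 20 rows, whose member counts sum to 121 MTA with mean
PVE 0.11.

### Genetic ↔ physical coordinates

Physical positions are obtained by piecewise-linear interpolation of Mb
over cM between anchor markers, per chromosome, with nearest-interval
extrapolation (flagged) outside the anchor span. Locally non-monotone
anchors — real maps contain inversions — produce a warning but are still
interpolated. For the bin comparison each chromosome is cut into five
equal-length segments on each scale and every hotspot is placed once, by
its CI midpoint (the midpoint is defined on both scales, unlike the peak
bin, which exists only on the genetic one). Percentages are rounded to
integers in reports; full precision is kept in JSON.

## Synteny (ortho-MQTL)

Marker sequences of breeding-hotspot members are aligned externally
(e.g. bwa-mem) against Brachypodium, rice and maize at three stringency
rounds; the package consumes the SAM files. Hits are kept only when the
aligned fraction of the marker exceeds 60% *and* MAPQ exceeds 10, both
strictly. Per marker and genome, the highest stringency round with a
surviving hit wins; within it the unique top-MAPQ primary hit is kept,
and a top-MAPQ tie between different loci discards the marker as
ambiguous. The surviving hits of one hotspot are clustered per target
chromosome by single linkage at `max_gap_bp` (default 5 Mb — unstated in
the original analysis, so configuration-exposed); clusters with at least
`min_markers` (default 2) distinct markers become ortho regions. Gene
models intersecting a region (half-open overlap; internal coordinates
are 0-based half-open throughout, converted from SAM's 1-based
convention at the boundary) are returned from GFF3 annotation.

## The synthetic-data generator

Real inputs require several external downloads (consensus map, genome
assemblies, the full MTA supplement), so the package ships a generator
that emulates the compilation's published statistics and carries its
own ground truth:

* **Scale** — 10 studies, 395 MTA, 14 chromosomes totalling 2,630 cM;
  panel sizes summing to 1,598.
* **CI distribution** — log-normal solved exactly through the two
  printed quantile points (83% ≤ 5 cM, 97% ≤ 10 cM), truncated to
  [0.1, 43] cM; the implied mean is 3.24 cM against the reported
  average of 3.3. A two-parameter family cannot also match the mean
  exactly; the quantiles drive the standardization so they take
  priority. Exactly round(0.514 × n) = 203 records have their CI
  withheld (the compilation reports an exact count, not a rate).
* **PVE distribution** — Beta fitted by least squares through 79% < 0.1
  and 95% < 0.2.
* **Trait shares** — YPC at 24%, the remainder spread over the other
  dictionary codes.
* **Placement** — 20 planted Gaussian clusters (sd 1.5 cM, ≥ 30 cM
  apart, ≥ 10 cM from chromosome ends) receive 80% of the MTA; the rest
  is uniform background. The clustered-majority regime reflects the
  published outcome (92 hotspots from 395 MTA — most associations sit
  in hotspots); the 10-cM margin keeps planted clusters clear of edge
  truncation.
* **Physical axis** — anchor tables encode a tanh sigmoid cM→Mb
  relation (steepness 8): recombination is suppressed mid-chromosome,
  so genetically uniform positions concentrate physically in the
  telomeric fifths of each chromosome (≈ 83% in bins 1 and 5 by
  construction, matching the reported physical enrichment).
* **Synteny fixtures** — planted ortho regions per genome with
  controlled rounds, MAPQs and length fractions, plus decoy hits at
  exactly the filter edges, low-round duplicates, and equal-MAPQ ties
  that the merge rules must reject; GFF3 gene models are planted inside
  every region.

The same seed yields byte-identical files. What the generator does *not*
emulate: real marker order and LD structure, study-specific source maps
(generated positions are already in consensus coordinates, exercising
the identity-projection path that dominates real SNP-panel data),
inter-study heterogeneity of CI quality, and sequence content (CIGAR
strings carry the length information). Passing recovery tests therefore
demonstrate the pipeline's correctness under the stated positional
model, not robustness to map errors or alignment noise.

## Numerical choices and degenerate inputs

* 1-cM half-open bins $[k, k+1)$, 0-based, left edge at 0 cM; one fixed
  discretization for everything downstream.
* Coordinates are continuous; nothing is rounded before reporting.
* A zero or missing CI is a contract violation at standardization
  (imputation must run first); a zero-length source interval or fewer
  than two shared markers is a projection error.
* Empty inputs yield empty summaries, not failures; an empty overview
  profile is an error for thresholding (a mean of nothing is
  undefined).
* Hotspot recovery metrics: a planted cluster is recovered when a
  called hotspot CI overlaps its center ± 3 sd; precision is judged
  over calls with ≥ 3 members, the conventional minimum support for a
  meta-QTL — a single precisely-located MTA legitimately exceeds the
  density threshold without being a cluster, and the selection stage
  never uses such calls.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run the generator at the
compilation's own scale (395 MTA, 2,630 cM); the multi-replicate
calibration and recovery checks use 20 seeds. These sizes keep every
check at desk scale while matching the regime in which the published
thresholds (0.15, 0.75) arise.

## Known limitations

* The merge of 158 peaks into 92 hotspots in the published analysis is
  not further specified there; the run-gap rule with a 2-cM default is
  this package's own convention.
* Classical likelihood-based meta-QTL clustering (Goffinet–Gerber
  style) is out of scope; the overview index is a density heuristic,
  not a model-based estimator of QTL number.
* The ortho-region step implements positional synteny only; it is not
  orthology inference, and marker-level "quality of the markers"
  redundancy criteria beyond the alignment-level rules are not defined.
* Published per-chromosome counts, peak counts (564/158), the 92-hotspot
  set and the 134 ortho-marker total depend on the full MTA supplement
  and external genome sequences, which are not redistributable here;
  the package validates those pathways on calibrated synthetic data and
  on the printed summary tables instead.
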