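Package: qtlhotspots
Title: Meta-Analysis of Marker-Trait Associations into QTL Hotspots on a
    Consensus Genetic Map
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to combine marker-trait associations (MTA) from multiple
    genome-wide association studies of durum wheat quality traits into
    consensus QTL hotspots. MTA are projected onto a common consensus
    genetic map by homothetic (flanking-anchor) rescaling, confidence
    intervals missing in the original studies are imputed from
    per-chromosome linkage-disequilibrium decay, and a per-centimorgan QTL
    overview density index converts the standardized positional
    uncertainties into a genome-wide density profile. Supra-threshold peaks
    of the profile are merged into hotspots, "breeding" hotspots are
    selected by physical-interval width, supporting-MTA count and mean
    phenotypic variance explained, and hotspot distributions are compared
    between genetic and physical chromosome axes. Marker alignments against
    other grass genomes (SAM) can be filtered and clustered into syntenic
    ortho-meta-QTL regions with candidate gene lookup from GFF3 annotation.
    A calibrated synthetic-data generator produces complete ground-truth
    inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Rsamtools,
    GenomicAlignments,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    digest
Config/testthat/edition: 3
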