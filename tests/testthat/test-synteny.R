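test_that("SAM hits are parsed with CIGAR-derived lengths", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               "@SQ\tSN:bd1\tLN:75000000",
               "mk1\t0\tbd1\t1001\t55\t90M10S\t*\t0\t0\t*\t*",
               "mk2\t256\tbd1\t5001\t12\t100M\t*\t0\t0\t*\t*",
               "mk3\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"), sam)
  hits <- read_alignments(sam, genome = "bd", round = "high")
  expect_equal(nrow(hits), 2)  # unmapped skipped
  expect_equal(hits$marker_length, c(100, 100))
  expect_equal(hits$aligned_length, c(90, 100))
  expect_equal(hits$target_start, c(1000, 5000))  # 0-based
  expect_equal(hits$target_end[1], 1090)
  expect_equal(hits$is_secondary, c(FALSE, TRUE))
})

test_that("hit filtering is strict at both cutoffs and idempotent", {
  hits <- rbind(make_hit("keep", aligned_length = 75L, mapq = 30L),
                make_hit("frac_edge", aligned_length = 60L, mapq = 30L),
                make_hit("mapq_edge", aligned_length = 90L, mapq = 10L),
                make_hit("both_over", aligned_length = 61L, mapq = 11L))
  out <- filter_hits(hits)
  expect_setequal(out$marker_id, c("keep", "both_over"))
  expect_equal(filter_hits(out), out)
  zero <- make_hit("z", marker_length = 0L, aligned_length = 0L)
  expect_warning(res <- filter_hits(rbind(hits, zero)), "zero marker length")
  expect_false("z" %in% res$marker_id)
})

test_that("round merging prefers stringency, then MAPQ, and drops ties", {
  hits <- rbind(
    make_hit("a", round = "high", mapq = 25L, start = 100L),
    make_hit("a", round = "low", mapq = 60L, start = 900000L),
    make_hit("b", round = "low", mapq = 40L, start = 1000L),
    make_hit("b", round = "low", mapq = 12L, start = 2000L),
    make_hit("tie", round = "medium", mapq = 30L, chrom = "bd1"),
    make_hit("tie", round = "medium", mapq = 30L, chrom = "bd2"))
  out <- merge_rounds(hits)
  expect_equal(out$target_start[out$marker_id == "a"], 100)   # high round
  expect_equal(out$mapping_quality[out$marker_id == "b"], 40) # top mapq
  expect_false("tie" %in% out$marker_id)                      # ambiguous
  expect_lte(max(table(paste(out$marker_id, out$target_genome))), 1)
})

test_that("ortho regions require enough clustered markers", {
  hits <- rbind(make_hit("m1", start = 1000000L),
                make_hit("m2", start = 1500000L),
                make_hit("m3", start = 1900000L),
                make_hit("m4", genome = "os", chrom = "os5",
                         start = 500000L))
  regs <- call_ortho_regions("h1", c("m1", "m2", "m3", "m4"), hits)
  expect_equal(nrow(regs), 1)  # single os hit below min_markers
  expect_equal(regs$target_genome, "bd")
  expect_equal(regs$n_markers, 3)
  expect_setequal(regs$supporting_markers[[1]], c("m1", "m2", "m3"))
  expect_equal(regs$start, 1000000)
  # region count monotone non-increasing in min_markers
  counts <- vapply(1:4, function(k) {
    nrow(call_ortho_regions("h1", paste0("m", 1:4), hits, min_markers = k))
  }, 0L)
  expect_true(all(diff(counts) <= 0))
  # far-apart hits split by the gap parameter
  far <- rbind(make_hit("m1", start = 0L), make_hit("m2", start = 10000000L))
  expect_equal(nrow(call_ortho_regions("h", c("m1", "m2"), far)), 0)
  expect_equal(nrow(call_ortho_regions("h", c("m1", "m2"), far,
                                       max_gap_bp = 2e7)), 1)
  # members only: foreign markers never support a region
  expect_equal(nrow(call_ortho_regions("h", "absent", hits)), 0)
})

test_that("gene lookup uses half-open interval overlap", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
    "bd1\tsim\tgene\t101\t200\t.\t+\t.\tID=g1;description=first",
    "bd1\tsim\tgene\t251\t300\t.\t-\t.\tID=g2;description=second",
    "bd1\tsim\tgene\t401\t500\t.\t+\t.\tID=g3;description=third",
    "bd1\tsim\tgene\t601\t700\t.\t+\t.\tID=g4;description=fourth",
    "bd2\tsim\tgene\t101\t200\t.\t+\t.\tID=g5;description=fifth"), gff)
  hit <- genes_in_interval(gff, "bd1", 150, 300)
  expect_equal(hit$gene_id, c("g1", "g2"))
  expect_equal(hit$strand, c("+", "-"))
  # half-open: gene [100,200) does not intersect query [200,300)
  expect_false("g1" %in% genes_in_interval(gff, "bd1", 200, 250)$gene_id)
  expect_warning(none <- genes_in_interval(gff, "os1", 0, 1000),
                 "not present")
  expect_equal(nrow(none), 0)
})

test_that("planted synteny fixtures are recovered exactly", {
  db <- simulate_mta_database(generator_config(seed = 17))
  std <- standardize_mta(project_mta(impute_ci(db$mta, db$ld_decay),
                                     db$map))
  prof <- overview_index(std, db$map)
  hs <- merge_peaks(detect_peaks(
    prof, overview_high_threshold(overview_mean_threshold(prof))), std)
  hs <- select_breeding(hotspot_physical_ci(hs, db$anchors))
  br <- hs[hs$is_breeding, ]
  fx <- simulate_synteny_fixture(br, db$mta, seed = 18,
                                 dir = withr::local_tempdir())
  merged <- merge_rounds(filter_hits(read_alignment_set(fx$sam_files)))
  expect_false(any(grepl("decoy", merged$marker_id)))
  regs <- do.call(rbind, lapply(seq_len(nrow(br)), function(i) {
    mk <- db$mta$marker_id[match(br$members[[i]], db$mta$mta_id)]
    call_ortho_regions(br$hotspot_id[i], mk, merged)
  }))
  key <- function(d) paste(d$hotspot_id, d$target_genome,
                           d$target_chromosome)
  expect_setequal(key(regs), key(fx$planted_regions))
  # per-genome ortho-marker counts sum to the overall total
  per_genome <- tapply(regs$n_markers, regs$target_genome, sum)
  expect_equal(sum(per_genome), sum(regs$n_markers))
  # planted gene models are retrievable from the region annotation
  r1 <- regs[1, ]
  gfile <- grep(paste0("genes_", r1$target_genome), fx$gff_files,
                value = TRUE)
  genes <- genes_in_interval(gfile, r1$target_chromosome, r1$start, r1$end)
  expect_gt(nrow(genes), 0)
})
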