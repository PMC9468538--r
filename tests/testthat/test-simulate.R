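test_that("distribution fits hit the stated calibration points", {
  ci <- fit_ci_lognormal()
  expect_equal(stats::plnorm(5, ci$meanlog, ci$sdlog), 0.83)
  expect_equal(stats::plnorm(10, ci$meanlog, ci$sdlog), 0.97)
  expect_equal(ci$mean, 3.3, tolerance = 0.03)
  pve <- fit_pve_beta()
  expect_equal(stats::pbeta(0.1, pve$shape1, pve$shape2), 0.79,
               tolerance = 0.01)
  expect_equal(stats::pbeta(0.2, pve$shape1, pve$shape2), 0.95,
               tolerance = 0.01)
  expect_error(fit_ci_lognormal(q1 = 5, p1 = 0.97, q2 = 10, p2 = 0.83),
               "inconsistent")
})

test_that("the generated database has the configured shape", {
  cfg <- generator_config(seed = 1)
  db <- simulate_mta_database(cfg)
  expect_equal(nrow(db$mta), 395)
  expect_equal(nrow(db$studies), 10)
  expect_equal(sum(db$studies$n_mta), 395)
  expect_equal(sum(db$studies$size), 1598)
  expect_equal(sum(is.na(db$mta$ci_cM)), 203)  # exact missing-CI count
  expect_equal(sum(db$map$chrom_lengths_cM), 2630)
  expect_equal(sort(unique(db$mta$chromosome)), sort(durum_chromosomes()))
  expect_true(all(db$mta$position_cM <=
                    db$map$chrom_lengths_cM[db$mta$chromosome]))
  expect_equal(nrow(db$ground_truth$planted), 20)
  expect_equal(sum(db$ground_truth$planted$n_planted) +
                 sum(is.na(db$ground_truth$membership$planted_id)), 395)
  expect_error(generator_config(), "seed is mandatory")
  expect_error(generator_config(seed = 1, clustered_fraction = 1.4),
               "fractions")
})

test_that("YPC is the modal trait at roughly a quarter of MTA", {
  share <- vapply(1:5, function(k) {
    db <- simulate_mta_database(generator_config(seed = 30 + k))
    mean(db$mta$trait_code == "YPC")
  }, 0)
  expect_equal(mean(share), 0.24, tolerance = 0.03)
})

test_that("identical seeds give byte-identical files, different seeds differ", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  simulate_mta_database(generator_config(seed = 42), dir = d1)
  simulate_mta_database(generator_config(seed = 42), dir = d2)
  simulate_mta_database(generator_config(seed = 43), dir = d3)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  expect_false(identical(readLines(file.path(d1, "mta.tsv")),
                         readLines(file.path(d3, "mta.tsv"))))
})

test_that("generated tables are readable through the package readers", {
  dir <- withr::local_tempdir()
  db <- simulate_mta_database(generator_config(seed = 2), dir = dir)
  mta <- read_mta(file.path(dir, "mta.tsv"))
  expect_equal(mta, db$mta)
  studies <- read_studies(file.path(dir, "studies.tsv"))
  expect_equal(studies$n_mta, db$studies$n_mta)
  map <- read_genetic_map(file.path(dir, "map.tsv"),
                          file.path(dir, "chrom_lengths.tsv"))
  expect_equal(map$chrom_lengths_cM, db$map$chrom_lengths_cM)
  ld <- read_ld_decay(file.path(dir, "ld_decay.tsv"))
  expect_equal(ld, db$ld_decay)
  anc <- read_anchors(file.path(dir, "anchors_Svevo.tsv"))
  expect_equal(anc$reference_name, "Svevo")
  expect_equal(anc$anchors$Mb, db$anchors$Svevo$anchors$Mb)
})

test_that("planted clusters dominate their neighbourhoods", {
  db <- simulate_mta_database(generator_config(seed = 3))
  std <- standardize_mta(project_mta(impute_ci(db$mta, db$ld_decay),
                                     db$map))
  prof <- overview_index(std, db$map)
  hs <- merge_peaks(detect_peaks(
    prof, overview_high_threshold(overview_mean_threshold(prof))), std)
  rec <- planted_recovery(hs, db$ground_truth)
  expect_gte(rec$sensitivity, 0.9)
  expect_gte(rec$precision, 0.9)
  # each planted cluster's members are largely captured by its hotspot
  truth <- db$ground_truth
  for (i in seq_len(nrow(truth$planted))) {
    ids <- truth$membership$mta_id[
      !is.na(truth$membership$planted_id) &
        truth$membership$planted_id == truth$planted$planted_id[i]]
    caught <- vapply(hs$members, function(m) mean(ids %in% m), 0)
    expect_gte(max(caught), 0.9)
  }
})
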