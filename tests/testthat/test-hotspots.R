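test_that("CI standardization follows s = CI / 3.92", {
  out <- standardize_mta(make_mta("1A", c(10, 20), ci_cM = c(3.92, 7.84)))
  expect_equal(out$s, c(1, 2))
  expect_equal(out$s_squared, c(1, 4))
  expect_error(standardize_mta(make_mta("1A", 10, ci_cM = NA)), "positive CI")
  expect_error(standardize_mta(transform(make_mta("1A", 10), ci_cM = 0)),
               "positive CI")
})

test_that("a near-point MTA puts all its mass in one bin", {
  mta <- standardize_mta(make_mta("1A", 50.5, ci_cM = 1e-9))
  prof <- overview_index(mta, tiny_map("1A", 100))
  expect_equal(nrow(prof), 100)
  expect_equal(prof$u[prof$bin_start == 50], 1)
  expect_equal(sum(prof$u), 1)
})

test_that("overview index conserves Gaussian mass for interior MTAs", {
  mta <- standardize_mta(make_mta("1A", 50, ci_cM = 3.92))  # s = 1
  prof <- overview_index(mta, tiny_map("1A", 100))
  expect_equal(sum(prof$u), 1, tolerance = 1e-6)

  # against the fine-grid numerical-integration oracle, bin by bin
  set.seed(11)
  mu <- runif(5, 30, 70)
  ci <- runif(5, 1, 8)
  mta <- standardize_mta(make_mta("1A", mu, ci_cM = ci))
  prof <- overview_index(mta, tiny_map("1A", 100))
  expect_equal(prof$u, oracle_bin_mass(mu, ci / 3.92, 100),
               tolerance = 1e-6)
})

test_that("mean of the overview index approximates N / map length", {
  set.seed(3)
  n <- 60
  mta <- standardize_mta(make_mta("1A", runif(n, 20, 180), ci_cM = 4))
  prof <- overview_index(mta, tiny_map("1A", 200))
  expect_equal(mean(prof$u), n / 200, tolerance = 0.01 * n / 200)
})

test_that("doubling CIs leaves the interior mass unchanged", {
  set.seed(4)
  mu <- runif(30, 40, 160)
  p1 <- overview_index(standardize_mta(make_mta("1A", mu, ci_cM = 3)),
                       tiny_map("1A", 200))
  p2 <- overview_index(standardize_mta(make_mta("1A", mu, ci_cM = 6)),
                       tiny_map("1A", 200))
  expect_equal(sum(p1$u), sum(p2$u), tolerance = 1e-6)
})

test_that("thresholds: high is exactly five times the mean", {
  prof <- data.frame(chromosome = "1A", bin_start = 0:9, u = rep(0.2, 10))
  expect_equal(overview_mean_threshold(prof), 0.2)
  expect_equal(overview_high_threshold(0.2), 1.0)
  expect_equal(overview_high_threshold(0.15), 0.75)
  expect_error(overview_mean_threshold(prof[0, ]), "empty")
})

test_that("peak detection: local maxima, plateaus count once at the left", {
  prof <- data.frame(chromosome = "1A", bin_start = 0:4,
                     u = c(0, 0, 1, 0, 0))
  pk <- detect_peaks(prof, 0.5)
  expect_equal(pk$peak_bin, 2)
  expect_equal(c(pk$run_start, pk$run_end), c(2, 2))

  plateau <- data.frame(chromosome = "1A", bin_start = 0:4,
                        u = c(0, 1, 1, 1, 0))
  pk <- detect_peaks(plateau, 0.5)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$peak_bin, 1)
  expect_equal(c(pk$run_start, pk$run_end), c(1, 3))
})

test_that("a bimodal profile yields two peaks above the saddle", {
  mta <- standardize_mta(make_mta("1A", c(35, 65), ci_cM = 3.92))
  prof <- overview_index(mta, tiny_map("1A", 100))
  saddle <- prof$u[prof$bin_start == 50]
  pk <- detect_peaks(prof, (saddle + max(prof$u)) / 2)
  expect_equal(nrow(pk), 2)
})

test_that("peak count is monotone non-increasing in the threshold", {
  db <- simulate_mta_database(generator_config(seed = 5))
  std <- standardize_mta(project_mta(impute_ci(db$mta, db$ld_decay),
                                     db$map))
  prof <- overview_index(std, db$map)
  counts <- vapply(c(0.05, 0.15, 0.3, 0.75, 1.5, 3),
                   function(t) nrow(detect_peaks(prof, t)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("adjacent runs merge into one hotspot, distant ones do not", {
  peaks <- data.frame(chromosome = "2B", peak_bin = c(11, 14),
                      u = c(1, 1.2), run_start = c(10, 13),
                      run_end = c(12, 15), stringsAsFactors = FALSE)
  mta <- standardize_mta(make_mta("2B", c(11, 14, 70), ci_cM = 2))
  hs <- merge_peaks(peaks, mta)
  expect_equal(nrow(hs), 1)
  expect_equal(c(hs$ci_start_cM, hs$ci_end_cM), c(10, 16))
  expect_setequal(hs$members[[1]], c("m001", "m002"))

  apart <- data.frame(chromosome = "2B", peak_bin = c(11, 51),
                      u = c(1, 1), run_start = c(10, 50),
                      run_end = c(12, 52), stringsAsFactors = FALSE)
  expect_equal(nrow(merge_peaks(apart, mta)), 2)
})

test_that("hotspot members are assigned by CI overlap and PVE averaged", {
  peaks <- data.frame(chromosome = "1A", peak_bin = 20, u = 1,
                      run_start = 20, run_end = 21, stringsAsFactors = FALSE)
  mta <- make_mta("1A", c(20.5, 23.5, 60), ci_cM = c(2, 4, 2),
                  pve = c(0.1, NA, 0.5))
  hs <- merge_peaks(peaks, standardize_mta(mta))
  # CI of m002 is [21.5, 25.5] vs hotspot [20, 22]: overlaps; m003 does not
  expect_setequal(hs$members[[1]], c("m001", "m002"))
  expect_equal(hs$n_mta, 2)
  expect_equal(hs$pve_mean, 0.1)  # missing PVE excluded from the mean
})

test_that("breeding rule branches behave as specified", {
  # n >= 5 branch: mean PVE >= 0.04, width strictly < 20 Mb
  expect_true(breeding_rule(19.9, 6, 0.04))
  expect_false(breeding_rule(25, 6, 0.04))
  expect_false(breeding_rule(20, 6, 0.5))    # width not strictly below
  # 3 <= n < 5 branch: strict PVE > 0.1
  expect_true(breeding_rule(5, 3, 0.12))
  expect_false(breeding_rule(5, 3, 0.08))
  expect_false(breeding_rule(5, 4, 0.1))     # strict >
  expect_false(breeding_rule(5, 2, 0.5))     # never with < 3 members
  expect_false(breeding_rule(5, 8, NA))      # no observed PVE
})

test_that("select_breeding uses the primary reference physical width", {
  hs <- data.frame(hotspot_id = 1:2, chromosome = "1A",
                   ci_start_cM = c(0, 50), ci_end_cM = c(2, 52),
                   n_mta = c(6L, 6L), pve_mean = c(0.1, 0.1),
                   ci_svevo_start_Mb = c(1, 300),
                   ci_svevo_end_Mb = c(8, 350), stringsAsFactors = FALSE)
  out <- select_breeding(hs)
  expect_equal(out$is_breeding, c(TRUE, FALSE))
  expect_error(select_breeding(hs[, 1:6]), "physical CI")
})
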