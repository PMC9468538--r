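test_that("LD-decay imputation fills only missing CIs", {
  ld <- c("7A" = 4.0)
  mta <- make_mta("7A", c(10, 20), ci_cM = c(NA, 2.5))
  out <- impute_ci(mta, ld)
  expect_equal(out$ci_cM, c(4.0, 2.5))
  expect_equal(out$ci_source, c("ld_decay", "original"))
  expect_error(impute_ci(make_mta("1B", 5, ci_cM = NA), ld), "LD-decay")
})

test_that("flanking-anchor rescaling interpolates and extrapolates", {
  # anchors (10,15),(20,35): doubling interval
  pr <- project_position(c(15, 5, 25), c(10, 20), c(15, 35))
  expect_equal(pr$position, c(25, 5, 45))
  expect_equal(pr$flag, c("anchored", "extrapolated", "extrapolated"))
  expect_error(project_position(5, c(10), c(15)), ">= 2 shared markers")
  expect_error(project_position(5, c(10, 10), c(15, 35)), "zero-length")
})

test_that("projection identity leaves positions and CIs unchanged", {
  map <- tiny_map("1A", 200)
  mta <- make_mta("1A", c(10, 102, 150.5), ci_cM = c(2, 4.2, 6))
  out <- project_mta(mta, map)
  expect_equal(out$position_cM, mta$position_cM)
  expect_equal(out$ci_cM, mta$ci_cM)
  expect_true(all(out$projection_flag == "identity"))
  expect_false(any(out$ci_clamped))
})

test_that("projection preserves marker order under increasing anchors", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    src <- sort(runif(n, 0, 100))
    dst <- sort(runif(n, 0, 250))
    p <- sort(runif(15, -10, 110))
    pos <- project_position(p, src, dst)$position
    expect_true(all(diff(pos) >= -1e-9))
  }
})

test_that("two-step projection composes exactly through a middle map", {
  set.seed(7)
  for (rep in 1:10) {
    n <- 6
    src <- sort(runif(n, 0, 100))
    mid <- sort(runif(n, 0, 150))
    dst <- sort(runif(n, 0, 300))
    p <- runif(10, min(src), max(src))
    one <- project_position(p, src, dst)$position
    two <- project_position(project_position(p, src, mid)$position,
                            mid, dst)$position
    expect_equal(two, one, tolerance = 1e-10)
  }
})

test_that("CI width scales with the local ratio and clamps at ends", {
  # source interval [10,20] maps to [15,35]: local ratio 2
  src_map <- genetic_map(
    data.frame(marker = c("a", "b"), chromosome = "1A",
               position_cM = c(10, 20)), c("1A" = 40), name = "src")
  cons_map <- genetic_map(
    data.frame(marker = c("a", "b"), chromosome = "1A",
               position_cM = c(15, 35)), c("1A" = 80), name = "cons")
  mta <- make_mta("1A", 15, ci_cM = 3)
  out <- project_mta(mta, cons_map, src_map)
  expect_equal(out$position_cM, 25)
  expect_equal(out$ci_cM, 6)  # width x2

  # CI straddling 0 after projection is truncated and flagged
  near0 <- project_mta(make_mta("1A", 0.5, ci_cM = 4), tiny_map("1A", 100))
  expect_true(near0$ci_clamped)
  expect_equal(near0$ci_cM, 2.5)  # [-1.5, 2.5] clamps to [0, 2.5]
})

test_that("markers found by name on the consensus map are placed directly", {
  cons <- genetic_map(
    data.frame(marker = c("mk1", "mk2"), chromosome = "1A",
               position_cM = c(30, 60)), c("1A" = 100), name = "cons")
  mta <- make_mta("1A", 999, ci_cM = 2, marker_id = "mk2")
  mta$position_cM <- 10  # source coordinate, ignored for named markers
  out <- project_mta(mta, cons)
  expect_equal(out$position_cM, 60)
  expect_equal(out$projection_flag, "identity")
})

test_that("genetic-to-physical interpolation is piecewise linear", {
  at <- anchor_table(
    data.frame(chromosome = "1A", marker = c("a", "b", "c"),
               cM = c(0, 50, 100), Mb = c(0, 100, 600)), "Svevo")
  expect_equal(genetic_to_physical(75, at, "1A"), 350)
  expect_equal(genetic_to_physical(50, at, "1A"), 100)  # anchor hit
  two <- anchor_table(
    data.frame(chromosome = "1A", marker = c("a", "b"),
               cM = c(0, 100), Mb = c(0, 500)), "Svevo")
  expect_equal(genetic_to_physical(50, two, "1A"), 250)
  d <- genetic_to_physical(c(50, 120), two, "1A", details = TRUE)
  expect_equal(d$flag, c("interpolated", "extrapolated"))
  expect_equal(d$Mb[2], 600)  # nearest-interval slope extension
  inv <- anchor_table(
    data.frame(chromosome = "1A", marker = c("a", "b", "c"),
               cM = c(0, 50, 100), Mb = c(0, 200, 100)), "Svevo")
  expect_warning(genetic_to_physical(25, inv, "1A"), "non-monotone")
})
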