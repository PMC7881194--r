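test_that("partition_levels splits the LI range in thirds with zero apart", {
  gt <- make_li_table(c(0, 0, 5, 10, 15, 20, 25, 30))
  p <- partition_levels(gt)
  expect_equal(p$li_min, 0)
  expect_equal(p$li_max, 30)
  expect_equal(p$cutoff_c1, 10)
  expect_equal(p$cutoff_c2, 20)
  expect_equal(as.character(p$levels),
               c("zero", "zero", "low", "low", "medium", "medium",
                 "high", "high"))
  expect_equal(unname(p$proportions), rep(0.25, 4))
  expect_equal(sum(p$proportions), 1, tolerance = 1e-12)
})

test_that("partition_levels handles degenerate ranges", {
  # all equal and positive: one non-zero level, labelled high
  p <- partition_levels(make_li_table(rep(7, 5)))
  expect_equal(unname(p$proportions["high"]), 1)
  # all zero
  p0 <- partition_levels(make_li_table(rep(0, 4)))
  expect_equal(unname(p0$proportions["zero"]), 1)
  expect_error(partition_levels(make_table(c(50L), c(0L)) |> apply_qc()),
               "empty slide")
})

test_that("select_fields apportions picks by largest remainder", {
  # four balanced levels: exactly one pick per level
  p <- partition_levels(make_li_table(c(0, 0, 5, 10, 15, 20, 25, 30)))
  set.seed(1)
  ids <- select_fields(p, n_fields = 4)
  expect_length(ids, 4L)
  lv <- p$levels[match(ids, p$grids$grid_id)]
  expect_equal(sort(as.character(lv)),
               sort(c("zero", "low", "medium", "high")))

  # single non-empty level: all picks from it
  ph <- partition_levels(make_li_table(rep(40, 10)))
  expect_length(select_fields(ph, 4), 4L)

  # proportions (0.7, 0.1, 0.1, 0.1) over (zero, low, medium, high):
  # largest-remainder allocation is (3, 1, 0, 0)
  gt <- make_li_table(c(rep(0, 7), 3, 18, 33))
  pu <- partition_levels(gt)  # range 0-33, c1 11, c2 22
  expect_equal(unname(pu$proportions), c(0.7, 0.1, 0.1, 0.1))
  set.seed(2)
  ids <- select_fields(pu, 4)
  lv <- table(pu$levels[match(ids, pu$grids$grid_id)])
  expect_equal(as.integer(lv), c(3L, 1L, 0L, 0L))

  # fewer grids than fields: every grid selected
  p3 <- partition_levels(make_li_table(c(1, 2, 3)))
  expect_setequal(select_fields(p3, 4), p3$grids$grid_id)
})

test_that("global and weighted averages follow the protocol arithmetic", {
  gt <- make_table(c(100L, 100L), c(10L, 30L))
  p <- partition_levels(gt)
  expect_equal(ikwg_global_average(p, c("g1", "g2")), 20)
  expect_equal(ikwg_global_average(p, "g1"), 10)

  # one selected grid per level, proportions 0.25 each, LIs (0, 5, 15, 25)
  gt4 <- make_li_table(c(0, 5, 15, 25))
  p4 <- partition_levels(gt4)  # range 25: c1 8.33, c2 16.67
  expect_equal(as.character(p4$levels), c("zero", "low", "medium", "high"))
  expect_equal(ikwg_weighted_average(p4, p4$grids$grid_id),
               0.25 * 0 + 0.25 * 5 + 0.25 * 15 + 0.25 * 25)

  # homogeneous slide: weighted average is the common LI
  ph <- partition_levels(make_li_table(rep(9, 6)))
  expect_equal(ikwg_weighted_average(ph, ph$grids$grid_id[1:4]), 9)
  expect_equal(ikwg_weighted_average(partition_levels(make_li_table(rep(0, 6))),
                                     c("g1", "g2")), 0)
  expect_error(ikwg_weighted_average(p4, character(0)), "empty")
})

test_that("unsampled non-zero levels renormalize; zero level always counts", {
  # levels: zero {0}, low {6}, medium {12}, high {18, 20}; proportions 0.2/0.2/0.2/0.4
  gt <- make_li_table(c(0, 6, 12, 18, 20))
  p <- partition_levels(gt)
  # selection missing the medium grid: mass = 0.2 (zero) + 0.2 (low) + 0.4 (high)
  w <- ikwg_weighted_average(p, c("g1", "g2", "g4", "g5"))
  expect_equal(w, (6 * 0.2 + 19 * 0.4) / 0.8)
})

test_that("run_ikwg_simulation is deterministic and respects bounds", {
  set.seed(99)
  gt <- random_table(n_grids = 30)
  s1 <- run_ikwg_simulation(gt, n_replicates = 200, seed = 7)
  s2 <- run_ikwg_simulation(gt, n_replicates = 200, seed = 7)
  expect_identical(s1$replicates, s2$replicates)
  expect_identical(s1$medians, s2$medians)

  li <- grid_li(gt$grids$tumor_cells, gt$grids$positive_cells)
  expect_true(all(s1$replicates$global_average >= min(li) - 1e-9))
  expect_true(all(s1$replicates$global_average <= max(li) + 1e-9))
  expect_true(all(s1$replicates$weighted_average >= 0))
  expect_true(all(s1$replicates$weighted_average <= max(li) + 1e-9))
  expect_true(all(s1$ci_low <= s1$medians & s1$medians <= s1$ci_high))

  # homogeneous slide: degenerate distributions at the common LI
  hom <- run_ikwg_simulation(make_li_table(rep(14, 8)), n_replicates = 50,
                             seed = 3)
  expect_equal(unname(hom$medians), c(14, 14))
  expect_equal(unname(hom$ci_low), unname(hom$ci_high))
})

test_that("simulated weighted average matches the exhaustive selection oracle", {
  gt <- make_li_table(c(0, 0, 5, 10, 15, 20, 25, 30))
  # one pick per level; zero picks are score-neutral, so W ranges over
  # 0.25 * (l + m + h) for l in {5,10}, m in {15,20}, h in {25,30}
  combos <- expand.grid(l = c(5, 10), m = c(15, 20), h = c(25, 30))
  w_all <- 0.25 * rowSums(combos)
  s <- run_ikwg_simulation(gt, n_replicates = 2000, seed = 42)
  mc_se <- sd(w_all) / sqrt(2000)
  expect_lt(abs(mean(s$replicates$weighted_average) - mean(w_all)), 4 * mc_se)
  # the discrete distribution puts mass 1/2 at or below 12.5, so the sample
  # median lies between the two central atoms
  expect_gte(s$medians[["weighted_average"]], 12.5)
  expect_lte(s$medians[["weighted_average"]], 13.75)
})

test_that("median scores are stable across seeds at n = 1000", {
  set.seed(31)
  gt <- random_table(n_grids = 50)
  m1 <- run_ikwg_simulation(gt, 1000, seed = 1, keep_replicates = FALSE)
  m2 <- run_ikwg_simulation(gt, 1000, seed = 2, keep_replicates = FALSE)
  li <- grid_li(gt$grids$tumor_cells, gt$grids$positive_cells)
  spread <- diff(range(li)) + 1e-9
  expect_lt(abs(m1$medians[["weighted_average"]] -
                  m2$medians[["weighted_average"]]) / spread, 0.1)
  expect_lt(abs(m1$medians[["global_average"]] -
                  m2$medians[["global_average"]]) / spread, 0.25)
})
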