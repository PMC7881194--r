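test_that("simulate_slide is deterministic given the RNG state", {
  p <- slide_sim_params(n_rows = 10, n_cols = 10)
  set.seed(5)
  a <- simulate_slide(p)
  set.seed(5)
  b <- simulate_slide(p)
  expect_identical(a$grids, b$grids)
  expect_equal(nrow(a$grids), 100L)
  expect_true(all(a$grids$positive_cells <= a$grids$tumor_cells))
})

test_that("slide and cohort parameter validation", {
  expect_error(slide_sim_params(n_rows = 0), "dimensions")
  expect_error(slide_sim_params(baseline_li = 1.2), "fraction")
  expect_error(slide_sim_params(hotspot_sigma_grids = 0), "sigma")
  expect_error(cohort_sim_params(grade_probs = c(0.5, 0.5, 0.5)), "sum to 1")
  expect_error(cohort_sim_params(rs_link = list(beta0 = 0, beta1 = 1,
                                                beta2 = 0, sigma = -1)),
               "sigma")
})

test_that("amplitude-0 slides recover the baseline LI within 3 SE", {
  set.seed(61)
  p <- slide_sim_params(n_rows = 20, n_cols = 20, baseline_li = 0.1,
                        hotspot_amplitude = 0, n_hotspots = 0)
  gt <- simulate_slide(p)
  a <- average_score(apply_qc(gt, 0))
  n_cells <- sum(gt$grids$tumor_cells)
  se <- 100 * sqrt(0.1 * 0.9 / n_cells)
  expect_lt(abs(a - 10), 3 * se)
})

test_that("a planted hotspot lifts the hottest spot above the average", {
  set.seed(62)
  p <- slide_sim_params(n_rows = 20, n_cols = 20, baseline_li = 0.05,
                        hotspot_amplitude = 0.5, n_hotspots = 1)
  s <- score_slide(simulate_slide(p))
  expect_gt(s$hottest_spot, s$average + 20)
})

test_that("the top grid falls near a bump center in >= 95% of simulations", {
  set.seed(63)
  p <- slide_sim_params(n_rows = 20, n_cols = 20)
  hits <- 0L
  n_sim <- 60L
  for (i in seq_len(n_sim)) {
    gt <- simulate_slide(p)
    centers <- attr(gt, "hotspot_centers")
    top <- hotspot_score(apply_qc(gt, 100), k = 1)$grid_ids
    g <- gt$grids[gt$grids$grid_id == top, ]
    d <- sqrt((g$row_index - centers[, "row"])^2 +
                (g$col_index - centers[, "col"])^2)
    if (min(d) <= 2 * p$hotspot_sigma_grids) hits <- hits + 1L
  }
  expect_gte(hits / n_sim, 0.95)
})

test_that("regrid pools counts exactly and never raises the max LI", {
  expect_error(regrid(make_li_table(1:3), 0), "positive integer")
  gt <- make_li_table(c(5, 10, 20))
  expect_identical(regrid(gt, 1), gt)

  set.seed(64)
  p <- slide_sim_params(n_rows = 12, n_cols = 12)
  for (i in 1:5) {
    gt <- simulate_slide(p)
    for (f in c(2L, 3L)) {
      rg <- regrid(gt, f)
      expect_equal(sum(rg$grids$tumor_cells), sum(gt$grids$tumor_cells))
      expect_equal(sum(rg$grids$positive_cells),
                   sum(gt$grids$positive_cells))
      expect_equal(average_score(apply_qc(rg, 0)),
                   average_score(apply_qc(gt, 0)))
      expect_lte(hottest_spot_score(apply_qc(rg, 0)),
                 hottest_spot_score(apply_qc(gt, 0)) + 1e-12)
      expect_equal(rg$grid_size_um, gt$grid_size_um * f)
    }
  }
})

test_that("cohort simulation hits its calibration targets", {
  sim <- simulate_cohort(cohort_sim_params(n_cases = 240), seed = 17)
  co <- sim$cohort
  expect_equal(nrow(co), 240L)
  expect_length(sim$slides, 240L)
  # regression band for the LI-RS link calibration
  expect_gt(pearson_r(co$average, co$rs), 0.35)
  expect_lt(pearson_r(co$average, co$rs), 0.65)
  # hotspot runs about twice the average score
  ratio <- median(co$hotspot) / median(co$average)
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 3.5)
  expect_true(all(co$rs >= 0 & co$rs <= 100))
  expect_true(all(co$grade %in% 1:3))

  # noiseless link: RS is a deterministic transform of average and grade
  p0 <- cohort_sim_params(n_cases = 40,
                          rs_link = list(beta0 = 2, beta1 = 4.4, beta2 = 0,
                                         sigma = 0))
  co0 <- simulate_cohort(p0, seed = 18)$cohort
  expect_equal(co0$rs,
               as.integer(round(pmin(pmax(2 + 4.4 * sqrt(co0$average), 0),
                                     100))))
  # perfect up to integer rounding of RS
  expect_gt(pearson_r(sqrt(co0$average), co0$rs), 0.99)

  # empty cohort
  e <- simulate_cohort(cohort_sim_params(n_cases = 0), seed = 1)
  expect_equal(nrow(e$cohort), 0L)
})

test_that("simulate_cohort is reproducible for a fixed seed", {
  p <- cohort_sim_params(n_cases = 5)
  a <- simulate_cohort(p, seed = 23)
  b <- simulate_cohort(p, seed = 23)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$slides[[3]]$grids, b$slides[[3]]$grids)
})
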