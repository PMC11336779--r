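test_that("built-in coefficient tables hold the published zone multipliers", {
  expect_equal(default_coefficients("all")$coefficients, c(1.37, 1.02, 0.74))
  expect_equal(default_coefficients("normal")$coefficients, c(1.40, 1.04, 0.74))
  expect_equal(default_coefficients("dual_task")$coefficients, c(1.36, 1.01, 0.73))
  expect_equal(default_coefficients("all")$zone_edges, c(0.2, 0.5, 0.8, 1.1))
  expect_error(default_coefficients("fast"))
})

test_that("adjustment multiplies by the zone coefficient of the raw estimate", {
  ct <- default_coefficients("all")
  expect_equal(apply_adjustment(0.60, ct)$adjusted, 0.60 * 1.02)
  expect_equal(apply_adjustment(0.60, ct)$zone, 2)
  expect_equal(apply_adjustment(0.30, ct)$adjusted, 0.30 * 1.37)
  expect_equal(apply_adjustment(0.90, ct)$adjusted, 0.90 * 0.74)
  # half-open zones: boundaries belong to the upper zone; last zone closed
  expect_equal(apply_adjustment(0.5, ct)$zone, 2)
  expect_equal(apply_adjustment(0.8, ct)$zone, 3)
  expect_equal(apply_adjustment(1.1, ct)$zone, 3)
  # out-of-range values clamp to the nearest zone and are flagged
  low <- apply_adjustment(0.15, ct)
  expect_equal(low$zone, 1)
  expect_true(low$out_of_range)
  high <- apply_adjustment(1.3, ct)
  expect_equal(high$zone, 3)
  expect_true(high$out_of_range)
  expect_error(apply_adjustment(-0.2, ct), "positive", class = "pg_input_error")
})

test_that("adjustment is exactly linear per zone and the all-ones table is the identity", {
  ct <- default_coefficients("all")
  set.seed(4)
  x <- runif(500, 0.21, 1.09)
  res <- apply_adjustment(x, ct)
  expect_identical(res$adjusted, ct$coefficients[res$zone] * x)
  ones <- coefficient_table(c(0.2, 0.5, 0.8, 1.1), c(1, 1, 1))
  expect_identical(apply_adjustment(x, ones)$adjusted, x)
})

test_that("fitting on unbiased data returns unit coefficients", {
  set.seed(9)
  ref <- runif(200, 0.3, 1.0)
  paired <- paired_steps(est = ref, ref = ref)
  ct <- fit_zone_coefficients(paired, 0.30)
  expect_equal(ct$coefficients, rep(1, length(ct$coefficients)))
})

test_that("fit-then-apply reproduces per-zone reference means exactly", {
  set.seed(10)
  ref <- runif(300, 0.3, 1.0)
  est <- ref * runif(300, 0.8, 1.25)
  paired <- paired_steps(est, ref)
  ct <- fit_zone_coefficients(paired, 0.25)
  adj <- apply_adjustment(est, ct)
  for (z in unique(adj$zone)) {
    sel <- adj$zone == z
    if (sum(sel) >= 2) {
      expect_equal(mean(adj$adjusted[sel]), mean(ref[sel]), tolerance = 1e-12)
    }
  }
})

test_that("scaling estimates and the grid together halves the coefficients", {
  set.seed(12)
  ref <- runif(150, 0.3, 1.0)
  est <- ref * runif(150, 0.9, 1.1)
  c1 <- fit_zone_coefficients(paired_steps(est, ref), 0.2, anchor = 0.2)
  c2 <- fit_zone_coefficients(paired_steps(2 * est, ref), 0.4, anchor = 0.4)
  expect_equal(c2$coefficients, c1$coefficients / 2, tolerance = 1e-12)
})

test_that("generator coefficients are recovered within 0.05 at the true width", {
  pp <- simulate_paired_steps(400, noise_sd = 0.02, seed = 21)
  ct <- fit_zone_coefficients(pp$paired, 0.30)
  core <- which(ct$zone_edges[-length(ct$zone_edges)] %in% c(0.2, 0.5, 0.8))
  expect_equal(ct$coefficients[core], c(1.37, 1.02, 0.74), tolerance = 0.05)
})

test_that("sparse zones inherit the nearest populated coefficient and are flagged", {
  # all estimates in one narrow band -> outer zones must inherit
  est <- runif(50, 0.55, 0.75)
  paired <- paired_steps(est, est * 1.1)
  ct <- fit_zone_coefficients(paired, 0.1)
  expect_true(any(!ct$flagged))
  if (any(ct$flagged)) {
    expect_true(all(ct$coefficients[ct$flagged] %in% ct$coefficients[!ct$flagged]))
  }
})

test_that("interval search honours its tie-break and determinism contracts", {
  set.seed(31)
  ref <- runif(250, 0.3, 1.0)
  est <- ref + rnorm(250, 0, 0.005)
  paired <- paired_steps(est, ref)
  # unbiased data: all widths near slope 1; smallest width wins ties
  res <- select_interval(paired, widths = c(0.2, 0.3))
  expect_true(res$selected_width %in% c(0.2, 0.3))
  single <- select_interval(paired, widths = 0.25)
  expect_equal(single$selected_width, 0.25)
  expect_equal(nrow(single$table), 1)
  # deterministic: repeated calls agree bit-for-bit
  r1 <- select_interval(paired)
  r2 <- select_interval(paired)
  expect_identical(r1$table, r2$table)
  expect_identical(r1$selected_width, r2$selected_width)
})

test_that("exact ties in the interval search fall to the smallest width", {
  # noiseless unbiased pairs: every width fits slope exactly 1, intercept 0
  ref <- seq(0.30, 1.00, length.out = 60)
  paired <- paired_steps(est = ref, ref = ref)
  res <- select_interval(paired, widths = c(0.10, 0.25, 0.50))
  expect_equal(res$selected_width, 0.10)
})

test_that("coefficient tables round-trip through YAML", {
  ct <- default_coefficients("dual_task")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_coefficients(ct, path)
  back <- read_coefficients(path)
  expect_equal(back$zone_edges, ct$zone_edges)
  expect_equal(back$coefficients, ct$coefficients)
  expect_equal(back$condition, "dual_task")
})

test_that("adjusted stride speed is recomputed from adjusted step lengths", {
  sim <- simulate_imu_walk(walk_profile(n_steps = 16, seed = 6))
  tab <- estimate_gait(sim$recording, coeffs = default_coefficients("all"))
  expect_equal(tab$speed_adj_mps,
               (tab$step_length_adj_1_m + tab$step_length_adj_2_m) / tab$stride_time_s,
               tolerance = 1e-12)
})
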