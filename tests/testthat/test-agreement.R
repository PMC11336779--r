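test_that("Passing-Bablok recovers identity and exact linear relations", {
  x <- as.numeric(1:10)
  pb <- passing_bablok(x, x)
  expect_equal(pb$slope, 1)
  expect_equal(pb$intercept, 0)
  pb2 <- passing_bablok(x, 2 * x + 1)
  expect_equal(pb2$slope, 2)
  expect_equal(pb2$intercept, 1)
})

test_that("Passing-Bablok matches the brute-force oracle on seeded data", {
  for (s in 1:20) {
    set.seed(100 + s)
    n <- sample(5:30, 1)
    x <- runif(n, 0.3, 1.2)
    y <- 1.3 * x - 0.1 + rnorm(n, 0, 0.05)
    pb <- passing_bablok(x, y)
    or <- pb_oracle(x, y)
    expect_identical(pb$slope, or$slope)
    expect_identical(pb$intercept, or$intercept)
    expect_identical(pb$slope_ci, or$slope_ci)
    expect_identical(pb$intercept_ci, or$intercept_ci)
  }
})

test_that("Passing-Bablok is equivariant under positive affine maps of y", {
  set.seed(41)
  x <- sort(runif(25, 0.5, 1.5))
  y <- x + rnorm(25, 0, 0.02)       # all pairwise slopes near 1 (K = 0)
  base <- passing_bablok(x, y)
  a <- 1.7; b <- 0.3
  mapped <- passing_bablok(x, a * y + b)
  expect_equal(mapped$slope, a * base$slope, tolerance = 1e-12)
  expect_equal(mapped$intercept, a * base$intercept + b, tolerance = 1e-12)
})

test_that("Passing-Bablok slope inverts when the axes are swapped", {
  set.seed(42)
  x <- runif(7, 0.5, 1.5)           # C(7,2) = 21 pairwise slopes, odd
  y <- 1.4 * x + rnorm(7, 0, 0.03)
  fwd <- passing_bablok(x, y)
  bwd <- passing_bablok(y, x)
  expect_equal(fwd$slope, 1 / bwd$slope, tolerance = 1e-12)
})

test_that("degenerate Passing-Bablok inputs are rejected", {
  expect_error(passing_bablok(rep(1, 5), 1:5), "identical",
               class = "pg_compute_error")
  expect_error(passing_bablok(1:2, 1:2), "at least 3", class = "pg_input_error")
})

test_that("Bland-Altman reproduces its defining closed forms", {
  x <- c(1, 2, 3, 4, 5)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_low, 0)
  expect_equal(ba0$loa_high, 0)
  ba <- bland_altman(x, x + 0.5)
  expect_equal(ba$bias, 0.5)
  expect_equal(ba$sd_diff, 0)
  expect_equal(c(ba$loa_low, ba$loa_high), c(0.5, 0.5))
  expect_equal(ba$means, x + 0.25)
})

test_that("Bland-Altman limits match the sampling distribution at n = 10^4", {
  set.seed(77)
  x <- runif(1e4, 0.5, 1.5)
  y <- x + rnorm(1e4, 0, 0.1)
  ba <- bland_altman(x, y)
  expect_lt(abs(ba$bias), 0.003)
  expect_lt(abs(ba$loa_high - 0.196), 0.01)
})

test_that("Bland-Altman is invariant to pair order and common shifts", {
  set.seed(78)
  x <- runif(50); y <- x + rnorm(50, 0, 0.2)
  ba <- bland_altman(x, y)
  perm <- sample(50)
  ba_p <- bland_altman(x[perm], y[perm])
  expect_equal(ba_p$bias, ba$bias)
  expect_equal(ba_p$loa_high, ba$loa_high)
  ba_s <- bland_altman(x + 3, y + 3)
  expect_equal(ba_s$bias, ba$bias)
  expect_equal(ba_s$sd_diff, ba$sd_diff)
})

test_that("ICC(1,1) matches the one-way ANOVA closed form on a 6x3 matrix", {
  m <- matrix(c(1.10, 1.12, 1.08,
                0.95, 0.99, 0.97,
                1.30, 1.25, 1.28,
                1.02, 1.05, 1.00,
                0.88, 0.91, 0.90,
                1.18, 1.15, 1.20), nrow = 6, byrow = TRUE)
  r <- icc_1_1(m)
  expect_equal(r$icc, 0.975246132208157, tolerance = 1e-12)
  expect_equal(r$icc, icc_oracle_aov(m), tolerance = 1e-12)
  expect_equal(r$label, "excellent")
  expect_equal(r$n_subjects, 6)
  expect_equal(r$k_measures, 3)
})

test_that("ICC(1,1) boundary regimes behave as the model dictates", {
  # perfect repeatability with between-subject spread
  m1 <- matrix(rep(c(1.0, 1.2, 0.9, 1.4), each = 3), ncol = 3, byrow = TRUE)
  r1 <- icc_1_1(m1)
  expect_equal(r1$icc, 1)
  expect_equal(r1$label, "excellent")
  # identical subject means, within-subject noise only
  m2 <- rbind(c(0.9, 1.1, 1.0), c(1.1, 0.9, 1.0), c(1.0, 0.9, 1.1))
  r2 <- icc_1_1(m2)
  expect_lte(r2$icc, 0)
  expect_equal(r2$label, "poor")
})

test_that("ICC(1,1) stays within its admissible range on random matrices", {
  set.seed(55)
  for (i in 1:1000) {
    n <- sample(2:8, 1)
    k <- sample(2:5, 1)
    m <- matrix(rnorm(n * k), n, k)
    icc <- icc_1_1(m)$icc
    expect_gte(icc, -1 / (k - 1) - 1e-12)
    expect_lte(icc, 1 + 1e-12)
  }
})

test_that("rows with missing measures are dropped and counted", {
  m <- matrix(runif(12), 4, 3)
  m[2, 1] <- NA
  r <- icc_1_1(m)
  expect_equal(r$n_dropped, 1)
  expect_equal(r$n_subjects, 3)
  m[, 1] <- NA
  expect_error(icc_1_1(m[1:2, ]), "complete", class = "pg_input_error")
})

test_that("reliability bands follow the lower-inclusive convention", {
  expect_equal(classify_reliability(0.86), "excellent")
  expect_equal(classify_reliability(0.76), "excellent")
  expect_equal(classify_reliability(0.75), "good")
  expect_equal(classify_reliability(0.64), "good")
  expect_equal(classify_reliability(0.60), "good")
  expect_equal(classify_reliability(0.59), "fair")
  expect_equal(classify_reliability(0.40), "fair")
  expect_equal(classify_reliability(0.39), "poor")
  expect_equal(classify_reliability(-0.2), "poor")
  expect_error(classify_reliability(NaN), "finite", class = "pg_input_error")
})
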