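test_that("descriptive statistics use the sample (n-1) convention", {
  d <- descriptive(c(1, 2, 3))
  expect_equal(d$mean, 2)
  expect_equal(d$sd, 1)
  expect_equal(c(d$min, d$max), c(1, 3))
  expect_equal(descriptive(rep(4, 5))$sd, 0)
  expect_error(descriptive(3), "n >= 2")
})

test_that("partial correlation matches the closed-form recursion", {
  set.seed(11)
  for (rep in 1:20) {
    n <- 6 + rep
    x <- rnorm(n); y <- rnorm(n); z <- rnorm(n)
    pc <- partial_correlation(x, y, z)
    rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
    r_ref <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
    expect_equal(pc$r, r_ref, tolerance = 1e-10)
    expect_equal(pc$df, n - 3)
    # symmetry and affine invariance
    expect_equal(partial_correlation(y, x, z)$r, pc$r, tolerance = 1e-12)
    expect_equal(partial_correlation(2 * x - 7, y / 3 + 1, 5 * z - 2)$r,
                 pc$r, tolerance = 1e-10)
  }
})

test_that("perfect dependence and degenerate inputs behave per contract", {
  x <- c(1, 3, 2, 5, 4, 6)
  z <- c(2, 1, 4, 3, 6, 5)
  expect_equal(partial_correlation(x, x, z)$r, 1)
  expect_error(partial_correlation(rep(1, 6), x, z), "constant")
  expect_error(partial_correlation(x[1:3], x[1:3], z[1:3]), "n >= 4")
  expect_error(partial_correlation(x, x[1:5], z), "equal length")
})

test_that("p-values follow the t reference distribution", {
  set.seed(21)
  n <- 40
  x <- rnorm(n); y <- rnorm(n); z <- rnorm(n)
  pc <- partial_correlation(x, y, z)
  expect_equal(pc$p,
               2 * pt(abs(pc$r * sqrt((n - 3) / (1 - pc$r^2))), n - 3,
                      lower.tail = FALSE))
  expect_true(pc$p >= 0 && pc$p <= 1)
})

test_that("the correlation panel reports all four adjusted pairs", {
  rec <- simulate_cohort_records(50, partial_r = 0.6, seed = 2)
  panel <- run_correlation_panel(rec)
  expect_equal(nrow(panel), 4)
  expect_setequal(panel$independent,
                  c("FSU_L1L3", "BMD_L1L3", "Displacement_L1L3", "Load_L1L3"))
  expect_true(all(panel$df == nrow(rec) - 3))
  expect_error(run_correlation_panel(rec[1:3, ]), ">= 4")
  expect_error(run_correlation_panel(rec[, -2]), "lack columns")
})

test_that("a constant covariate reduces to the Pearson correlation", {
  rec <- simulate_cohort_records(40, partial_r = 0.5, seed = 3)
  rec$bmd_ratio <- 1
  panel <- run_correlation_panel(rec)
  expect_equal(panel$r[panel$independent == "FSU_L1L3"],
               cor(rec$fsu_f, rec$fsu_l1l3), tolerance = 1e-10)
})

test_that("built-in partial correlation is recovered from generated cohorts", {
  rec <- simulate_cohort_records(200, partial_r = 0.8, seed = 4)
  panel <- run_correlation_panel(rec)
  expect_true(all(abs(panel$r - 0.8) < 0.1))
})
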