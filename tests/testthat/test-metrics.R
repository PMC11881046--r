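ref_exp <- bcp_reference()$e_exp

test_that("signed and absolute error metrics match loop oracles", {
  expect_equal(mse(ref_exp, ref_exp), 0)
  expect_equal(mse(ref_exp + 0.1, ref_exp), 0.1)
  # constant-zero predictor against the reference: minus its mean
  expect_equal(mse(rep(0, 12), ref_exp), -0.4426, tolerance = 1e-4)

  expect_equal(mad(ref_exp, ref_exp), 0)
  expect_equal(max_abs(ref_exp, ref_exp), 0)
  expect_equal(mad(c(0.1, -0.1) + 1:2, 1:2), 0.1)
  expect_equal(max_abs(c(0.1, -0.1) + 1:2, 1:2), 0.1)

  set.seed(11)
  for (i in 1:10) {
    calc <- rnorm(12); exp <- rnorm(12)
    expect_equal(mad(calc, exp), mad_oracle(calc, exp))
    expect_equal(max_abs(calc, exp), max_oracle(calc, exp))
    expect_true(max_abs(calc, exp) >= mad(calc, exp))
  }
  expect_error(mse(1:3, 1:4), "equal length")
})

test_that("trimmed deviations are shift-invariant and bounded by each other", {
  expect_equal(madtr(ref_exp - 0.7, ref_exp), 0)
  expect_equal(maxtr(ref_exp - 0.7, ref_exp), 0)
  set.seed(12)
  for (i in 1:10) {
    calc <- rnorm(12); shift <- runif(1, -5, 5)
    expect_equal(madtr(calc + shift, ref_exp), madtr(calc, ref_exp))
    expect_equal(maxtr(calc + shift, ref_exp), maxtr(calc, ref_exp))
    expect_true(maxtr(calc, ref_exp) >= madtr(calc, ref_exp))
  }
})

test_that("range metrics measure spread and its deviation from experiment", {
  expect_equal(range_calc(ref_exp), 0.558) # 0.798 - 0.240
  expect_equal(range_calc(rep(0.3, 5)), 0)
  expect_equal(rel_range(ref_exp, 0.558), 0)
  expect_equal(rel_range(c(0, 1), 0.6), 0.4)
  # the printed-constant override is just a different pinned range
  expect_equal(rel_range(ref_exp, 0.568), 0.01, tolerance = 1e-12)
})

test_that("calibration slope and R2 match lm()/cor() on noisy lines", {
  sr <- slope_r2(2 * ref_exp + 0.3, ref_exp)
  expect_equal(sr$slope, 2)
  expect_equal(sr$r2, 1)
  sr0 <- slope_r2(rep(0.5, 12), ref_exp)
  expect_equal(sr0$slope, 0)
  expect_equal(sr0$r2, 0)
  set.seed(13)
  for (i in 1:10) {
    calc <- 0.8 * ref_exp + rnorm(12, 0, 0.1)
    sr <- slope_r2(calc, ref_exp)
    expect_equal(sr$slope, slope_oracle(calc, ref_exp))
    expect_equal(sr$r2, cor(calc, ref_exp)^2)
  }
  expect_error(slope_r2(1:3, rep(1, 3)), "degenerate")
})

test_that("rel_slope penalises over- and under-scaling symmetrically", {
  expect_equal(rel_slope(1), 0)
  expect_equal(rel_slope(2), 0.5)
  expect_equal(rel_slope(0.5), 0.5)
  expect_equal(rel_slope(-0.3), 1)
  expect_equal(rel_slope(0), 1)
  ks <- exp(seq(log(0.05), log(20), length.out = 41))
  expect_equal(rel_slope(ks), rel_slope(1 / ks))
  # monotone increase as k departs from 1 in either direction
  up <- rel_slope(seq(1, 10, by = 0.5))
  down <- rel_slope(seq(1, 0.05, by = -0.05))
  expect_true(all(diff(up) > 0))
  expect_true(all(diff(down) > 0))
  expect_true(all(rel_slope(ks) >= 0 & rel_slope(ks) <= 1))
})

test_that("rank correlations agree with exhaustive pair enumeration", {
  expect_equal(spearman_rho(ref_exp * 2 + 1, ref_exp), 1)
  expect_equal(kendall_tau(ref_exp * 2 + 1, ref_exp), 1)
  expect_equal(spearman_rho(-ref_exp, ref_exp), -1)
  expect_equal(kendall_tau(-ref_exp, ref_exp), -1)

  set.seed(14)
  for (n in 3:8) {
    for (i in 1:20) {
      # integer draws force ties so the tau-b correction is exercised
      x <- sample(1:4, n, replace = TRUE)
      y <- sample(1:4, n, replace = TRUE)
      if (length(unique(x)) == 1L || length(unique(y)) == 1L) next
      expect_equal(kendall_tau(x, y), tau_oracle(x, y),
                   info = paste("n =", n))
    }
  }
  # invariance under strictly monotone transforms of calc
  set.seed(15)
  calc <- rnorm(12)
  expect_equal(kendall_tau(exp(calc), ref_exp), kendall_tau(calc, ref_exp))
  expect_equal(spearman_rho(calc^3, ref_exp), spearman_rho(calc, ref_exp))
})

test_that("metric_set assembles all twelve fields consistently", {
  perfect <- metric_set(ref_exp, ref_exp)
  for (col in c("mse", "mad", "max_abs", "madtr", "maxtr", "rel_range",
                "rel_slope")) {
    expect_equal(perfect[[col]], 0, info = col)
  }
  for (col in c("slope", "r2", "rho", "tau")) {
    expect_equal(perfect[[col]], 1, info = col)
  }

  # constant predictor: correlations, slope and range all zero by convention
  const <- metric_set(rep(0.44, 12), ref_exp)
  for (col in c("r2", "rho", "tau", "slope", "range_calc")) {
    expect_equal(const[[col]], 0, info = col)
  }

  # exact affine prediction: closed-form mse and slope, perfect correlation
  a <- -0.9; b <- 1.4
  ms <- metric_set(a + b * ref_exp, ref_exp)
  expect_equal(ms$mse, a + (b - 1) * mean(ref_exp))
  expect_equal(ms$slope, b)
  expect_equal(ms$r2, 1)
  expect_equal(ms$tau, 1)
  expect_equal(ms$range_calc, b * 0.558)
})

test_that("shift invariance holds across the whole metric set", {
  set.seed(16)
  calc <- rnorm(12, 0, 0.4)
  base <- metric_set(calc, ref_exp)
  shifted <- metric_set(calc + 1.23, ref_exp)
  expect_equal(shifted$mse, base$mse + 1.23)
  for (col in c("madtr", "maxtr", "range_calc", "rel_range", "slope",
                "rel_slope", "r2", "rho", "tau")) {
    expect_equal(shifted[[col]], base[[col]], info = col)
  }
})
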