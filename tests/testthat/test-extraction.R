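test_that("touch mask applies the four-times-noise rule exactly", {
  n <- 200
  t <- (0:(n - 1)) / 50
  fn <- rep(0, n)
  tr <- force_trace(t, rep(0, n), rep(0, n), fn)
  expect_false(any(touch_mask(tr, noise_level = 0.01)))

  # step from 0.02 N to 1.0 N with noise 0.01 N: threshold is 0.04 N
  fn2 <- c(rep(0.02, 100), rep(1.0, 100))
  tr2 <- force_trace(t, rep(0.1, n), rep(0, n), fn2)
  mask <- touch_mask(tr2, noise_level = 0.01)
  expect_identical(mask, fn2 > 0.04)
  expect_equal(sum(mask), 100)

  expect_error(touch_mask(tr2, noise_level = 0), "positive")
})

test_that("noise is estimated from the leading idle second when not supplied", {
  tr <- generate_force_trace(0.9, trial_config(sensor_noise_sd_n = 0.02),
                             seed = 4)
  est <- estimate_sensor_noise(tr)
  expect_lt(abs(est - 0.02), 0.005)
  fs <- friction_coefficient(tr)
  expect_equal(fs$noise_estimate, est)
})

test_that("friction summary computes FF/FN on touch samples only", {
  # 3-4-5 triangle: FF = 1.0 at FN = 1.0 -> mu = 1
  n <- 300
  t <- (0:(n - 1)) / 50
  tr <- force_trace(t, rep(0.6, n), rep(0.8, n), rep(1.0, n))
  fs <- friction_coefficient(tr, noise_level = 0.01)
  expect_equal(fs$mu_median, 1.0)
  expect_equal(fs$fn_in_range_fraction, 1.0)
  expect_equal(fs$touch_fraction, 1.0)

  # idle samples are excluded: contaminate flanks with junk below threshold
  fn <- c(rep(0.02, 50), rep(1.0, 200), rep(0.02, 50))
  fx <- c(rep(5, 50), rep(0.6, 200), rep(5, 50))
  fy <- c(rep(5, 50), rep(0.8, 200), rep(5, 50))
  tr2 <- force_trace(t, fx, fy, fn)
  expect_equal(friction_coefficient(tr2, noise_level = 0.01)$mu_median, 1.0)
})

test_that("mu is invariant under common positive rescaling and idle length", {
  tr <- generate_force_trace(1.1, trial_config(), seed = 33)
  base <- friction_coefficient(tr, noise_level = 0.01)$mu_median
  scaled <- force_trace(tr$t_s, 3 * tr$Fx_N, 3 * tr$Fy_N, 3 * tr$FN_N)
  expect_equal(friction_coefficient(scaled, noise_level = 0.03)$mu_median,
               base, tolerance = 1e-12)

  long_idle <- generate_force_trace(
    1.1, trial_config(duration_s = 40, pre_post_idle_s = 7), seed = 33)
  short_idle <- generate_force_trace(
    1.1, trial_config(duration_s = 28, pre_post_idle_s = 1), seed = 33)
  expect_equal(
    friction_coefficient(long_idle, noise_level = 0.01)$mu_median,
    friction_coefficient(short_idle, noise_level = 0.01)$mu_median,
    tolerance = 0.01)
})

test_that("the median summary resists 10% outlier contamination", {
  tr <- generate_force_trace(0.92, trial_config(), seed = 55)
  clean <- friction_coefficient(tr, noise_level = 0.01)$mu_median
  mask <- touch_mask(tr, 0.01)
  idx <- sample(which(mask), round(0.1 * sum(mask)))
  dirty <- tr
  dirty$Fx_N[idx] <- dirty$Fx_N[idx] + 5  # gross outliers
  got <- friction_coefficient(dirty, noise_level = 0.01)$mu_median
  expect_lt(abs(got - clean) / clean, 0.05)
})

test_that("missing trials and degenerate inputs are reported, not computed", {
  n <- 100
  t <- (0:(n - 1)) / 50
  silent <- force_trace(t, rnorm(n, 0, 0.01), rnorm(n, 0, 0.01),
                        rnorm(n, 0, 0.01))
  fs <- friction_coefficient(silent, noise_level = 0.01)
  expect_true(fs$missing)
  expect_true(is.na(fs$mu_median))

  # constant-direction friction: no rotation -> zero cycles
  tr <- force_trace(t, rep(0.9, n), rep(0, n), rep(1, n))
  cyc <- cycle_rate(tr, rep(TRUE, n))
  expect_equal(cyc$n_cycles, 0)

  # degenerate tangential forces -> rate missing
  tr0 <- force_trace(t, rep(0, n), rep(0, n), rep(1, n))
  expect_true(is.na(cycle_rate(tr0, rep(TRUE, n))$n_cycles))

  # non-uniform sampling is rejected at construction
  tbad <- t; tbad[50] <- tbad[50] + 0.015
  expect_error(force_trace(tbad, rep(1, n), rep(1, n), rep(1, n)),
               "non-uniform|increasing")
})

test_that("synthetic circular traces count cycles by phase unwrapping", {
  fs <- 50; dur <- 25
  t <- (0:(dur * fs - 1)) / fs
  theta <- 2 * pi * 0.4 * t
  tr <- force_trace(t, 0.9 * cos(theta), 0.9 * sin(theta), rep(1, length(t)))
  cyc <- cycle_rate(tr, rep(TRUE, length(t)))
  expect_equal(cyc$n_cycles, 10, tolerance = 0.01)
  expect_equal(cyc$cycle_rate, 0.4, tolerance = 0.008)
})

test_that("force traces survive a CSV round trip", {
  tr <- generate_force_trace(0.8, trial_config(duration_s = 16), seed = 2)
  path <- tempfile(fileext = ".csv")
  write_force_trace(tr, path)
  back <- read_force_trace(path)
  expect_equal(as.data.frame(back), as.data.frame(tr), tolerance = 1e-9)
  expect_error(read_force_trace({
    p <- tempfile(); writeLines("a,b\n1,2", p); p
  }), "columns")
})
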