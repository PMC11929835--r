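test_that("pillar density matches the hexagonal closed form and a counting oracle", {
  expect_equal(pillar_density(40), 1 / (2 * sqrt(3) * 0.04^2))
  expect_equal(round(pillar_density(40)), 180)
  expect_equal(pillar_density(150), 12.8, tolerance = 0.01)
  # quadratic scaling
  expect_equal(pillar_density(80), pillar_density(40) / 4)
  expect_error(pillar_density(-1), "positive")

  # counting oracle: enumerate lattice points of a hexagonal lattice with
  # constant a = 2D in a large patch
  d_um <- 100; a <- 2 * d_um / 1000  # lattice constant in mm
  side <- 40  # mm: large patch keeps the boundary error well under 1%
  i <- seq(-500, 500)
  pts <- expand.grid(i = i, j = i)
  x <- a * (pts$i + 0.5 * pts$j)
  y <- a * (sqrt(3) / 2) * pts$j
  inside <- x >= 0 & x < side & y >= 0 & y < side
  expect_gt(sum(inside), 100)
  counted <- sum(inside) / side^2
  expect_equal(counted, pillar_density(d_um), tolerance = 0.01)
})

test_that("bending stiffness follows pi E D^4 / (32 L^2)", {
  s100 <- micropillar_sample("100/100", 100, 100)
  s300 <- micropillar_sample("100/300", 100, 300)
  expect_equal(bending_stiffness(s100) / bending_stiffness(s300), 9)
  expect_equal(bending_stiffness(100, 100), 1.67e-3, tolerance = 0.002)

  tab <- micropillar_samples()
  expect_equal(tab$label[which.min(tab$stiffness_n_per_rad)], "40/120")
  expect_equal(tab$label[which.max(tab$stiffness_n_per_rad)], "150/150")

  # strictly increasing in D, strictly decreasing in L
  ds <- seq(40, 200, by = 20)
  expect_true(all(diff(bending_stiffness(ds, 150)) > 0))
  ls <- seq(100, 400, by = 50)
  expect_true(all(diff(vapply(ls, function(l)
    bending_stiffness(100, l), numeric(1))) < 0))
})

test_that("self-affine synthesis hits Sq exactly and has the right spectrum", {
  hm <- synthesize_self_affine_surface(0.4, 0.8, n_grid = 256, dx_mm = 0.1,
                                       seed = 12)
  expect_equal(rms_roughness(hm), 0.4, tolerance = 1e-12)

  psd <- radial_psd(hm)
  fit <- lm(log(psd$psd) ~ log(psd$q))
  expect_equal(unname(coef(fit)[2]), -2 - 2 * 0.8, tolerance = 0.2)

  expect_error(
    synthesize_self_affine_surface(0.4, 0.8, n_grid = 64, dx_mm = 0.3,
                                   lambda_short_mm = 0.5),
    "cutoff")
  expect_error(
    synthesize_self_affine_surface(0.4, 0.8, n_grid = 100), "power of two")
})

test_that("rms curvature decreases with Hurst exponent at fixed Sq", {
  curv <- vapply(c(0.4, 0.6, 0.8), function(h) {
    mean(vapply(1:3, function(s)
      rms_curvature(synthesize_self_affine_surface(0.4, h, n_grid = 128,
                                                   dx_mm = 0.1,
                                                   seed = 100 + s)),
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(curv) < 0))
})

test_that("rms curvature matches analytic and brute-force oracles", {
  # affine plane -> zero curvature
  n <- 64; dx <- 0.1
  xg <- outer(seq_len(n), rep(1, n)) * dx
  yg <- t(xg)
  plane <- 0.3 + 0.2 * xg - 0.7 * yg
  expect_lt(rms_curvature(plane, dx_mm = dx), 1e-10)

  # sinusoid h = A sin(qx): rms second derivative A q^2 / sqrt(2)
  A <- 0.4; lam <- 0.5; q <- 2 * pi / lam
  nn <- 1000; dxs <- lam / 200  # fine grid, integer periods
  xs <- (seq_len(nn) - 1) * dxs
  h <- outer(A * sin(q * xs), rep(1, 50))
  analytic <- A * q^2 / sqrt(2)
  expect_equal(analytic, 44.68, tolerance = 0.001)
  expect_equal(rms_curvature(h, dx_mm = dxs), analytic, tolerance = 1e-3)

  # invariance under adding an affine plane
  hm <- synthesize_self_affine_surface(0.4, 0.6, n_grid = 64, dx_mm = 0.1,
                                       seed = 9)
  tilted <- hm$h + 0.5 + 0.1 * xg - 0.05 * yg
  expect_equal(rms_curvature(tilted, dx_mm = 0.1), rms_curvature(hm),
               tolerance = 1e-10)

  # independent brute-force loop over interior nodes
  brute <- function(h, dx) {
    n <- nrow(h); m <- ncol(h)
    sx <- 0; cx <- 0
    for (i in 2:(n - 1)) for (j in 1:m) {
      sx <- sx + ((h[i - 1, j] - 2 * h[i, j] + h[i + 1, j]) / dx^2)^2
      cx <- cx + 1
    }
    sy <- 0; cy <- 0
    for (i in 1:n) for (j in 2:(m - 1)) {
      sy <- sy + ((h[i, j - 1] - 2 * h[i, j] + h[i, j + 1]) / dx^2)^2
      cy <- cy + 1
    }
    sqrt(sx / cx + sy / cy)
  }
  small <- synthesize_self_affine_surface(0.4, 0.5, n_grid = 32, dx_mm = 0.15,
                                          lambda_long_mm = 2.4, seed = 4)
  expect_equal(rms_curvature(small), brute(small$h, small$dx_mm),
               tolerance = 1e-12)
})

test_that("height maps survive a CSV round trip", {
  hm <- synthesize_self_affine_surface(0.4, 0.6, n_grid = 32, dx_mm = 0.12,
                                       lambda_long_mm = 1.9, seed = 3)
  path <- tempfile(fileext = ".csv")
  write_height_map(hm, path)
  back <- read_height_map(path)
  expect_equal(back$h, hm$h, tolerance = 1e-9)
  expect_equal(back$dx_mm, hm$dx_mm)
  expect_equal(back$hurst, hm$hurst)
  expect_equal(rms_curvature(back), rms_curvature(hm), tolerance = 1e-9)
})
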