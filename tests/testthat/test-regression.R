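test_that("ols_fit matches the normal-equations oracle", {
  set.seed(41)
  n <- 80
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- 1 + 2 * X$a - 0.5 * X$b + rnorm(n)
  fit <- ols_fit(X, y)
  Xm <- cbind(1, as.matrix(X))
  beta <- solve(t(Xm) %*% Xm, t(Xm) %*% y)
  expect_equal(unname(coef(fit)), as.numeric(beta), tolerance = 1e-8)
  expect_equal(fit$df_resid, n - 3 - 1)

  # exact linear outcome
  fit2 <- ols_fit(X, 3 + X$a + X$b + X$c)
  expect_equal(fit2$r_squared, 1, tolerance = 1e-12)
  expect_lt(max(abs(residuals(fit2))), 1e-10)

  # rank deficiency names the offending column
  X$dup <- X$a
  expect_error(ols_fit(X, y), "dup")
})

test_that("Johnson weights sum to R^2 and collapse to r^2 under orthogonality", {
  # exactly orthogonal predictors
  Q <- orthogonal_predictors(100, 3, seed = 2)
  set.seed(3)
  y <- 0.6 * Q[, 1] + 0.3 * Q[, 2] + rnorm(100, 0, 0.5)
  rw <- johnson_relative_weights(as.data.frame(Q), y)
  r2y <- as.numeric(cor(Q, y))^2
  expect_equal(unname(rw$raw_weights), r2y, tolerance = 1e-10)
  expect_equal(sum(rw$raw_weights), rw$r_squared, tolerance = 1e-10)

  # correlated predictors: identity with ols R^2 holds to 1e-8
  co <- fixture_cohort(400, 23)
  X <- co[, c("sc_hydration", "ue", "r2", "sc_thickness")]
  mu <- generate_friction_coefficients(co, friction_model_config(seed = 24))
  y2 <- rowMeans(mu[, paste0("mu_", rough_sample_labels())])
  rw2 <- johnson_relative_weights(X, y2)
  expect_equal(sum(rw2$raw_weights), ols_fit(X, y2)$r_squared,
               tolerance = 1e-8)
  expect_true(all(rw2$raw_weights >= 0))
  expect_equal(sum(rw2$rescaled_pct), 100, tolerance = 1e-8)
})

test_that("two-predictor Johnson weights match the symbolic eigen solution", {
  set.seed(61)
  n <- 150
  x1 <- rnorm(n)
  x2 <- 0.6 * x1 + 0.8 * rnorm(n)
  y <- x1 + 0.5 * x2 + rnorm(n)
  rw <- johnson_relative_weights(data.frame(x1 = x1, x2 = x2), y)

  # closed form: eigenvectors of a 2x2 correlation matrix are fixed at
  # (1,1)/sqrt(2) and (1,-1)/sqrt(2) with eigenvalues 1 +/- r12
  z1 <- as.numeric(scale(x1)); z2 <- as.numeric(scale(x2))
  zy <- as.numeric(scale(y))
  r12 <- cor(z1, z2); r1y <- cor(z1, zy); r2y <- cor(z2, zy)
  a <- (sqrt(1 + r12) + sqrt(1 - r12)) / 2  # diagonal of Lambda
  b <- (sqrt(1 + r12) - sqrt(1 - r12)) / 2  # off-diagonal
  det_l <- a^2 - b^2
  beta1 <- (a * r1y - b * r2y) / det_l
  beta2 <- (a * r2y - b * r1y) / det_l
  eps1 <- a^2 * beta1^2 + b^2 * beta2^2
  eps2 <- b^2 * beta1^2 + a^2 * beta2^2
  expect_equal(unname(rw$raw_weights), c(eps1, eps2), tolerance = 1e-10)
})

test_that("relative weights are invariant to affine predictor rescaling", {
  co <- fixture_cohort(300, 29)
  X <- co[, c("sc_hydration", "ue", "r2", "sc_thickness")]
  y <- zscore(co$sc_hydration) + 0.5 * zscore(co$ue) + rnorm(300, 0, 0.8)
  rw1 <- johnson_relative_weights(X, y)
  X2 <- X
  X2$sc_hydration <- 1000 + 0.01 * X2$sc_hydration
  X2$ue <- -X2$ue  # sign flip: weights are squared quantities
  rw2 <- johnson_relative_weights(X2, y)
  expect_equal(unname(rw1$raw_weights), unname(rw2$raw_weights),
               tolerance = 1e-10)
})

test_that("interaction_model recovers sign and gains explained variance", {
  # exactly additive outcome -> zero interaction coefficient
  set.seed(71)
  x1 <- rnorm(60); x2 <- rnorm(60)
  fit0 <- interaction_model(x1, x2, x1 + x2)
  expect_equal(fit0$interaction[["coefficient"]], 0, tolerance = 1e-10)
  expect_equal(fit0$delta_r2, 0, tolerance = 1e-10)

  # planted negative interaction recovered in >= 95% of replicates
  hits <- vapply(1:200, function(i) {
    set.seed(1000 + i)
    a <- rnorm(60); b <- rnorm(60)
    yy <- a + b - 0.5 * a * b + rnorm(60, 0, 0.8)
    f <- interaction_model(a, b, yy)
    f$interaction[["coefficient"]] < 0 && f$delta_r2 > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("per-sample batch regressions reuse the same math", {
  co <- fixture_cohort(200, 83)
  mu <- generate_friction_coefficients(co, friction_model_config(seed = 84))
  X <- co[, c("sc_hydration", "ue", "r2", "sc_thickness")]
  cols <- paste0("mu_", c("S01", "S09"))
  batch <- sample_regressions(mu[, cols], X)
  expect_equal(nrow(batch), 2)
  one <- johnson_relative_weights(X, mu$mu_S01)
  expect_equal(batch$r_squared[1], one$r_squared)
  expect_equal(unname(unlist(batch[1, paste0("wt_", names(X))])),
               unname(one$rescaled_pct))
})
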