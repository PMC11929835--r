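make_block_data <- function(n = 200, seed = 13, loading = 0.9) {
  set.seed(seed)
  f <- matrix(rnorm(n * 3), n)
  noise_sd <- sqrt(1 - loading^2)
  X <- do.call(cbind, lapply(1:3, function(b)
    sapply(1:3, function(j) loading * f[, b] + rnorm(n, 0, noise_sd))))
  colnames(X) <- paste0("v", 1:9)
  X
}

test_that("KMO is high for block-structured data and always within [0, 1]", {
  set.seed(7)
  n <- 300
  f1 <- rnorm(n); f2 <- rnorm(n)
  X <- cbind(f1 + rnorm(n, 0, 0.3), f1 + rnorm(n, 0, 0.3),
             f1 + rnorm(n, 0, 0.3),
             f2 + rnorm(n, 0, 0.3), f2 + rnorm(n, 0, 0.3),
             f2 + rnorm(n, 0, 0.3))
  expect_gt(kmo_score(X), 0.5)

  for (i in 1:5) {
    set.seed(i)
    Y <- matrix(rnorm(50 * 4), 50)
    k <- kmo_score(Y)
    expect_gte(k, 0)
    expect_lte(k, 1)
  }
})

test_that("KMO and Bartlett are invariant to affine rescaling of columns", {
  X <- make_block_data()
  Y <- X
  Y[, 1] <- 100 + 7 * Y[, 1]
  Y[, 5] <- -2 * Y[, 5]
  expect_equal(kmo_score(X), kmo_score(Y), tolerance = 1e-10)
  expect_equal(bartlett_sphericity(X)$chi2, bartlett_sphericity(Y)$chi2,
               tolerance = 1e-10)
})

test_that("Bartlett sphericity matches the determinant formula and nulls out", {
  # identity correlation -> chi2 exactly 0
  expect_equal(bartlett_sphericity(diag(4), n = 50)$chi2, 0)

  X <- make_block_data(n = 120, seed = 31)
  got <- bartlett_sphericity(X)
  # independent oracle: determinant via eigenvalue product
  R <- cor(X)
  n <- nrow(X); p <- ncol(X)
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * sum(log(eigen(R)$values))
  expect_equal(got$chi2, chi2, tolerance = 1e-8)
  expect_equal(got$df, p * (p - 1) / 2)
  expect_lt(got$p, 1e-6)
  expect_error(bartlett_sphericity(matrix(rnorm(20), 4, 5)), "more observations")
})

test_that("pca_varimax recovers planted orthogonal block structure", {
  X <- make_block_data(n = 400, seed = 77)
  fit <- pca_varimax(X)
  expect_equal(fit$n_components, 3)
  # each variable loads > 0.8 on its own block component, < 0.2 elsewhere
  blocks <- rep(1:3, each = 3)
  for (v in 1:9) {
    own <- which.max(abs(fit$loadings[v, ]))
    expect_gt(abs(fit$loadings[v, own]), 0.8)
    expect_lt(max(abs(fit$loadings[v, -own])), 0.2)
  }
  # variables of the same block share a component
  comp_of <- apply(abs(fit$loadings), 1, which.max)
  expect_equal(length(unique(tapply(comp_of, blocks, unique))), 3)
})

test_that("varimax rotation preserves communalities and cross-products", {
  X <- make_block_data(n = 150, seed = 5)
  fit <- pca_varimax(X)
  h_rot <- rowSums(fit$loadings^2)
  h_unrot <- rowSums(fit$unrotated_loadings^2)
  expect_equal(unname(h_rot), unname(h_unrot), tolerance = 1e-8)
  expect_equal(fit$loadings %*% t(fit$loadings),
               fit$unrotated_loadings %*% t(fit$unrotated_loadings),
               tolerance = 1e-8, ignore_attr = TRUE)
  # rotation matrix is orthogonal
  expect_equal(t(fit$rotation) %*% fit$rotation, diag(fit$n_components),
               tolerance = 1e-8)
  # sign convention: dominant loading of every component is positive
  expect_true(all(apply(fit$loadings, 2, function(l) l[which.max(abs(l))]) > 0))
  # cumulative variance bounded by 100
  expect_lte(max(fit$cumulative_pct), 100 + 1e-8)
  expect_error(pca_varimax(cbind(X, const = 1)), "zero-variance")
})

test_that("Bartlett factor scores reproduce latent factors on clean data", {
  X <- make_block_data(n = 500, seed = 99, loading = 0.95)
  fit <- pca_varimax(X)
  # scores should correlate strongly with the block means
  blocks <- rep(1:3, each = 3)
  for (b in 1:3) {
    bm <- rowMeans(X[, blocks == b])
    best <- max(abs(cor(fit$scores, bm)))
    expect_gt(best, 0.95)
  }
  expect_equal(colMeans(fit$scores), rep(0, 3), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("composites implement the loading-threshold rule", {
  co <- fixture_cohort(500, 9)
  mu <- generate_friction_coefficients(co, friction_model_config(seed = 10))
  set.seed(11)
  pillar <- runif(500)
  twopt <- sample(2:8, 500, replace = TRUE)
  comp <- build_composites(mu, pillar, twopt)

  rough_cols <- paste0("mu_", rough_sample_labels())
  expect_equal(comp$mu_rough, rowMeans(mu[, rough_cols]))
  fib_cols <- paste0("mu_", gsub("/", "_", fibril_sample_labels()))
  expect_equal(comp$mu_fibril, rowMeans(mu[, fib_cols]))
  # aspect-ratio-1 samples excluded from both composites
  expect_false(any(grepl("100_100|150_150", c(rough_cols, fib_cols))))

  # s_perc is centered and unit-insensitive (mm -> cm)
  expect_equal(mean(comp$s_perc), 0, tolerance = 1e-12)
  comp_cm <- build_composites(mu, pillar, twopt / 10)
  expect_equal(comp$s_perc, comp_cm$s_perc, tolerance = 1e-12)

  # participant at the cohort mean of both measures scores 0
  pillar2 <- c(mean(pillar), pillar[-1])
  twopt2 <- c(mean(twopt), twopt[-1])
  comp2 <- build_composites(mu, pillar2, twopt2)
  z <- function(x) (x[1] - mean(x)) / sd(x)
  expect_equal(comp2$s_perc[1],
               mean(c(z(pillar2), -z(twopt2))), tolerance = 1e-12)

  expect_error(build_composites(mu[, 1:5], pillar, twopt), "missing sample")
})

test_that("PCA separates rough and fibrillar friction into distinct components", {
  co <- fixture_cohort(300, 17)
  mu <- generate_friction_coefficients(co, friction_model_config(seed = 18))
  cols <- c(paste0("mu_", rough_sample_labels()),
            paste0("mu_", gsub("/", "_", fibril_sample_labels())))
  fit <- pca_varimax(mu[, cols])
  rough_idx <- 1:6; fib_idx <- 7:10
  comp_rough <- which.max(colSums(abs(fit$loadings[rough_idx, , drop = FALSE])))
  comp_fib <- which.max(colSums(abs(fit$loadings[fib_idx, , drop = FALSE])))
  expect_false(comp_rough == comp_fib)
  expect_true(all(abs(fit$loadings[rough_idx, comp_fib]) < 0.5))
  expect_true(all(abs(fit$loadings[fib_idx, comp_rough]) < 0.5))
})
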