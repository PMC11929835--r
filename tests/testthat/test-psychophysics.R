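test_that("the psychometric curve starts at chance and its JND inverts analytically", {
  for (k in c(0.5, 5.55, 40)) for (d in c(0.5, 2, 6)) {
    expect_identical(weibull_p(0, k, d), 0.5)
    # p at the JND is exactly 0.75
    expect_equal(weibull_p(weibull_jnd(k, d), k, d), 0.75, tolerance = 1e-12)
  }
  expect_equal(weibull_jnd(5.55, 2), 0.150, tolerance = 1e-3)
  # jnd strictly decreasing in k at fixed d
  ks <- seq(1, 20, length.out = 10)
  expect_true(all(diff(weibull_jnd(ks, 2)) < 0))
})

test_that("fit_weibull recovers parameters from dense clean data", {
  x <- c(0.03, 0.06, 0.1, 0.15, 0.25, 0.4, 0.7)
  n <- 4000
  set.seed(21)
  succ <- rbinom(length(x), n, weibull_p(x, 5.55, 2))
  fit <- fit_weibull(x, succ, rep(n, length(x)))
  expect_equal(fit$k, 5.55, tolerance = 0.1)
  expect_equal(fit$d, 2, tolerance = 0.15)
  expect_equal(fit$jnd, 0.15, tolerance = 0.01)
  expect_false(fit$boundary)
  expect_equal(unname(coef(fit)), c(fit$k, fit$d))
  expect_equal(predict(fit, 0), 0.5)
})

test_that("fit_weibull is scale-equivariant and flags degenerate data", {
  x <- c(0.05, 0.1, 0.2, 0.4)
  set.seed(3)
  succ <- rbinom(4, 500, weibull_p(x, 5.55, 2))
  f1 <- fit_weibull(x, succ, rep(500, 4))
  f2 <- fit_weibull(10 * x, succ, rep(500, 4))
  expect_equal(f2$k, f1$k / 10, tolerance = 1e-4)
  expect_equal(f2$d, f1$d, tolerance = 1e-4)
  expect_equal(f2$jnd, 10 * f1$jnd, tolerance = 1e-4)

  all_correct <- fit_weibull(x, rep(500, 4), rep(500, 4))
  expect_true(all_correct$boundary)
  expect_error(fit_weibull(c(0.1, 0.1), c(5, 6), c(10, 10)), "distinct")
  expect_error(fit_weibull(c(0, 0.1), c(5, 6), c(10, 10)), "positive")
})

test_that("JND recovery at study scale is accurate in the median", {
  rel <- pair_relative_differences(rough_sample_curvatures())$rel_diff
  errs <- vapply(1:40, function(i) {
    s <- simulate_pairwise_comparisons(rel, 60, 5, k = 5.55, d = 2,
                                       seed = 4000 + i)
    fit_weibull(s$rel_diff, s$n_success, s$n_trials)$jnd - 0.15
  }, numeric(1))
  expect_lt(abs(median(errs)), 0.01)
  expect_lt(median(abs(errs)), 0.015)
})

test_that("triplet designs are balanced and randomized but reproducible", {
  labels <- rough_sample_labels()
  des <- build_triplet_design(labels, seed = 5)
  expect_equal(dim(des$triplets), c(10, 3))
  counts <- table(as.vector(des$triplets))
  expect_true(all(counts == 5))
  expect_setequal(names(counts), labels)
  expect_equal(nrow(des$pairs), 30)

  expect_identical(build_triplet_design(labels, seed = 5)$triplets,
                   des$triplets)
  expect_false(identical(build_triplet_design(labels, seed = 6)$triplets,
                         des$triplets))
  expect_error(build_triplet_design(labels[1:5]), "6")
})

test_that("a balanced 10-subset of triples exists by exhaustive enumeration", {
  triples <- t(combn(6, 3))
  subsets <- combn(20, 10)
  inc <- matrix(0L, 20, 6)
  for (i in 1:20) inc[i, triples[i, ]] <- 1L
  found <- FALSE
  for (j in seq_len(ncol(subsets))) {
    if (all(colSums(inc[subsets[, j], ]) == 5L)) { found <- TRUE; break }
  }
  expect_true(found)
})

test_that("pairwise_outcomes scores rankings against the curvature order", {
  curv <- rough_sample_curvatures()
  des <- build_triplet_design(names(curv), seed = 2)
  # rankings that always match the true curvature order -> all successes
  perfect <- lapply(seq_len(10), function(i) {
    tri <- des$triplets[i, ]
    tri[order(curv[tri])]
  })
  out <- pairwise_outcomes(perfect, curv)
  expect_true(all(out$rate == 1))
  expect_equal(sum(out$n_trials), 30)

  # fully reversed rankings -> all failures
  reversed <- lapply(perfect, rev)
  expect_true(all(pairwise_outcomes(reversed, curv)$rate == 0))

  expect_error(pairwise_outcomes(list(c("S01", "S02")), curv), "total order")
  expect_error(pairwise_outcomes(list(c("S01", "S02", "XX")), curv),
               "without a curvature")
})

test_that("random rankings give 50% success", {
  curv <- rough_sample_curvatures()
  des <- build_triplet_design(names(curv), seed = 8)
  set.seed(9)
  rankings <- lapply(rep(seq_len(10), 1000), function(i)
    sample(des$triplets[i, ]))
  out <- pairwise_outcomes(rankings, curv)
  overall <- sum(out$n_success) / sum(out$n_trials)
  expect_equal(overall, 0.5, tolerance = 0.03)
})

test_that("two-point protocol records the minimal two-point distance", {
  # perceives two at every distance >= 2, one point at 1 mm
  resp <- setNames(c(FALSE, rep(TRUE, 7)), as.character(c(0, 2:8)))
  rec <- two_point_threshold(resp, retest = function(d) d >= 2)
  expect_equal(rec$threshold_mm, 2)

  # deterministic latent threshold 3.5 mm -> recorded 4 mm
  latent <- 3.5
  resp <- setNames(c(0, 2:8) >= latent, as.character(c(0, 2:8)))
  rec <- two_point_threshold(resp, retest = function(d) d >= latent)
  expect_equal(rec$threshold_mm, 4)

  # latent below 1 mm: the 1 mm retest wins
  resp <- setNames(c(FALSE, rep(TRUE, 7)), as.character(c(0, 2:8)))
  rec <- two_point_threshold(resp, retest = function(d) d >= 0.8)
  expect_equal(rec$threshold_mm, 1)

  # never two points
  none <- setNames(rep(FALSE, 8), as.character(c(0, 2:8)))
  expect_equal(two_point_threshold(none)$threshold_mm, Inf)

  expect_error(two_point_threshold(c("2" = TRUE)), "cover")
})

test_that("detection rates come with exact Clopper-Pearson intervals", {
  det <- matrix(c(1, 1, 1, 1, 1,
                  1, 0, 1, 0, 1), 5, 2,
                dimnames = list(NULL, c("150/150", "40/120")))
  res <- detection_probability(det)
  expect_equal(res$per_sample$rate, c(1, 0.6))
  # Clopper-Pearson oracle by direct beta quantiles, k successes of n
  cp <- function(k, n) c(if (k == 0) 0 else qbeta(0.025, k, n - k + 1),
                         if (k == n) 1 else qbeta(0.975, k + 1, n - k))
  expect_equal(c(res$per_sample$ci_low[2], res$per_sample$ci_high[2]),
               cp(3, 5), tolerance = 1e-10)
  expect_equal(res$per_sample$ci_high[1], 1)
  expect_equal(res$per_participant,
               rowMeans(det))
  expect_error(detection_probability(det[0, , drop = FALSE]), "empty")
})
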