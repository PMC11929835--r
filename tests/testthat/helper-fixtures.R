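# shared fixtures, built once per test run

fixture_env <- new.env(parent = emptyenv())

# memoized default cohort at a given size
fixture_cohort <- function(n = 60, seed = 101) {
  key <- sprintf("cohort_%d_%d", n, seed)
  if (is.null(fixture_env[[key]]))
    fixture_env[[key]] <- generate_cohort(
      cohort_config(n_participants = n, seed = seed))
  fixture_env[[key]]
}

fixture_large_cohort <- function() fixture_cohort(10000, 424242)

# predictor columns that are exactly mutually uncorrelated in-sample:
# QR of [1, random] makes columns orthogonal to each other and to the
# intercept (zero mean), so their sample correlation matrix is identity
orthogonal_predictors <- function(n, p, seed = 1) {
  set.seed(seed)
  m <- cbind(1, matrix(rnorm(n * p), n))
  q <- qr.Q(qr(m))[, 2:(p + 1), drop = FALSE]
  q <- scale(q)
  colnames(q) <- paste0("x", seq_len(p))
  q
}

# noiseless circular force trace with known friction coefficient
noiseless_trace <- function(mu_true = 1.2, seed = 7) {
  generate_force_trace(mu_true,
                       trial_config(sensor_noise_sd_n = 0, fn_jitter_n = 0),
                       seed = seed)
}
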