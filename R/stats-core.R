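#' Pearson correlation with significance test
#'
#' Computes the Pearson correlation coefficient between two vectors together
#' with the two-sided p-value from the t-statistic
#' \eqn{t = R\sqrt{(n-2)/(1-R^2)}} (equivalent to the one-predictor
#' regression F test). Incomplete pairs are dropped (pairwise deletion), so
#' the effective n is reported alongside the coefficient.
#'
#' @param x,y numeric vectors of equal length.
#' @return A list of class \code{"correlation_result"} with elements
#'   \code{R}, \code{p} and \code{n}.
#' @examples
#' set.seed(1)
#' x <- rnorm(30)
#' pearson_with_p(x, x + rnorm(30))
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  out <- list(R = unname(ct$estimate), p = ct$p.value, n = n)
  class(out) <- "correlation_result"
  out
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson R = %.3f (p = %.3g, n = %d)\n", x$R, x$p, x$n))
  invisible(x)
}

#' Relative standard deviation
#'
#' Sample standard deviation (n-1 denominator) divided by the mean:
#' the coefficient of variation used to compare the spread of skin
#' parameters with heterogeneous units.
#'
#' @param x numeric vector; missing values are dropped.
#' @return The relative SD as a fraction (0.41 means 41\%).
#' @export
relative_sd <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  if (m == 0) stop("mean is zero: relative SD undefined")
  stats::sd(x) / m
}

#' Z-score standardization
#'
#' Centers to mean zero and scales to unit sample standard deviation.
#'
#' @param x numeric vector with positive SD; missing values are preserved
#'   in place and ignored for the mean/SD.
#' @return Standardized vector of the same length.
#' @export
zscore <- function(x) {
  m <- mean(x, na.rm = TRUE)
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("zero or undefined SD: z-score undefined")
  (x - m) / s
}

#' Exponential decay of Meissner corpuscle density with age
#'
#' Fits a log-linear model \eqn{\ln(\mathrm{density}) = a + b \cdot
#' \mathrm{age}} by ordinary least squares and converts the slope into a
#' half-life \eqn{t_{1/2} = \ln 2 / (-b)}: the number of years over which
#' receptor density halves. The correlation coefficient is reported on the
#' log scale. A percentile bootstrap confidence interval for the half-life
#' (resampling age/density pairs with replacement) is attached when a
#' \code{bootstrap_config} is supplied.
#'
#' @param age numeric vector, years.
#' @param density numeric vector, mm^-2; strictly positive.
#' @param bootstrap optional \code{\link{bootstrap_config}} for a
#'   percentile CI of the half-life.
#' @return Object of class \code{"decay_fit"}: list with \code{slope}
#'   (per year, natural-log scale), \code{intercept}, \code{half_life}
#'   (years; \code{NA} when the slope is non-negative, i.e. no decay),
#'   \code{R}, \code{n}, and \code{ci_low}/\code{ci_high} when
#'   bootstrapped.
#' @examples
#' fit_age_decay(c(20, 39), c(10, 5))$half_life  # exactly 19 years
#' @export
fit_age_decay <- function(age, density, bootstrap = NULL) {
  keep <- is.finite(age) & is.finite(density)
  age <- age[keep]; density <- density[keep]
  if (length(age) < 3) stop("need at least 3 complete pairs")
  if (any(density <= 0)) stop("density must be strictly positive")
  ld <- log(density)
  fit <- stats::lm(ld ~ age)
  b <- unname(stats::coef(fit)[2])
  out <- list(
    slope = b,
    intercept = unname(stats::coef(fit)[1]),
    half_life = if (b < 0) log(2) / (-b) else NA_real_,
    R = unname(stats::cor(age, ld)),
    n = length(age),
    ci_low = NA_real_, ci_high = NA_real_
  )
  if (!is.null(bootstrap)) {
    hl <- function(d) {
      cf <- stats::cov(d[, 1], log(d[, 2])) / stats::var(d[, 1])
      if (cf < 0) log(2) / (-cf) else NA_real_
    }
    ci <- bootstrap_ci(hl, cbind(age, density), config = bootstrap)
    out$ci_low <- ci[1]; out$ci_high <- ci[2]
  }
  class(out) <- "decay_fit"
  out
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("Log-linear age decay fit\n")
  cat(sprintf("  slope     %.4f per year (R = %.2f on log scale, n = %d)\n",
              x$slope, x$R, x$n))
  if (is.na(x$half_life)) {
    cat("  half-life undefined (no decay: slope >= 0)\n")
  } else {
    cat(sprintf("  half-life %.1f years", x$half_life))
    if (!is.na(x$ci_low))
      cat(sprintf(" [95%% CI %.1f-%.1f]", x$ci_low, x$ci_high))
    cat("\n")
  }
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Bootstrap configuration
#'
#' @param n_resamples number of bootstrap resamples. The default (1e4) is
#'   sized for interactive use; raise to 1e6 for full-fidelity intervals.
#' @param confidence central coverage of the percentile interval.
#' @param seed integer seed making the resampling reproducible.
#' @return List of class \code{"bootstrap_config"}.
#' @export
bootstrap_config <- function(n_resamples = 1e4, confidence = 0.95, seed = 1L) {
  stopifnot(n_resamples >= 1, confidence > 0, confidence < 1)
  structure(list(n_resamples = as.integer(n_resamples),
                 confidence = confidence, seed = as.integer(seed)),
            class = "bootstrap_config")
}

#' Percentile bootstrap confidence interval
#'
#' Resamples rows (value pairs) of \code{data} with replacement,
#' recomputes \code{statistic} on each resample, and returns the central
#' percentile interval. Deterministic under the seed in \code{config}.
#'
#' @param statistic function taking a matrix/data frame and returning one
#'   number.
#' @param data matrix or data frame; rows are resampled jointly.
#' @param config a \code{\link{bootstrap_config}}.
#' @return Numeric vector \code{c(low, high)}. Errors if the statistic
#'   fails (returns \code{NA} or throws) on more than 1\% of resamples.
#' @export
bootstrap_ci <- function(statistic, data, config = bootstrap_config()) {
  data <- as.matrix(data)
  n <- nrow(data)
  stopifnot(n >= 2)
  set.seed(config$seed)
  stats_out <- vapply(seq_len(config$n_resamples), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    tryCatch(statistic(data[idx, , drop = FALSE]),
             error = function(e) NA_real_)
  }, numeric(1))
  bad <- sum(!is.finite(stats_out))
  if (bad > 0.01 * config$n_resamples)
    stop(sprintf("statistic failed on %d of %d resamples",
                 bad, config$n_resamples))
  alpha <- (1 - config$confidence) / 2
  unname(stats::quantile(stats_out, c(alpha, 1 - alpha), na.rm = TRUE,
                         names = FALSE, type = 7))
}

#' Sex differences in skin parameters (Welch's t-test)
#'
#' Runs Welch's unequal-variance t-test of each numeric column against the
#' two-level sex factor.
#'
#' @param data data frame with a \code{sex} column (two levels) and
#'   numeric parameter columns.
#' @param vars character vector of column names to test; defaults to all
#'   numeric columns except \code{id}.
#' @return Data frame with columns \code{variable}, \code{mean_F},
#'   \code{mean_M}, \code{t}, \code{p}.
#' @export
sex_difference_test <- function(data, vars = NULL) {
  stopifnot("sex" %in% names(data))
  sex <- factor(data$sex)
  stopifnot(nlevels(sex) == 2)
  if (is.null(vars)) {
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
    vars <- setdiff(vars, "id")
  }
  rows <- lapply(vars, function(v) {
    tt <- stats::t.test(data[[v]] ~ sex)
    data.frame(variable = v,
               mean_F = unname(tt$estimate[1]),
               mean_M = unname(tt$estimate[2]),
               t = unname(tt$statistic), p = tt$p.value)
  })
  do.call(rbind, rows)
}

#' Combined correlation/significance matrix
#'
#' Builds a square variables-by-variables table with Pearson R above the
#' diagonal and the corresponding p-values below it (1 on the diagonal),
#' the layout used for supplementary correlation matrices. Pairwise
#' deletion of missing values.
#'
#' @param X numeric data frame or matrix.
#' @return Square numeric matrix with dimnames; attribute \code{"n"}
#'   holds the pairwise sample sizes.
#' @export
correlation_matrix_table <- function(X) {
  X <- as.data.frame(X)
  p <- ncol(X)
  out <- diag(1, p)
  nmat <- matrix(NA_integer_, p, p)
  dimnames(out) <- list(names(X), names(X))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      r <- pearson_with_p(X[[i]], X[[j]])
      out[i, j] <- r$R
      out[j, i] <- r$p
      nmat[i, j] <- nmat[j, i] <- r$n
    }
  }
  attr(out, "n") <- nmat
  out
}
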