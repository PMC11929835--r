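#' Multiple linear regression with per-predictor t statistics
#'
#' Ordinary least squares of an outcome on a table of predictors
#' (intercept included), reporting the explained variance R^2 and the t
#' and two-sided p value of every predictor. Rows with any missing value
#' are dropped (listwise deletion) and the resulting degrees of freedom
#' are reported.
#'
#' @param X data frame or matrix of predictors (columns named).
#' @param y numeric outcome.
#' @return Object of class \code{"ols_fit"}: list with
#'   \code{coefficients} (incl. intercept), \code{r_squared},
#'   \code{t_values}, \code{p_values} (per predictor), \code{df_resid},
#'   \code{n}, and the underlying \code{lm} fit.
#' @export
ols_fit <- function(X, y) {
  X <- as.data.frame(X)
  stopifnot(nrow(X) == length(y))
  dat <- cbind(X, .y = y)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  p <- ncol(X)
  if (n <= p + 1) stop("need n > number of predictors + 1")
  qrX <- qr(cbind(1, as.matrix(dat[, names(X), drop = FALSE])))
  if (qrX$rank < p + 1) {
    drop_idx <- qrX$pivot[(qrX$rank + 1):(p + 1)] - 1L
    stop("rank-deficient predictor matrix; offending column(s): ",
         paste(names(X)[drop_idx], collapse = ", "))
  }
  fit <- stats::lm(.y ~ ., data = dat)
  # exact fits are legitimate here (identities are tested against them);
  # silence the "essentially perfect fit" note from summary.lm
  sm <- suppressWarnings(summary(fit))
  ct <- sm$coefficients
  out <- list(coefficients = stats::coef(fit),
              r_squared = sm$r.squared,
              t_values = ct[-1, "t value"],
              p_values = ct[-1, "Pr(>|t|)"],
              df_resid = fit$df.residual,
              n = n, lm = fit)
  class(out) <- "ols_fit"
  out
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS fit: R^2 = %.3f (n = %d, residual df = %d)\n",
              x$r_squared, x$n, x$df_resid))
  tab <- data.frame(coef = x$coefficients[-1],
                    t = x$t_values, p = signif(x$p_values, 2))
  print(tab)
  invisible(x)
}

#' @export
coef.ols_fit <- function(object, ...) object$coefficients

#' @export
predict.ols_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) stats::fitted(object$lm)
  else stats::predict(object$lm, newdata = as.data.frame(newdata))
}

#' @export
residuals.ols_fit <- function(object, ...) stats::residuals(object$lm)

#' Johnson relative weights of correlated predictors
#'
#' Decomposes the R^2 of a multiple regression into non-negative
#' contributions of each (correlated) predictor via Johnson's orthogonal
#' approximation. With predictors standardized and their correlation
#' matrix factored as \eqn{R_{xx} = V \Delta^2 V'}, the symmetric square
#' root \eqn{\Lambda = V \Delta V'} holds the correlations between
#' predictors and their closest orthogonal counterparts; the orthogonal
#' counterparts' regression coefficients are \eqn{\beta = \Lambda^{-1}
#' r_{xy}}, and the raw weight of predictor j is \eqn{\epsilon_j =
#' \sum_k \lambda_{jk}^2 \beta_k^2}. The raw weights sum exactly to R^2;
#' rescaled weights express each as a percentage of R^2.
#'
#' @param X data frame or matrix of predictors.
#' @param y numeric outcome.
#' @return Object of class \code{"relative_weights"}: list with
#'   \code{raw_weights} (variance units, sum = R^2),
#'   \code{rescaled_pct} (sum = 100), \code{r_squared}, \code{n}.
#' @export
johnson_relative_weights <- function(X, y) {
  X <- as.data.frame(X)
  stopifnot(nrow(X) == length(y))
  dat <- cbind(X, .y = y)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (n <= ncol(X) + 1) stop("need n > number of predictors + 1")
  Z <- scale(as.matrix(dat[, names(X), drop = FALSE]))
  zy <- as.numeric(scale(dat$.y))
  Rxx <- stats::cor(Z)
  if (kappa(Rxx, exact = TRUE) > 1e8)
    stop("near-singular predictor correlation matrix")
  rxy <- as.numeric(stats::cor(Z, zy))
  eg <- eigen(Rxx, symmetric = TRUE)
  lambda <- eg$vectors %*% diag(sqrt(eg$values)) %*% t(eg$vectors)
  beta <- solve(lambda, rxy)
  eps <- as.numeric(lambda^2 %*% beta^2)
  names(eps) <- names(X)
  r2 <- sum(eps)
  out <- list(raw_weights = eps,
              rescaled_pct = 100 * eps / r2,
              r_squared = r2, n = n)
  class(out) <- "relative_weights"
  out
}

#' @export
print.relative_weights <- function(x, ...) {
  cat(sprintf("Johnson relative weights (R^2 = %.3f, n = %d)\n",
              x$r_squared, x$n))
  print(data.frame(raw = round(x$raw_weights, 4),
                   pct_of_R2 = round(x$rescaled_pct, 1)))
  invisible(x)
}

#' Interaction regression model
#'
#' Fits \code{y ~ x1 + x2 + x1:x2 (+ covariates)} with x1 and x2
#' mean-centered before forming the product (decorrelating the
#' interaction from the main effects), and compares against the
#' main-effects-only model.
#'
#' @param x1,x2 numeric predictors.
#' @param y numeric outcome.
#' @param covariates optional data frame of additional main-effect
#'   predictors.
#' @return List of class \code{"interaction_fit"}: the full
#'   \code{\link{ols_fit}} (element \code{fit}), \code{interaction}
#'   (coefficient, t, p of the product term), \code{delta_r2}
#'   (R^2 gain over the no-interaction model) and \code{r2_base}.
#' @export
interaction_model <- function(x1, x2, y, covariates = NULL) {
  x1c <- x1 - mean(x1, na.rm = TRUE)
  x2c <- x2 - mean(x2, na.rm = TRUE)
  Xb <- data.frame(x1 = x1c, x2 = x2c)
  if (!is.null(covariates)) Xb <- cbind(Xb, as.data.frame(covariates))
  Xf <- cbind(Xb, x1_x2 = x1c * x2c)
  base <- ols_fit(Xb, y)
  full <- ols_fit(Xf, y)
  out <- list(fit = full,
              interaction = c(
                coefficient = unname(full$coefficients[["x1_x2"]]),
                t = unname(full$t_values[["x1_x2"]]),
                p = unname(full$p_values[["x1_x2"]])),
              delta_r2 = full$r_squared - base$r_squared,
              r2_base = base$r_squared)
  class(out) <- "interaction_fit"
  out
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat(sprintf(
    "Interaction model: R^2 %.3f -> %.3f (delta %.3f)\n",
    x$r2_base, x$fit$r_squared, x$delta_r2))
  cat(sprintf("  interaction term: coef %.4g, t = %.2f, p = %.3g\n",
              x$interaction[["coefficient"]], x$interaction[["t"]],
              x$interaction[["p"]]))
  invisible(x)
}

#' Per-sample regressions with relative weights
#'
#' Repeats the multiple regression and Johnson relative-weights
#' decomposition for each sample column of a friction table: the batch
#' view of how much friction variance physiology explains per sample.
#'
#' @param mu_table data frame of per-sample friction coefficients.
#' @param predictors data frame of physiological predictors (same rows).
#' @return Data frame with one row per sample: \code{sample},
#'   \code{r_squared}, and one \code{wt_<predictor>} column per
#'   predictor holding its rescaled weight as \% of R^2.
#' @export
sample_regressions <- function(mu_table, predictors) {
  predictors <- as.data.frame(predictors)
  rows <- lapply(names(mu_table), function(s) {
    rw <- johnson_relative_weights(predictors, mu_table[[s]])
    cbind(data.frame(sample = s, r_squared = rw$r_squared),
          stats::setNames(as.data.frame(t(rw$rescaled_pct)),
                          paste0("wt_", names(rw$rescaled_pct))))
  })
  do.call(rbind, rows)
}
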