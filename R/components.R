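#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' Overall KMO measure: the ratio of summed squared correlations to the
#' sum of squared correlations plus squared anti-image partial
#' correlations, over all off-diagonal pairs. Values near 1 indicate
#' that partial correlations are small and the data are suitable for
#' factor extraction.
#'
#' @param X numeric data frame or matrix (observations x variables), or
#'   a correlation matrix (square, unit diagonal).
#' @return KMO score in [0, 1].
#' @export
kmo_score <- function(X) {
  R <- as_correlation(X)
  p <- ncol(R)
  if (p < 3) stop("need at least 3 variables")
  Rinv <- tryCatch(solve(R), error = function(e)
    stop("singular correlation matrix: KMO undefined"))
  d <- 1 / sqrt(diag(Rinv))
  partial <- -Rinv * outer(d, d)     # anti-image partial correlations
  off <- upper.tri(R)
  sum(R[off]^2) / (sum(R[off]^2) + sum(partial[off]^2))
}

#' Bartlett's test of sphericity
#'
#' Tests whether a correlation matrix differs from the identity:
#' \eqn{\chi^2 = -(n - 1 - (2p + 5)/6)\,\ln\det R} with
#' \eqn{p(p-1)/2} degrees of freedom.
#'
#' @param X numeric data frame or matrix (observations x variables).
#' @param n number of observations; taken from \code{nrow(X)} when X is
#'   a data matrix, required when X is a correlation matrix.
#' @return List with \code{chi2}, \code{df}, \code{p}.
#' @export
bartlett_sphericity <- function(X, n = NULL) {
  if (is_correlation_matrix(X)) {
    if (is.null(n)) stop("n required when passing a correlation matrix")
    R <- as.matrix(X)
  } else {
    X <- stats::na.omit(as.matrix(X))
    n <- nrow(X)
    R <- stats::cor(X)
  }
  p <- ncol(R)
  if (n <= p) stop("need more observations than variables")
  detR <- det(R)
  if (detR <= 0) stop("correlation matrix not positive definite")
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * log(detR)
  df <- p * (p - 1) / 2
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

is_correlation_matrix <- function(X) {
  is.matrix(X) && nrow(X) == ncol(X) &&
    all(abs(diag(X) - 1) < 1e-12) && max(abs(X)) <= 1 + 1e-12 &&
    isTRUE(all.equal(X, t(X), tolerance = 1e-8))
}

as_correlation <- function(X) {
  if (is_correlation_matrix(as.matrix(X))) return(as.matrix(X))
  stats::cor(stats::na.omit(as.matrix(X)))
}

#' Principal component analysis with varimax rotation
#'
#' Eigendecomposition of the correlation matrix (variables have
#' heterogeneous units, so components are extracted from correlations),
#' retention by the Kaiser criterion (eigenvalue > 1, overridable),
#' Kaiser-normalized varimax rotation of the retained loadings, and
#' factor scores by Bartlett's weighted-least-squares method. Each
#' rotated component is sign-fixed so that its largest-magnitude loading
#' is positive, and components are ordered by rotated explained
#' variance.
#'
#' @param X numeric data frame or matrix, observations x variables;
#'   columns are standardized internally. Rows with missing values are
#'   dropped for the correlation matrix and produce \code{NA} scores.
#' @param n_components number of components to retain; default
#'   \code{NULL} applies the Kaiser criterion.
#' @param rotate logical; varimax-rotate when more than one component is
#'   retained (default TRUE).
#' @return Object of class \code{"pca_varimax"}: list with
#'   \code{eigenvalues}, \code{n_components}, \code{loadings} (rotated,
#'   variables x components), \code{unrotated_loadings},
#'   \code{variance_explained_pct}, \code{cumulative_pct}, \code{kmo},
#'   \code{bartlett} (chi2/df/p), \code{scores} (Bartlett WLS,
#'   observations x components), \code{communalities}, \code{n}.
#' @export
pca_varimax <- function(X, n_components = NULL, rotate = TRUE) {
  X <- as.data.frame(X)
  vars <- names(X)
  M <- as.matrix(X)
  complete <- stats::complete.cases(M)
  Z <- M[complete, , drop = FALSE]
  sds <- apply(Z, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance column: ", paste(vars[sds == 0], collapse = ", "))
  Z <- scale(Z)
  R <- stats::cor(Z)
  eg <- eigen(R, symmetric = TRUE)
  ev <- eg$values
  k <- if (is.null(n_components)) max(1L, sum(ev > 1)) else
    as.integer(n_components)
  stopifnot(k >= 1, k <= ncol(R))
  L <- eg$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k)]), k)
  rotL <- L
  rotation <- diag(k)
  if (rotate && k > 1) {
    vm <- stats::varimax(L, normalize = TRUE, eps = 1e-6)
    rotL <- L %*% vm$rotmat
    rotation <- vm$rotmat
  }
  # sign fix: largest-|loading| entry of each component positive
  for (j in seq_len(k)) {
    i_max <- which.max(abs(rotL[, j]))
    if (rotL[i_max, j] < 0) {
      rotL[, j] <- -rotL[, j]
      rotation[, j] <- -rotation[, j]
    }
  }
  expl <- colSums(rotL^2) / ncol(R) * 100
  ord <- order(expl, decreasing = TRUE)
  rotL <- rotL[, ord, drop = FALSE]
  rotation <- rotation[, ord, drop = FALSE]
  expl <- expl[ord]
  dimnames(rotL) <- list(vars, paste0("PC", seq_len(k)))
  communal <- rowSums(rotL^2)
  # Bartlett weighted-least-squares factor scores
  psi <- pmax(1 - communal, 1e-6)
  W <- solve(t(rotL) %*% (rotL / psi)) %*% t(rotL / psi)
  scores <- matrix(NA_real_, nrow(M), k,
                   dimnames = list(NULL, colnames(rotL)))
  scores[complete, ] <- Z %*% t(W)
  bart <- bartlett_sphericity(R, n = nrow(Z))
  out <- list(eigenvalues = ev, n_components = k, loadings = rotL,
              unrotated_loadings = L, rotation = rotation,
              variance_explained_pct = expl,
              cumulative_pct = cumsum(expl),
              kmo = kmo_score(R), bartlett = bart,
              scores = scores, communalities = communal, n = nrow(Z))
  class(out) <- "pca_varimax"
  out
}

#' @export
print.pca_varimax <- function(x, digits = 3, ...) {
  cat(sprintf(
    "PCA (correlation matrix), %d component%s retained (Kaiser), varimax rotated\n",
    x$n_components, if (x$n_components > 1) "s" else ""))
  cat(sprintf("  n = %d, KMO = %.3f, Bartlett chi2 = %.1f (df %d, p = %.2g)\n",
              x$n, x$kmo, x$bartlett$chi2, x$bartlett$df, x$bartlett$p))
  cat(sprintf("  variance explained: %s (cumulative %.1f%%)\n",
              paste(sprintf("%.1f%%", x$variance_explained_pct),
                    collapse = ", "),
              x$cumulative_pct[x$n_components]))
  cat("\nRotated loadings:\n")
  print(round(x$loadings, digits))
  invisible(x)
}

#' @export
summary.pca_varimax <- function(object, ...) {
  print(object, ...)
  invisible(object)
}

#' Composite friction and perception outcomes
#'
#' Reduces the per-sample outcome table to the three composites carried
#' through the correlation analysis, following the loading-threshold
#' rule (components defined by loadings above 0.75):
#' \itemize{
#'   \item \code{mu_rough}: mean friction coefficient over the six
#'     randomly rough plastic samples;
#'   \item \code{mu_fibril}: mean friction coefficient over the four
#'     micropillar samples with aspect ratio > 1 (40/120, 100/200,
#'     100/300, 150/350); the aspect-ratio-1 samples are excluded;
#'   \item \code{s_perc}: perception sensitivity, the mean of the
#'     z-scored pillar-detection rate and the negated z-scored two-point
#'     threshold (lower threshold = higher acuity).
#' }
#'
#' @param mu_table data frame of friction coefficients with columns
#'   \code{mu_<label>} (or plain labels) for the twelve samples, rows =
#'   participants.
#' @param pillar_perception numeric vector: per-participant mean pillar
#'   detection rate.
#' @param two_point numeric vector: per-participant two-point threshold
#'   in mm (any monotone unit).
#' @param loading_threshold retained for interface compatibility with
#'   the component-selection rule; the sample sets above correspond to
#'   the default 0.75.
#' @return Data frame with columns \code{mu_rough}, \code{mu_fibril},
#'   \code{s_perc}, one row per participant.
#' @export
build_composites <- function(mu_table, pillar_perception, two_point,
                             loading_threshold = 0.75) {
  rough <- rough_sample_labels()
  fibril <- fibril_sample_labels()
  find_col <- function(lab) {
    cand <- c(paste0("mu_", lab), lab, paste0("mu_", gsub("/", "_", lab)),
              gsub("/", "_", lab))
    hit <- cand[cand %in% names(mu_table)]
    if (length(hit) == 0) stop("missing sample column: ", lab)
    hit[1]
  }
  rough_cols <- vapply(rough, find_col, character(1))
  fibril_cols <- vapply(fibril, find_col, character(1))
  n <- nrow(mu_table)
  stopifnot(length(pillar_perception) == n, length(two_point) == n)
  data.frame(
    mu_rough = rowMeans(mu_table[, rough_cols, drop = FALSE]),
    mu_fibril = rowMeans(mu_table[, fibril_cols, drop = FALSE]),
    s_perc = rowMeans(cbind(zscore(pillar_perception), -zscore(two_point)))
  )
}

#' Sample label sets
#'
#' @return Character vectors of the six rough-plastic labels, the four
#'   fibrillar (aspect ratio > 1) micropillar labels, and the two
#'   aspect-ratio-1 micropillar labels.
#' @export
rough_sample_labels <- function() names(rough_sample_curvatures())

#' @rdname rough_sample_labels
#' @export
fibril_sample_labels <- function() c("40/120", "100/200", "100/300", "150/350")

#' @rdname rough_sample_labels
#' @export
ar1_sample_labels <- function() c("100/100", "150/150")
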