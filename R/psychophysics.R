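#' Weibull psychometric function
#'
#' Success probability of a two-alternative roughness comparison as a
#' function of the relative stimulus difference x:
#' \deqn{p(x) = 1 - 0.5 \exp(-(kx)^d),}
#' starting at 0.5 (chance) for zero difference and approaching 1 for
#' large differences.
#'
#' @param x relative difference (non-negative, vectorized).
#' @param k scale parameter (> 0), inverse units of x.
#' @param d shape parameter (> 0).
#' @return Probability in [0.5, 1).
#' @export
weibull_p <- function(x, k, d) {
  stopifnot(k > 0, d > 0)
  1 - 0.5 * exp(-(k * x)^d)
}

#' Just-noticeable difference of a Weibull psychometric curve
#'
#' The relative difference at which the curve crosses 75\% correct:
#' \eqn{\mathrm{JND} = (\ln 2)^{1/d} / k}.
#'
#' @param k,d Weibull parameters.
#' @return JND on the relative-difference axis.
#' @export
weibull_jnd <- function(k, d) {
  stopifnot(k > 0, d > 0)
  log(2)^(1 / d) / k
}

#' Maximum-likelihood fit of the Weibull psychometric function
#'
#' Fits \eqn{p(x) = 1 - 0.5\exp(-(kx)^d)} to binomial success counts by
#' maximizing the binomial log-likelihood over (log k, log d), with a
#' small multi-start grid to avoid local optima. The 75\%-correct
#' threshold (just-noticeable difference) is computed analytically from
#' the fitted parameters.
#'
#' By default the likelihood carries a Firth-type Jeffreys penalty
#' (\code{method = "firth"}): psychometric designs often place only a
#' few conditions on the rising part of the curve while the rest sit in
#' the saturated region, which makes the plain MLE of the threshold
#' noticeably biased downward in small samples and leaves it undefined
#' for degenerate (all-correct) data. The penalty
#' \eqn{+\tfrac12 \log\det I(\theta)} removes the leading-order bias
#' and keeps the estimate finite; \code{method = "mle"} gives the
#' unpenalized fit. Both are exactly equivariant under rescaling of x.
#'
#' @param x relative differences (> 0), one per condition.
#' @param successes number of correct responses per condition.
#' @param trials number of trials per condition.
#' @param method \code{"firth"} (default, bias-reduced) or
#'   \code{"mle"}.
#' @return Object of class \code{"weibull_fit"}: list with \code{k},
#'   \code{d}, \code{jnd}, \code{n_obs} (total trials),
#'   \code{log_likelihood} (unpenalized, at the optimum),
#'   \code{boundary} (TRUE when the data were all successes or all
#'   failures, flagging a fit the data barely constrain) and the input
#'   data.
#' @examples
#' x <- c(0.05, 0.1, 0.2, 0.4, 0.8)
#' p <- weibull_p(x, 5.55, 2)
#' fit <- fit_weibull(x, round(200 * p), rep(200, 5))
#' fit$jnd
#' @export
fit_weibull <- function(x, successes, trials,
                        method = c("firth", "mle")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(successes), length(x) == length(trials))
  keep <- trials > 0
  x <- x[keep]; successes <- successes[keep]; trials <- trials[keep]
  if (any(x <= 0)) stop("relative differences must be positive")
  if (length(unique(x)) < 2) stop("need at least 2 distinct x values")
  if (any(successes < 0) || any(successes > trials))
    stop("successes must lie in [0, trials]")

  loglik <- function(k, d) {
    p <- 1 - 0.5 * exp(-(k * x)^d)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    sum(successes * log(p) + (trials - successes) * log(1 - p))
  }
  objective <- function(par) {
    k <- exp(par[1]); d <- exp(par[2])
    val <- -loglik(k, d)
    if (method == "firth") {
      u <- (k * x)^d
      p <- pmin(pmax(1 - 0.5 * exp(-u), 1e-12), 1 - 1e-12)
      dpdu <- 0.5 * exp(-u)
      g1 <- dpdu * d * u                                  # dp/d log k
      g2 <- dpdu * u * d * log(pmax(k * x, 1e-300))       # dp/d log d
      w <- trials / (p * (1 - p))
      i11 <- sum(w * g1 * g1); i22 <- sum(w * g2 * g2)
      i12 <- sum(w * g1 * g2)
      det_i <- i11 * i22 - i12^2
      if (!is.finite(det_i) || det_i <= 0) return(1e10)
      val <- val - 0.5 * log(det_i)
    }
    val
  }
  starts <- expand.grid(logk = log(c(0.5, 2, 5.55, 20) / stats::median(x) * 0.15),
                        logd = log(c(0.7, 1.5, 2, 4)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    opt <- tryCatch(
      stats::optim(as.numeric(starts[i, ]), objective,
                   method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) stop("Weibull optimization failed from all starts")
  k <- exp(best$par[1]); d <- exp(best$par[2])
  boundary <- all(successes == trials) || all(successes == 0) ||
    k > 1e6 / max(x) || k < 1e-6 / max(x)
  out <- list(k = k, d = d, jnd = weibull_jnd(k, d),
              n_obs = sum(trials), log_likelihood = loglik(k, d),
              method = method, boundary = boundary,
              data = data.frame(x = x, successes = successes,
                                trials = trials))
  class(out) <- "weibull_fit"
  out
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat("Weibull psychometric fit: p(x) = 1 - 0.5 exp(-(kx)^d)\n")
  cat(sprintf("  k = %.3f, d = %.3f  (n = %d trials, logLik = %.2f)\n",
              x$k, x$d, x$n_obs, x$log_likelihood))
  cat(sprintf("  JND (75%% correct) = %.4f\n", x$jnd))
  if (x$boundary) cat("  warning: boundary fit (degenerate data)\n")
  invisible(x)
}

#' @export
coef.weibull_fit <- function(object, ...) {
  c(k = object$k, d = object$d)
}

#' @export
predict.weibull_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x
       else if (is.list(newdata)) newdata$x else newdata
  weibull_p(x, object$k, object$d)
}

#' Triplet presentation design for roughness ranking
#'
#' Groups six samples into ten ordered triplets such that every sample
#' appears in exactly five triplets (a balanced subset of the 20
#' possible triples, found by exhaustive search), then randomizes triplet
#' order and within-triplet position under the seed.
#'
#' @param labels character vector of exactly 6 sample labels.
#' @param seed integer seed for the presentation randomization.
#' @return Object of class \code{"triplet_design"}: list with
#'   \code{triplets} (10 x 3 character matrix) and \code{pairs}
#'   (data.frame of all within-triplet pairs, one row per pair slot).
#' @export
build_triplet_design <- function(labels, seed = 1L) {
  stopifnot(length(labels) == 6, !anyDuplicated(labels))
  triples <- t(utils::combn(6, 3))
  subset_idx <- find_balanced_triplets(triples, target = 5)
  tri <- triples[subset_idx, , drop = FALSE]
  set.seed(seed)
  tri <- tri[sample.int(nrow(tri)), , drop = FALSE]
  tri <- t(apply(tri, 1, function(r) r[sample.int(3)]))
  mat <- matrix(labels[tri], nrow = nrow(tri))
  pairs <- do.call(rbind, lapply(seq_len(nrow(mat)), function(i) {
    cmb <- utils::combn(mat[i, ], 2)
    data.frame(triplet = i, a = cmb[1, ], b = cmb[2, ])
  }))
  structure(list(triplets = mat, pairs = pairs), class = "triplet_design")
}

# Exhaustive search (with pruning) for a 10-subset of the 20 triples over
# 6 items in which every item is covered exactly `target` times.
find_balanced_triplets <- function(triples, target = 5) {
  n_tri <- nrow(triples)
  counts <- integer(6)
  chosen <- integer(0)
  recurse <- function(start, remaining) {
    if (remaining == 0) {
      if (all(counts == target)) return(chosen)
      return(NULL)
    }
    if (n_tri - start + 1 < remaining) return(NULL)
    for (i in start:n_tri) {
      tr <- triples[i, ]
      if (all(counts[tr] < target)) {
        counts[tr] <<- counts[tr] + 1L
        chosen <<- c(chosen, i)
        res <- recurse(i + 1, remaining - 1)
        if (!is.null(res)) return(res)
        counts[tr] <<- counts[tr] - 1L
        chosen <<- chosen[-length(chosen)]
      }
    }
    NULL
  }
  res <- recurse(1, 10)
  if (is.null(res)) stop("no balanced triplet design found")
  res
}

#' Score triplet rankings into pairwise successes
#'
#' For every within-triplet pair, a comparison counts as a success when
#' the member with the higher RMS curvature was ranked as rougher. The
#' relative curvature difference of a pair (c1 > c2) is
#' \eqn{(c_1 - c_2) / ((c_1 + c_2)/2)} by default.
#'
#' @param rankings list of rankings, one per presented triplet: each a
#'   character vector of the 3 labels ordered from least rough to
#'   roughest (a total order of its triplet).
#' @param curvature_by_label named numeric vector of RMS curvatures.
#' @param rel_diff how to normalize the curvature difference: the pair
#'   mean (default), the smaller, or the larger value.
#' @return Data frame with one row per relative-difference level:
#'   \code{rel_diff}, \code{n_success}, \code{n_trials}, \code{rate},
#'   plus attribute \code{"per_pair"} with the unaggregated table.
#' @export
pairwise_outcomes <- function(rankings, curvature_by_label,
                              rel_diff = c("mean", "smaller", "larger")) {
  rel_diff <- match.arg(rel_diff)
  rows <- lapply(rankings, function(rk) {
    if (length(rk) != 3 || anyDuplicated(rk))
      stop("each ranking must be a total order of 3 distinct labels")
    if (!all(rk %in% names(curvature_by_label)))
      stop("ranking contains labels without a curvature value")
    cmb <- utils::combn(rk, 2)
    data.frame(a = cmb[1, ], b = cmb[2, ],
               # position in rk encodes perceived roughness order
               a_rank = match(cmb[1, ], rk), b_rank = match(cmb[2, ], rk))
  })
  d <- do.call(rbind, rows)
  ca <- curvature_by_label[d$a]; cb <- curvature_by_label[d$b]
  if (any(ca == cb)) stop("tied curvatures are not supported")
  denom <- switch(rel_diff,
                  mean = (ca + cb) / 2,
                  smaller = pmin(ca, cb),
                  larger = pmax(ca, cb))
  d$rel_diff <- abs(ca - cb) / denom
  rougher_perceived <- ifelse(d$a_rank > d$b_rank, d$a, d$b)
  rougher_true <- ifelse(ca > cb, d$a, d$b)
  d$success <- as.integer(rougher_perceived == rougher_true)
  agg <- stats::aggregate(success ~ rel_diff, data = d,
                          FUN = function(s) c(sum(s), length(s)))
  out <- data.frame(rel_diff = agg$rel_diff,
                    n_success = agg$success[, 1],
                    n_trials = agg$success[, 2])
  out$rate <- out$n_success / out$n_trials
  out <- out[order(out$rel_diff), ]
  rownames(out) <- NULL
  attr(out, "per_pair") <- d
  out
}

#' Relative curvature differences of all sample pairs
#'
#' @param curvatures named numeric vector (e.g.
#'   \code{\link{rough_sample_curvatures}}).
#' @param rel_diff normalization, see \code{\link{pairwise_outcomes}}.
#' @return Data frame with columns \code{a}, \code{b}, \code{rel_diff}
#'   for all unordered pairs.
#' @export
pair_relative_differences <- function(curvatures,
                                      rel_diff = c("mean", "smaller",
                                                   "larger")) {
  rel_diff <- match.arg(rel_diff)
  cmb <- utils::combn(names(curvatures), 2)
  ca <- curvatures[cmb[1, ]]; cb <- curvatures[cmb[2, ]]
  denom <- switch(rel_diff,
                  mean = (ca + cb) / 2,
                  smaller = pmin(ca, cb),
                  larger = pmax(ca, cb))
  data.frame(a = cmb[1, ], b = cmb[2, ],
             rel_diff = unname(abs(ca - cb) / denom))
}

#' Two-point discrimination threshold from protocol responses
#'
#' Implements the measurement protocol: distances {0, 2, 3, 4, 5, 6, 7,
#' 8} mm are tested in random order and the minimal distance reported as
#' two points is retested together with the 1 mm distance; the retest
#' result wins. The recorded threshold is the final minimal distance
#' perceived as two separate points (\code{Inf} when no distance was).
#'
#' @param responses named logical vector: for each tested distance (names
#'   "0", "2", ..., "8"), whether the participant reported two points.
#' @param retest function taking a distance (mm) and returning a logical
#'   (perceived as two points); used for the 1 mm probe and the retest of
#'   the candidate minimum. Defaults to replaying \code{responses} for
#'   known distances and \code{FALSE} at 1 mm.
#' @return Object of class \code{"two_point_record"}: list with
#'   \code{threshold_mm} and \code{candidate_mm} (the pre-retest
#'   minimum).
#' @export
two_point_threshold <- function(responses, retest = NULL) {
  need <- as.character(c(0, 2:8))
  if (!all(need %in% names(responses)))
    stop("responses must cover distances 0 and 2-8 mm")
  responses <- responses[need]
  two_at <- as.numeric(names(responses))[responses]
  two_at <- two_at[two_at > 0]  # 0 mm reported as two is a false alarm
  if (length(two_at) == 0) {
    out <- list(threshold_mm = Inf, candidate_mm = Inf)
    class(out) <- "two_point_record"
    return(out)
  }
  candidate <- min(two_at)
  if (is.null(retest)) {
    retest <- function(d_mm) {
      key <- as.character(d_mm)
      if (key %in% names(responses)) unname(responses[key]) else FALSE
    }
  }
  final <- candidate
  if (isTRUE(retest(1))) final <- 1
  else if (!isTRUE(retest(candidate))) {
    # candidate not confirmed: next larger distance reported as two
    larger <- two_at[two_at > candidate]
    final <- if (length(larger)) min(larger) else Inf
  }
  out <- list(threshold_mm = final, candidate_mm = candidate)
  class(out) <- "two_point_record"
  out
}

#' @export
print.two_point_record <- function(x, ...) {
  cat(sprintf("Two-point discrimination threshold: %s mm\n",
              format(x$threshold_mm)))
  invisible(x)
}

#' Pillar detection rates with binomial confidence intervals
#'
#' Per-sample detection probability across participants, with an exact
#' Clopper-Pearson 95\% interval, and the per-participant mean detection
#' rate used in the perception composite.
#'
#' @param detections logical/0-1 matrix or data frame, participants x
#'   pillar samples.
#' @return List with \code{per_sample} (data.frame: sample, n, rate,
#'   ci_low, ci_high) and \code{per_participant} (named numeric vector of
#'   mean rates).
#' @export
detection_probability <- function(detections) {
  m <- as.matrix(detections)
  if (any(is.na(m))) stop("missing values in detection table")
  storage.mode(m) <- "integer"
  if (ncol(m) == 0 || nrow(m) == 0) stop("empty detection table")
  if (is.null(colnames(m))) colnames(m) <- paste0("P", seq_len(ncol(m)))
  per_sample <- do.call(rbind, lapply(colnames(m), function(s) {
    k <- sum(m[, s]); n <- nrow(m)
    bt <- stats::binom.test(k, n)
    data.frame(sample = s, n = n, rate = k / n,
               ci_low = bt$conf.int[1], ci_high = bt$conf.int[2])
  }))
  list(per_sample = per_sample, per_participant = rowMeans(m))
}
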