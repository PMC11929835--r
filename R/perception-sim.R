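#' Perception model configuration
#'
#' Parameterizes the simulated perception arm of the study:
#' \itemize{
#'   \item roughness comparisons: the probability of judging the
#'     higher-curvature sample of a pair as rougher follows the Weibull
#'     psychometric function with parameters \code{weibull_k},
#'     \code{weibull_d} of the pair's relative curvature difference;
#'   \item two-point discrimination: a latent threshold linear in log
#'     MC density (lower threshold for denser innervation) plus
#'     Gaussian observer noise, discretized by the measurement
#'     protocol;
#'   \item pillar detection: a Bernoulli response with logit linear in
#'     log pillar density (negative: dense fine pillars are not felt),
#'     log bending stiffness (positive: stiff pillars deform the skin),
#'     log MC density, hydration, and a negative MC-by-hydration
#'     interaction.
#' }
#' The default link coefficients were calibrated once against the
#' study-level summary statistics this generator is meant to emulate
#' (perception-MC correlation about 0.6, regression R^2 about 0.40
#' rising to 0.47 with the interaction term) and are documented in the
#' methods vignette.
#'
#' @param weibull_k,weibull_d psychometric parameters (defaults 5.55
#'   and 2, JND 0.15).
#' @param two_point_link list with \code{intercept} (mm, threshold at
#'   the reference MC density), \code{slope} (mm per natural-log unit
#'   of MC density; negative), \code{sd} (observer noise, mm),
#'   \code{ref_mc} (mm^-2).
#' @param pillar_detect_link list of logit coefficients:
#'   \code{intercept}, \code{log_density}, \code{log_stiffness},
#'   \code{mc}, \code{hydration}, \code{interaction}, and references
#'   \code{ref_density} (mm^-2), \code{ref_stiffness} (N/rad).
#' @param seed integer seed.
#' @return Object of class \code{"perception_model_config"}.
#' @export
perception_model_config <- function(
    weibull_k = 5.55, weibull_d = 2,
    two_point_link = list(intercept = 3.5, slope = -1.6, sd = 0.9,
                          ref_mc = 7.2),
    pillar_detect_link = list(intercept = 0.4, log_density = -0.55,
                              log_stiffness = 0.45, mc = 1.15,
                              hydration = 0.45, interaction = -1.5,
                              ref_density = 7.2, ref_stiffness = 1e-3),
    seed = 1L) {
  stopifnot(weibull_k > 0, weibull_d > 0)
  structure(list(weibull_k = weibull_k, weibull_d = weibull_d,
                 two_point_link = two_point_link,
                 pillar_detect_link = pillar_detect_link,
                 seed = as.integer(seed)),
            class = "perception_model_config")
}

#' Generate perception responses for a cohort
#'
#' Simulates the three perceptional tasks for every participant:
#' two-point discrimination (protocol over distances 0, 2-8 mm with the
#' 1 mm retest rule, driven by a latent threshold linked to MC
#' density), pillar detection on the six micropillar samples
#' (Bernoulli from the logit link), and pairwise roughness outcomes for
#' every within-triplet pair of the design (Bernoulli with Weibull
#' success probability at the pair's relative curvature difference).
#'
#' @param cohort data frame from \code{\link{generate_cohort}}.
#' @param perc a \code{\link{perception_model_config}}.
#' @param design a \code{\link{build_triplet_design}} result; default
#'   built from the rough-sample labels.
#' @param curvatures named RMS curvatures for the design labels
#'   (default \code{\link{rough_sample_curvatures}}).
#' @return List with \code{two_point} (data frame: id, threshold_mm),
#'   \code{pillar_detections} (participants x 6 logical matrix, columns
#'   = pillar labels), \code{roughness} (data frame: id, a, b,
#'   rel_diff, success, one row per presented pair).
#' @export
generate_perception_data <- function(cohort,
                                     perc = perception_model_config(),
                                     design = NULL,
                                     curvatures = rough_sample_curvatures()) {
  stopifnot(inherits(perc, "perception_model_config"))
  n <- nrow(cohort)
  if (n == 0) stop("cohort is empty")
  if (is.null(design))
    design <- build_triplet_design(names(curvatures), seed = perc$seed)
  if (!all(unique(c(design$pairs$a, design$pairs$b)) %in% names(curvatures)))
    stop("design contains sample ids without a curvature value")
  set.seed(perc$seed)

  # --- two-point discrimination ---
  tp <- perc$two_point_link
  x_mc <- log(cohort$mc_density) - log(tp$ref_mc)
  latent <- tp$intercept + tp$slope * x_mc + stats::rnorm(n, 0, tp$sd)
  latent <- pmax(latent, 0.5)
  thresholds <- vapply(seq_len(n), function(i) {
    dists <- c(0, 2:8)
    resp <- stats::setNames(dists >= latent[i], as.character(dists))
    two_point_threshold(resp,
                        retest = function(d) d >= latent[i])$threshold_mm
  }, numeric(1))
  # no distance perceived as two: score at just above the largest probe
  thresholds[!is.finite(thresholds)] <- 9

  # --- pillar detection ---
  pl <- perc$pillar_detect_link
  pil <- micropillar_samples()
  z_hyd <- zscore(cohort$sc_hydration)
  det <- matrix(NA, n, nrow(pil), dimnames = list(cohort$id, pil$label))
  for (j in seq_len(nrow(pil))) {
    lin <- pl$intercept +
      pl$log_density * (log(pil$density_mm2[j]) - log(pl$ref_density)) +
      pl$log_stiffness * (log(pil$stiffness_n_per_rad[j]) -
                            log(pl$ref_stiffness)) +
      pl$mc * x_mc + pl$hydration * z_hyd +
      pl$interaction * x_mc * z_hyd
    det[, j] <- stats::runif(n) < stats::plogis(lin)
  }

  # --- pairwise roughness outcomes ---
  pr <- design$pairs
  ca <- curvatures[pr$a]; cb <- curvatures[pr$b]
  rel <- abs(ca - cb) / ((ca + cb) / 2)
  p_success <- weibull_p(rel, perc$weibull_k, perc$weibull_d)
  rough <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(id = cohort$id[i], a = pr$a, b = pr$b,
               rel_diff = unname(rel),
               success = as.integer(stats::runif(nrow(pr)) < p_success))
  }))
  rownames(rough) <- NULL

  list(two_point = data.frame(id = cohort$id, threshold_mm = thresholds),
       pillar_detections = det,
       roughness = rough)
}

#' Simulate a set of pairwise roughness comparisons
#'
#' Draws binomial "higher-curvature judged rougher" outcomes for each
#' relative-difference level under the Weibull psychometric model, the
#' design used for psychometric-recovery checks: \code{n_participants}
#' observers each judging every pair \code{reps} times.
#'
#' @param rel_diffs vector of relative curvature differences (> 0),
#'   e.g. from \code{\link{pair_relative_differences}}.
#' @param n_participants number of simulated observers.
#' @param reps repetitions per observer and pair.
#' @param k,d Weibull parameters of the generating curve.
#' @param seed integer seed.
#' @return Data frame with \code{rel_diff}, \code{n_success},
#'   \code{n_trials} (aggregated over observers).
#' @export
simulate_pairwise_comparisons <- function(rel_diffs, n_participants = 60,
                                          reps = 5, k = 5.55, d = 2,
                                          seed = 1L) {
  stopifnot(all(rel_diffs > 0), n_participants >= 1, reps >= 1)
  set.seed(seed)
  p <- weibull_p(rel_diffs, k, d)
  n_trials <- n_participants * reps
  n_success <- stats::rbinom(length(rel_diffs), n_trials, p)
  data.frame(rel_diff = rel_diffs, n_success = n_success,
             n_trials = n_trials)
}
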