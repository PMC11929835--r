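#' Cohort configuration for the synthetic skin-physiology generator
#'
#' Defines the statistical structure of a simulated participant cohort:
#' truncated-normal age, lognormal marginals for the strictly positive
#' skin parameters (parameterized by mean and relative SD), a Gaussian
#' copula carrying the target pairwise correlations, and Meissner
#' corpuscle density generated as an exponential decay with age
#' (halving every \code{mc_half_life} years) times lognormal noise.
#'
#' The default marginal relative SDs and the non-zero default
#' correlations reproduce the spread and dependence structure reported
#' for a 60-participant tactile-perception cohort: RSDs of 25\% (SC
#' hydration), 25\% (SC thickness), 21\% (sweat-gland density), 15\%
#' (ridge distance), 31\% (R0), 41\% (Ue), 9\% (R2) and 40\% (MC
#' density); correlations R0-hydration 0.40, Ue-hydration 0.49,
#' R2-thickness 0.39, R2-hydration 0.31, hydration-age -0.31. Marginal
#' means other than the MC density (7.2 mm^-2) are plausible defaults
#' for finger-pad skin and fully configurable.
#'
#' @param n_participants cohort size (>= 3), default 60.
#' @param seed integer seed.
#' @param age_mean,age_sd,age_range parameters of the truncated normal
#'   age distribution (years), defaults 34, 11, c(20, 70).
#' @param marginal_means named numeric vector of marginal means for
#'   \code{sc_hydration} (corneometer a.u.), \code{sc_thickness} (um),
#'   \code{sg_density} (mm^-2), \code{ridge_distance} (um), \code{r0}
#'   (mm), \code{ue} (mm), \code{r2} (fraction), \code{mc_density}
#'   (mm^-2).
#' @param marginal_rsd named numeric vector of relative SDs (> 0 unless
#'   degenerate simulations are intended) for the same parameters.
#' @param target_correlations symmetric correlation matrix over
#'   \code{c("age", "sc_hydration", "sc_thickness", "sg_density",
#'   "ridge_distance", "r0", "ue", "r2")}; unspecified entries default
#'   to the values above. Repaired to the nearest PSD matrix by
#'   eigenvalue clipping when needed.
#' @param mc_half_life half-life of the MC-density decay with age,
#'   years (default 19).
#' @param sex_proportion_female fraction of female participants
#'   (default 37/60).
#' @param sex_offset named log-scale offsets between sexes applied
#'   mean-preservingly; only sweat-gland density and ridge distance
#'   differ between sexes by default.
#' @param missing_rate probability that any one physiological value is
#'   recorded as missing (default 0 = complete data).
#' @return Object of class \code{"cohort_config"}.
#' @export
cohort_config <- function(n_participants = 60, seed = 1L,
                          age_mean = 34, age_sd = 11,
                          age_range = c(20, 70),
                          marginal_means = NULL, marginal_rsd = NULL,
                          target_correlations = NULL,
                          mc_half_life = 19,
                          sex_proportion_female = 37 / 60,
                          sex_offset = c(sg_density = 0.12,
                                         ridge_distance = -0.08),
                          missing_rate = 0) {
  if (n_participants < 3) stop("n_participants must be at least 3")
  means <- c(sc_hydration = 50, sc_thickness = 150, sg_density = 6,
             ridge_distance = 450, r0 = 0.12, ue = 0.08, r2 = 0.65,
             mc_density = 7.2)
  rsd <- c(sc_hydration = 0.25, sc_thickness = 0.25, sg_density = 0.21,
           ridge_distance = 0.15, r0 = 0.31, ue = 0.41, r2 = 0.09,
           mc_density = 0.40)
  if (!is.null(marginal_means)) means[names(marginal_means)] <- marginal_means
  if (!is.null(marginal_rsd)) rsd[names(marginal_rsd)] <- marginal_rsd
  if (any(rsd < 0)) stop("relative SDs must be non-negative")
  vars <- c("age", "sc_hydration", "sc_thickness", "sg_density",
            "ridge_distance", "r0", "ue", "r2")
  R <- diag(length(vars))
  dimnames(R) <- list(vars, vars)
  set_r <- function(a, b, v) {
    R[a, b] <<- v; R[b, a] <<- v
  }
  set_r("r0", "sc_hydration", 0.40)
  set_r("ue", "sc_hydration", 0.49)
  set_r("r2", "sc_thickness", 0.39)
  set_r("r2", "sc_hydration", 0.31)
  set_r("sc_hydration", "age", -0.31)
  if (!is.null(target_correlations)) {
    tc <- as.matrix(target_correlations)
    if (!all(rownames(tc) %in% vars))
      stop("unknown variable in target_correlations")
    R[rownames(tc), colnames(tc)] <- tc
  }
  if (any(abs(R) > 1) || any(diag(R) != 1) || any(R != t(R)))
    stop("invalid correlation matrix: entries in [-1,1], unit diagonal, symmetric")
  stopifnot(mc_half_life > 0, missing_rate >= 0, missing_rate < 1,
            age_sd >= 0, age_range[1] < age_range[2])
  structure(list(
    n_participants = as.integer(n_participants), seed = as.integer(seed),
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    marginal_means = means, marginal_rsd = rsd,
    target_correlations = nearest_psd(R),
    mc_half_life = mc_half_life,
    sex_proportion_female = sex_proportion_female,
    sex_offset = sex_offset, missing_rate = missing_rate
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("Cohort config: n = %d, seed = %d\n", x$n_participants, x$seed))
  cat(sprintf("  age ~ truncN(%g, %g) on [%g, %g]; MC half-life %g y\n",
              x$age_mean, x$age_sd, x$age_range[1], x$age_range[2],
              x$mc_half_life))
  tab <- data.frame(mean = x$marginal_means,
                    rsd = x$marginal_rsd[names(x$marginal_means)])
  print(tab)
  invisible(x)
}

#' Nearest positive semidefinite correlation matrix
#'
#' Repairs an indefinite correlation matrix by clipping negative
#' eigenvalues to zero and renormalizing to a unit diagonal, iterating
#' until the smallest eigenvalue is above \code{-tol}.
#'
#' @param R symmetric matrix with unit diagonal.
#' @param tol tolerance on the smallest admissible eigenvalue
#'   (default 1e-8).
#' @param max_iter iteration cap.
#' @return PSD correlation matrix.
#' @export
nearest_psd <- function(R, tol = 1e-8, max_iter = 100) {
  R <- (R + t(R)) / 2
  for (i in seq_len(max_iter)) {
    eg <- eigen(R, symmetric = TRUE)
    if (min(eg$values) >= -tol) return(R)
    ev <- pmax(eg$values, 0)
    R <- eg$vectors %*% diag(ev) %*% t(eg$vectors)
    d <- sqrt(diag(R))
    R <- R / outer(d, d)
    diag(R) <- 1
  }
  if (min(eigen(R, symmetric = TRUE)$values) < -tol)
    stop("correlation matrix could not be repaired to PSD within tolerance")
  R
}

# Inverse CDF of the truncated normal, mapping standard-normal deviates
# onto [lo, hi]; degenerates to the mean when sd = 0.
qtruncnorm_from_z <- function(z, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, length(z)))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::pnorm(z) * (phi - plo), mean, sd)
}

# Mean and CV of g = 2^(-age / half_life) under the truncated normal age
# distribution, by numerical quadrature.
mc_age_factor_moments <- function(config) {
  with(config, {
    if (age_sd == 0) {
      g <- 2^(-age_mean / mc_half_life)
      return(list(mean = g, cv = 0))
    }
    dens <- function(a) stats::dnorm(a, age_mean, age_sd)
    z <- stats::integrate(dens, age_range[1], age_range[2])$value
    m1 <- stats::integrate(function(a)
      2^(-a / mc_half_life) * dens(a), age_range[1], age_range[2])$value / z
    m2 <- stats::integrate(function(a)
      2^(-2 * a / mc_half_life) * dens(a), age_range[1], age_range[2])$value / z
    list(mean = m1, cv = sqrt(max(m2 / m1^2 - 1, 0)))
  })
}

lognormal_params <- function(mean, rsd) {
  sdlog <- sqrt(log(1 + rsd^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic participant cohort
#'
#' Draws \code{n_participants} rows of age, sex and skin physiology with
#' the marginals and dependence structure of the supplied
#' \code{\link{cohort_config}}: a multivariate normal copula (repaired
#' target correlation matrix) is transformed through the truncated
#' normal age quantile and lognormal parameter quantiles matched to each
#' mean/RSD; Meissner corpuscle density is then generated as
#' \code{baseline * 2^(-age/half_life) * lognormal noise}, where the
#' baseline and the noise RSD are solved from the configured MC mean and
#' total RSD given the age distribution (so the configured marginal is
#' matched by construction, not by tuning). Deterministic under the
#' config seed.
#'
#' @param config a \code{\link{cohort_config}}.
#' @return Data frame with columns \code{id}, \code{age}, \code{sex},
#'   \code{sc_hydration}, \code{sc_thickness}, \code{sg_density},
#'   \code{ridge_distance}, \code{mc_density}, \code{r0}, \code{ue},
#'   \code{r2}.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_participants = 60, seed = 7))
#' relative_sd(cohort$ue)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_participants
  R <- config$target_correlations
  vars <- colnames(R)
  set.seed(config$seed)

  # Gaussian copula draw
  eg <- eigen(R, symmetric = TRUE)
  A <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0))) %*% t(eg$vectors)
  Z <- matrix(stats::rnorm(n * length(vars)), n) %*% A
  colnames(Z) <- vars

  age <- qtruncnorm_from_z(Z[, "age"], config$age_mean, config$age_sd,
                           config$age_range[1], config$age_range[2])
  out <- data.frame(id = sprintf("P%03d", seq_len(n)), age = age)
  out$sex <- ifelse(stats::runif(n) < config$sex_proportion_female, "F", "M")

  for (v in setdiff(vars, "age")) {
    lp <- lognormal_params(config$marginal_means[v], config$marginal_rsd[v])
    out[[v]] <- if (lp$sdlog == 0) rep(config$marginal_means[[v]], n) else
      stats::qlnorm(stats::pnorm(Z[, v]), lp$meanlog, lp$sdlog)
  }

  # mean-preserving sex offsets (log scale)
  f <- config$sex_proportion_female
  for (v in names(config$sex_offset)) {
    o <- config$sex_offset[[v]]
    fac <- ifelse(out$sex == "F", exp(o * (1 - f)), exp(-o * f))
    out[[v]] <- out[[v]] * fac
  }

  # MC density: exponential age decay times lognormal noise
  mom <- mc_age_factor_moments(config)
  rsd_mc <- config$marginal_rsd[["mc_density"]]
  ratio <- (1 + rsd_mc^2) / (1 + mom$cv^2)
  if (ratio < 1)
    stop("configured MC RSD is below the variability induced by the age ",
         "distribution alone; increase marginal_rsd['mc_density'] or ",
         "narrow the age range")
  cv_noise <- sqrt(ratio - 1)
  baseline <- config$marginal_means[["mc_density"]] / mom$mean
  lpn <- lognormal_params(1, cv_noise)
  noise <- if (cv_noise == 0) rep(1, n) else
    stats::rlnorm(n, lpn$meanlog, lpn$sdlog)
  out$mc_density <- baseline * 2^(-out$age / config$mc_half_life) * noise

  # r2 is a fraction: resample the rare draws above 1
  bad <- which(out$r2 > 1)
  guard <- 0
  while (length(bad) > 0 && guard < 100) {
    lp <- lognormal_params(config$marginal_means[["r2"]],
                           config$marginal_rsd[["r2"]])
    out$r2[bad] <- stats::qlnorm(stats::pnorm(stats::rnorm(length(bad))),
                                 lp$meanlog, lp$sdlog)
    bad <- which(out$r2 > 1)
    guard <- guard + 1
  }
  if (length(bad) > 0)
    stop("could not keep r2 within (0, 1]: RSD too large for the mean")

  if (config$missing_rate > 0) {
    pcols <- c("sc_hydration", "sc_thickness", "sg_density",
               "ridge_distance", "mc_density", "r0", "ue", "r2")
    for (v in pcols) {
      drop <- stats::runif(n) < config$missing_rate
      out[[v]][drop] <- NA_real_
    }
  }
  out[, c("id", "age", "sex", "sc_hydration", "sc_thickness", "sg_density",
          "ridge_distance", "mc_density", "r0", "ue", "r2")]
}

#' Descriptive statistics of a cohort table
#'
#' @param cohort data frame from \code{\link{generate_cohort}} (or a
#'   benchmark table with the same columns).
#' @return Data frame with mean, SD and relative SD per numeric
#'   parameter.
#' @export
cohort_descriptives <- function(cohort) {
  pcols <- intersect(c("age", "sc_hydration", "sc_thickness", "sg_density",
                       "ridge_distance", "mc_density", "r0", "ue", "r2"),
                     names(cohort))
  do.call(rbind, lapply(pcols, function(v) {
    x <- cohort[[v]][is.finite(cohort[[v]])]
    data.frame(parameter = v, n = length(x), mean = mean(x),
               sd = stats::sd(x), rsd = stats::sd(x) / mean(x))
  }))
}
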