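#' Friction model configuration
#'
#' Parameterizes the generator of "true" per-participant, per-sample
#' friction coefficients. Each sample class (rough plastic, fibrillar
#' micropillar with aspect ratio > 1, and the two aspect-ratio-1 pillar
#' samples) gets a physiology score built from standardized SC
#' hydration, SC thickness, Ue and R2 (weights proportional to the
#' regression t-ordering of each class), a participant random effect
#' shared within the class, and per-sample noise. The physiology-score
#' coefficient is solved in closed form so that the population R^2 of
#' the class-average friction (mu_rough, mu_fibril) on the four
#' predictors equals \code{r2_rough} / \code{r2_fibril}.
#'
#' @param mean_mu named vector of per-sample mean friction
#'   coefficients. Defaults: 0.92 for each of the six rough samples and
#'   1.2-2.0 for the pillar samples, increasing with aspect ratio.
#' @param within_sample_rsd named vector of per-sample relative SDs
#'   (defaults 0.28-0.33 rough, 0.17-0.22 pillars).
#' @param r2_rough,r2_fibril target explained variance of the class
#'   average by the four physiological predictors (defaults 0.74 and
#'   0.34).
#' @param participant_effect_share named fraction of residual variance
#'   shared across samples within each class,
#'   \code{c(rough = 0.85, fibril = 0.5, ar1 = 0.6)}; the rough default
#'   puts inter-sample correlations near 0.96 and the fibril default
#'   near 0.62.
#' @param seed integer seed.
#' @return Object of class \code{"friction_model_config"}.
#' @export
friction_model_config <- function(mean_mu = NULL, within_sample_rsd = NULL,
                                  r2_rough = 0.74, r2_fibril = 0.34,
                                  participant_effect_share =
                                    c(rough = 0.85, fibril = 0.5, ar1 = 0.6),
                                  seed = 1L) {
  mu <- c(S01 = 0.92, S02 = 0.92, S03 = 0.92, S07 = 0.92, S08 = 0.92,
          S09 = 0.92,
          "40/120" = 2.0, "100/100" = 1.2, "100/200" = 1.7,
          "100/300" = 1.9, "150/150" = 1.3, "150/350" = 1.8)
  rsd <- c(S01 = 0.28, S02 = 0.29, S03 = 0.30, S07 = 0.31, S08 = 0.32,
           S09 = 0.33,
           "40/120" = 0.22, "100/100" = 0.17, "100/200" = 0.20,
           "100/300" = 0.21, "150/150" = 0.18, "150/350" = 0.20)
  if (!is.null(mean_mu)) mu[names(mean_mu)] <- mean_mu
  if (!is.null(within_sample_rsd))
    rsd[names(within_sample_rsd)] <- within_sample_rsd
  if (any(mu <= 0)) stop("mean friction coefficients must be positive")
  if (r2_rough < 0 || r2_rough >= 1 || r2_fibril < 0 || r2_fibril >= 1)
    stop("R^2 targets must lie in [0, 1)")
  share <- c(rough = 0.85, fibril = 0.5, ar1 = 0.6)
  share[names(participant_effect_share)] <- participant_effect_share
  if (any(share < 0) || any(share > 1))
    stop("participant_effect_share must lie in [0, 1]")
  structure(list(sample_ids = names(mu), mean_mu = mu,
                 within_sample_rsd = rsd,
                 r2_rough = r2_rough, r2_fibril = r2_fibril,
                 participant_effect_share = share,
                 seed = as.integer(seed)),
            class = "friction_model_config")
}

# physiology score weights per class (proportional to the regression
# t-value ordering: hydration-led for rough, Ue-led for fibrillar)
friction_score_weights <- function() {
  list(rough = c(sc_hydration = 5.3, sc_thickness = 3.8, ue = 3.2,
                 r2 = 2.4),
       fibril = c(sc_hydration = -1.3, sc_thickness = 2.9, ue = 3.9,
                  r2 = 0.9))
}

# Coefficient A (variance fraction of the physiology score per sample)
# such that the class AVERAGE of n_s equicorrelated samples has
# R^2 = r2_target on the predictors:
#   R^2(avg) = A / (A + kappa (1 - A)),  kappa = eta + (1 - eta)/n_s
solve_score_share <- function(r2_target, eta, n_samples) {
  kappa <- eta + (1 - eta) / n_samples
  r2_target * kappa / (1 - r2_target + r2_target * kappa)
}

#' Generate true friction coefficients for a cohort
#'
#' For each participant and each of the twelve samples, draws
#' \deqn{\mu_{ps} = m_s (1 + c_s \cdot s_{ps}),}
#' where \eqn{m_s} is the sample mean, \eqn{c_s} the sample relative SD
#' and \eqn{s_{ps}} a unit-variance score combining the class
#' physiology score, a class-shared participant effect and per-sample
#' noise. Draws with non-positive \eqn{\mu} are resampled (truncation).
#' The aspect-ratio-1 samples mix the rough and fibrillar physiology
#' scores and participant effects equally, mirroring their intermediate
#' behaviour.
#'
#' @param cohort data frame from \code{\link{generate_cohort}}.
#' @param model a \code{\link{friction_model_config}}.
#' @return Data frame with \code{id} and one \code{mu_<label>} column
#'   per sample ("/" in labels replaced by "_").
#' @export
generate_friction_coefficients <- function(cohort, model =
                                             friction_model_config()) {
  stopifnot(inherits(model, "friction_model_config"))
  n <- nrow(cohort)
  if (n == 0) stop("cohort is empty")
  set.seed(model$seed)
  w <- friction_score_weights()
  Z <- cbind(sc_hydration = zscore(cohort$sc_hydration),
             sc_thickness = zscore(cohort$sc_thickness),
             ue = zscore(cohort$ue), r2 = zscore(cohort$r2))
  g_rough <- as.numeric(Z[, names(w$rough)] %*% w$rough)
  g_fibril <- as.numeric(Z[, names(w$fibril)] %*% w$fibril)
  g_rough <- g_rough / stats::sd(g_rough)
  g_fibril <- g_fibril / stats::sd(g_fibril)
  g_ar1 <- (g_rough + g_fibril)
  g_ar1 <- g_ar1 / stats::sd(g_ar1)

  u_rough <- stats::rnorm(n)
  u_fibril <- stats::rnorm(n)
  u_ar1 <- (u_rough + u_fibril) / sqrt(2)

  classes <- list(
    rough = list(samples = rough_sample_labels(), g = g_rough,
                 u = u_rough,
                 A = solve_score_share(model$r2_rough,
                                       model$participant_effect_share["rough"],
                                       length(rough_sample_labels())),
                 eta = model$participant_effect_share[["rough"]]),
    fibril = list(samples = fibril_sample_labels(), g = g_fibril,
                  u = u_fibril,
                  A = solve_score_share(model$r2_fibril,
                                        model$participant_effect_share["fibril"],
                                        length(fibril_sample_labels())),
                  eta = model$participant_effect_share[["fibril"]]),
    ar1 = list(samples = ar1_sample_labels(), g = g_ar1, u = u_ar1,
               A = 0.30, eta = model$participant_effect_share[["ar1"]])
  )
  out <- data.frame(id = cohort$id)
  for (cl in classes) {
    a <- sqrt(cl$A)
    b <- sqrt((1 - cl$A) * cl$eta)
    cc <- sqrt((1 - cl$A) * (1 - cl$eta))
    for (s in cl$samples) {
      m <- model$mean_mu[[s]]
      cs <- model$within_sample_rsd[[s]]
      eps <- stats::rnorm(n)
      mu <- m * (1 + cs * (a * cl$g + b * cl$u + cc * eps))
      bad <- which(mu <= 0)
      if (length(bad) > 0 && cc > 0) {
        # exact truncated resampling of the per-sample noise: eps must
        # exceed the bound that keeps mu positive
        lower <- (-1 / cs - a * cl$g[bad] - b * cl$u[bad]) / cc
        eps[bad] <- stats::qnorm(stats::runif(length(bad),
                                              stats::pnorm(lower), 1))
        mu[bad] <- m * (1 + cs * (a * cl$g[bad] + b * cl$u[bad] +
                                    cc * eps[bad]))
      }
      if (any(mu <= 0))
        stop("could not keep friction positive: RSD too large for the ",
             "configured noise share")
      out[[paste0("mu_", gsub("/", "_", s))]] <- mu
    }
  }
  out
}

#' Trial configuration for simulated force traces
#'
#' @param duration_s trial length in seconds (default 30; the study
#'   protocol spanned 15.4-69.4 s).
#' @param circle_rate_s exploration circle rate in 1/s (default 0.4;
#'   observed range 0.06-1.21).
#' @param fn_target_n target normal force in N (default 1.0; guidance
#'   band 0.8-1.2 N).
#' @param fn_jitter_n SD of the slow normal-force fluctuation in N
#'   (default 0.08).
#' @param sensor_noise_sd_n SD of the white sensor noise per channel in
#'   N (default 0.01).
#' @param sampling_rate_hz sampling rate, default 50 Hz.
#' @param pre_post_idle_s idle (no touch) time before and after the
#'   contact segment, seconds (default 2).
#' @return Object of class \code{"trial_config"}.
#' @export
trial_config <- function(duration_s = 30, circle_rate_s = 0.4,
                         fn_target_n = 1.0, fn_jitter_n = 0.08,
                         sensor_noise_sd_n = 0.01,
                         sampling_rate_hz = 50, pre_post_idle_s = 2) {
  if (duration_s < 15.4 || duration_s > 69.4)
    stop("duration must lie within the protocol bounds 15.4-69.4 s")
  if (circle_rate_s < 0.06 || circle_rate_s > 1.21)
    stop("circle rate must lie within the observed bounds 0.06-1.21 1/s")
  if (fn_target_n < 0.8 || fn_target_n > 1.2)
    stop("target normal force must lie within the guidance band 0.8-1.2 N")
  if (duration_s <= 2 * pre_post_idle_s)
    stop("duration must exceed twice the idle time")
  structure(list(duration_s = duration_s, circle_rate_s = circle_rate_s,
                 fn_target_n = fn_target_n, fn_jitter_n = fn_jitter_n,
                 sensor_noise_sd_n = sensor_noise_sd_n,
                 sampling_rate_hz = sampling_rate_hz,
                 pre_post_idle_s = pre_post_idle_s),
            class = "trial_config")
}

#' Simulate a three-axis force trace for one trial
#'
#' Builds a trace with idle flanks (sensor noise only) around a contact
#' segment in which the normal force oscillates slowly around the
#' target and the tangential force vector rotates at the circle rate
#' with magnitude \code{mu_true * FN}. White Gaussian sensor noise is
#' added independently per channel. With all noise terms zero the
#' extracted friction coefficient equals \code{mu_true} exactly.
#'
#' @param mu_true true friction coefficient (> 0).
#' @param trial a \code{\link{trial_config}}.
#' @param seed integer seed.
#' @return A \code{\link{force_trace}}.
#' @export
generate_force_trace <- function(mu_true, trial = trial_config(),
                                 seed = 1L) {
  stopifnot(mu_true > 0)
  set.seed(seed)
  fs <- trial$sampling_rate_hz
  n <- round(trial$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  contact <- t >= trial$pre_post_idle_s &
    t < trial$duration_s - trial$pre_post_idle_s

  fn_true <- numeric(n)
  # slow sinusoidal wander of the applied normal force (~0.2 Hz)
  wander <- trial$fn_jitter_n * sqrt(2) *
    sin(2 * pi * 0.2 * t + stats::runif(1, 0, 2 * pi))
  fn_true[contact] <- trial$fn_target_n + wander[contact]
  fn_true[contact] <- pmax(fn_true[contact], 0.1)

  phase0 <- stats::runif(1, 0, 2 * pi)
  theta <- 2 * pi * trial$circle_rate_s * t + phase0
  ff_true <- mu_true * fn_true
  fx <- ifelse(contact, ff_true * cos(theta), 0)
  fy <- ifelse(contact, ff_true * sin(theta), 0)

  noise <- function() stats::rnorm(n, 0, trial$sensor_noise_sd_n)
  force_trace(t,
              fx + if (trial$sensor_noise_sd_n > 0) noise() else 0,
              fy + if (trial$sensor_noise_sd_n > 0) noise() else 0,
              fn_true + if (trial$sensor_noise_sd_n > 0) noise() else 0)
}
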