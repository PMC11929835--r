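#' Force trace container
#'
#' A per-trial recording of the three force channels during circular
#' tactile exploration: time (s, uniform sampling, nominally 50 Hz),
#' the two tangential components Fx and Fy, and the normal force FN
#' (all N).
#'
#' @param t time stamps in seconds, strictly increasing, uniform within
#'   1 percent.
#' @param fx,fy tangential force components in N.
#' @param fn normal force in N.
#' @return Object of class \code{"force_trace"} (a data frame with
#'   columns \code{t_s}, \code{Fx_N}, \code{Fy_N}, \code{FN_N}).
#' @export
force_trace <- function(t, fx, fy, fn) {
  n <- length(t)
  stopifnot(length(fx) == n, length(fy) == n, length(fn) == n, n >= 2)
  dt <- diff(t)
  if (any(dt <= 0)) stop("time stamps must be strictly increasing")
  if ((max(dt) - min(dt)) / stats::median(dt) > 0.01)
    stop("non-uniform sampling: interval varies by more than 1%")
  structure(data.frame(t_s = t, Fx_N = fx, Fy_N = fy, FN_N = fn),
            class = c("force_trace", "data.frame"))
}

sampling_rate <- function(trace) {
  1 / stats::median(diff(trace$t_s))
}

#' Estimate unloaded-sensor noise from the leading idle window
#'
#' The noise of the unloaded force sensor is estimated as the standard
#' deviation of FN over the first second of the recording, when the
#' finger has not yet touched the sample.
#'
#' @param trace a \code{\link{force_trace}}.
#' @param window_s idle window length in seconds (default 1).
#' @return Noise estimate in N.
#' @export
estimate_sensor_noise <- function(trace, window_s = 1) {
  idx <- trace$t_s <= trace$t_s[1] + window_s
  if (sum(idx) < 3) stop("idle window too short to estimate noise")
  stats::sd(trace$FN_N[idx])
}

#' Touch mask: samples where the finger is in contact
#'
#' Touch is assumed where the normal force exceeds four times the noise
#' of the unloaded sensor.
#'
#' @param trace a \code{\link{force_trace}}.
#' @param noise_level sensor noise in N; when \code{NULL}, estimated
#'   with \code{\link{estimate_sensor_noise}}.
#' @return Logical vector, TRUE where FN > 4 * noise.
#' @export
touch_mask <- function(trace, noise_level = NULL) {
  if (is.null(noise_level)) noise_level <- estimate_sensor_noise(trace)
  if (!is.finite(noise_level) || noise_level <= 0)
    stop("noise level must be positive")
  trace$FN_N > 4 * noise_level
}

#' Per-trial friction summary from a force trace
#'
#' Computes the per-sample friction coefficient \eqn{\mu =
#' \sqrt{F_x^2 + F_y^2}/F_N} on touch samples only (samples at or below
#' the touch threshold are excluded entirely) and summarizes the trial
#' by the median \eqn{\mu} during touch, the touch duration and
#' fraction, the circling statistics, and the fraction of touch samples
#' with FN inside the instructed 0.8-1.2 N guidance band (flagged, not
#' excluded).
#'
#' @param trace a \code{\link{force_trace}}.
#' @param noise_level sensor noise in N (estimated from the leading
#'   idle window when \code{NULL}).
#' @param fn_range instructed normal-force band in N.
#' @return Object of class \code{"friction_summary"}: list with
#'   \code{mu_median}, \code{touch_fraction}, \code{touch_duration},
#'   \code{n_cycles}, \code{cycle_rate}, \code{fn_in_range_fraction},
#'   \code{noise_estimate}, \code{n_touch}. When no sample exceeds the
#'   touch threshold the trial is reported as missing
#'   (\code{mu_median = NA}, \code{missing = TRUE}).
#' @export
friction_coefficient <- function(trace, noise_level = NULL,
                                 fn_range = c(0.8, 1.2)) {
  if (is.null(noise_level)) noise_level <- estimate_sensor_noise(trace)
  mask <- touch_mask(trace, noise_level)
  dt <- stats::median(diff(trace$t_s))
  if (!any(mask)) {
    out <- list(mu_median = NA_real_, touch_fraction = 0,
                touch_duration = 0, n_cycles = NA_real_,
                cycle_rate = NA_real_, fn_in_range_fraction = NA_real_,
                noise_estimate = noise_level, n_touch = 0L,
                missing = TRUE)
    class(out) <- "friction_summary"
    return(out)
  }
  fn <- trace$FN_N[mask]
  ff <- sqrt(trace$Fx_N[mask]^2 + trace$Fy_N[mask]^2)
  mu <- ff / fn
  cyc <- cycle_rate(trace, mask)
  out <- list(
    mu_median = stats::median(mu),
    touch_fraction = mean(mask),
    touch_duration = sum(mask) * dt,
    n_cycles = cyc$n_cycles,
    cycle_rate = cyc$cycle_rate,
    fn_in_range_fraction = mean(fn >= fn_range[1] & fn <= fn_range[2]),
    noise_estimate = noise_level,
    n_touch = sum(mask),
    missing = FALSE
  )
  class(out) <- "friction_summary"
  out
}

#' @export
print.friction_summary <- function(x, ...) {
  if (isTRUE(x$missing)) {
    cat("Friction summary: no touch detected (missing trial)\n")
    return(invisible(x))
  }
  cat(sprintf("Friction summary: median mu = %.3f over %d touch samples\n",
              x$mu_median, x$n_touch))
  cat(sprintf("  touch %.1f s (%.0f%% of trial), %.1f cycles at %.2f /s\n",
              x$touch_duration, 100 * x$touch_fraction,
              x$n_cycles, x$cycle_rate))
  cat(sprintf("  FN within 0.8-1.2 N for %.0f%% of touch samples (noise %.3g N)\n",
              100 * x$fn_in_range_fraction, x$noise_estimate))
  invisible(x)
}

#' Circling statistics from the tangential force direction
#'
#' Counts exploration circles by unwrapping the phase of the tangential
#' force vector (Fx, Fy) over the touch samples; the accumulated phase
#' divided by 2 pi gives the number of cycles, and dividing by the touch
#' duration gives the circle rate.
#'
#' @param trace a \code{\link{force_trace}}.
#' @param mask logical touch mask (from \code{\link{touch_mask}}).
#' @return List with \code{n_cycles} and \code{cycle_rate} (1/s); both
#'   \code{NA} when the tangential force is degenerate (near zero)
#'   during touch or touch lasts under 1 s.
#' @export
cycle_rate <- function(trace, mask) {
  dt <- stats::median(diff(trace$t_s))
  touch_duration <- sum(mask) * dt
  if (touch_duration < 1)
    return(list(n_cycles = NA_real_, cycle_rate = NA_real_))
  fx <- trace$Fx_N[mask]; fy <- trace$Fy_N[mask]
  mag <- sqrt(fx^2 + fy^2)
  if (stats::median(mag) < 1e-9)
    return(list(n_cycles = NA_real_, cycle_rate = NA_real_))
  phase <- atan2(fy, fx)
  dphi <- diff(phase)
  dphi <- dphi - 2 * pi * round(dphi / (2 * pi))  # unwrap
  total <- abs(sum(dphi))
  n_cycles <- total / (2 * pi)
  list(n_cycles = n_cycles, cycle_rate = n_cycles / touch_duration)
}

#' Read / write force trace CSV
#'
#' Plain CSV with header columns \code{t_s, Fx_N, Fy_N, FN_N}.
#'
#' @param path file path.
#' @param trace a \code{\link{force_trace}} (for writing).
#' @return \code{read_force_trace} returns a \code{force_trace};
#'   \code{write_force_trace} the path, invisibly.
#' @export
read_force_trace <- function(path) {
  d <- utils::read.csv(path)
  need <- c("t_s", "Fx_N", "Fy_N", "FN_N")
  if (!all(need %in% names(d)))
    stop("trace CSV must have columns: ", paste(need, collapse = ", "))
  force_trace(d$t_s, d$Fx_N, d$Fy_N, d$FN_N)
}

#' @rdname read_force_trace
#' @export
write_force_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
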