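#' Micropillar sample description
#'
#' A micro-structured rubber sample: a hexagonal array of cylindrical
#' micropillars with flat tops, lattice constant (center-to-center
#' distance) equal to twice the pillar diameter.
#'
#' @param label sample label, conventionally "diameter/height" in um,
#'   e.g. \code{"100/300"}.
#' @param diameter_um pillar diameter D in micrometres.
#' @param height_um pillar height L in micrometres.
#' @param modulus_pa elastic modulus of the rubber in Pa (default 1.7 MPa).
#' @return List of class \code{"micropillar_sample"} with fields
#'   \code{label}, \code{diameter_um}, \code{height_um}, \code{spacing_um}
#'   (= 2 D), \code{modulus_pa} and \code{aspect_ratio} (= L/D).
#' @export
micropillar_sample <- function(label, diameter_um, height_um,
                               modulus_pa = 1.7e6) {
  stopifnot(diameter_um > 0, height_um > 0, modulus_pa > 0)
  structure(list(label = label,
                 diameter_um = diameter_um,
                 height_um = height_um,
                 spacing_um = 2 * diameter_um,
                 modulus_pa = modulus_pa,
                 aspect_ratio = height_um / diameter_um),
            class = "micropillar_sample")
}

#' @export
print.micropillar_sample <- function(x, ...) {
  cat(sprintf(
    "Micropillar sample %s: D = %g um, L = %g um (aspect ratio %.2f)\n",
    x$label, x$diameter_um, x$height_um, x$aspect_ratio))
  cat(sprintf("  pillar density    %.1f mm^-2\n", pillar_density(x$diameter_um)))
  cat(sprintf("  bending stiffness %.3g N/rad\n", bending_stiffness(x)))
  invisible(x)
}

#' The six micropillar geometries of the stimulus set
#'
#' @return Data frame with one row per sample (labels 40/120, 100/100,
#'   100/200, 100/300, 150/150, 150/350) and columns \code{label},
#'   \code{diameter_um}, \code{height_um}, \code{aspect_ratio},
#'   \code{density_mm2}, \code{stiffness_n_per_rad}.
#' @export
micropillar_samples <- function() {
  d <- c(40, 100, 100, 100, 150, 150)
  l <- c(120, 100, 200, 300, 150, 350)
  lab <- paste(d, l, sep = "/")
  data.frame(
    label = lab,
    diameter_um = d,
    height_um = l,
    aspect_ratio = l / d,
    density_mm2 = pillar_density(d),
    stiffness_n_per_rad = vapply(seq_along(d), function(i)
      bending_stiffness(micropillar_sample(lab[i], d[i], l[i])), numeric(1))
  )
}

#' RMS curvatures of the six randomly rough plastic samples
#'
#' Fixed surface constants of the rough stimulus set: each sample has
#' overall RMS roughness Sq = 0.4 mm but different small-scale roughness,
#' quantified by the RMS curvature of its height function. The mapping of
#' curvature values onto the S-labels is a package convention (lowest
#' curvature = S01 ... highest = S09); it is synthetic in the sense that
#' the original sample bookkeeping is not public.
#'
#' @return Named numeric vector of RMS curvatures in mm^-1.
#' @export
rough_sample_curvatures <- function() {
  c(S01 = 1.00, S02 = 1.09, S03 = 1.76, S07 = 1.93, S08 = 3.03, S09 = 3.29)
}

#' Areal density of a hexagonal micropillar lattice
#'
#' For a hexagonal lattice with lattice constant a = 2D the unit-cell
#' area is \eqn{\sqrt{3}/2 \, a^2 = 2\sqrt{3} D^2}, hence the density is
#' \eqn{1 / (2\sqrt{3} D^2)} pillars per unit area.
#'
#' @param diameter_um pillar diameter in micrometres (vectorized).
#' @return Pillar density in mm^-2.
#' @examples
#' pillar_density(40)   # ~180 mm^-2
#' pillar_density(150)  # ~12.8 mm^-2
#' @export
pillar_density <- function(diameter_um) {
  if (any(diameter_um <= 0)) stop("diameter must be positive")
  d_mm <- diameter_um / 1000
  1 / (2 * sqrt(3) * d_mm^2)
}

#' Bending stiffness of a micropillar
#'
#' Lateral force per bending angle of a cylindrical pillar loaded at its
#' top: \eqn{F_L/\theta = \pi E D^4 / (32 L^2)}, in N/rad (SI units
#' internally; D and L are given in micrometres).
#'
#' @param sample a \code{\link{micropillar_sample}}, or a diameter in um
#'   if \code{height_um} is also given.
#' @param height_um pillar height in um (when \code{sample} is a number).
#' @param modulus_pa elastic modulus in Pa (when \code{sample} is a
#'   number).
#' @return Bending stiffness in N/rad.
#' @examples
#' bending_stiffness(100, 100)  # ~1.67e-3 N/rad
#' @export
bending_stiffness <- function(sample, height_um = NULL, modulus_pa = 1.7e6) {
  if (inherits(sample, "micropillar_sample")) {
    d <- sample$diameter_um; l <- sample$height_um; e <- sample$modulus_pa
  } else {
    stopifnot(is.numeric(sample), !is.null(height_um))
    d <- sample; l <- height_um; e <- modulus_pa
  }
  d_m <- d * 1e-6; l_m <- l * 1e-6
  pi * e * d_m^4 / (32 * l_m^2)
}

#' Synthesize a self-affine randomly rough surface
#'
#' Spectral (Fourier-filtering) synthesis of an isotropic self-affine
#' height map: independent Gaussian Fourier amplitudes are shaped by a
#' power spectrum \eqn{C(q) \propto q^{-2-2H}} between a long- and a
#' short-wavelength cutoff, transformed to real space, and rescaled so
#' the realized RMS roughness equals \code{sq_mm} exactly.
#'
#' @param sq_mm target RMS roughness Sq in mm.
#' @param hurst Hurst exponent H in (0, 1); larger H means smoother at
#'   small scales.
#' @param n_grid grid size (power of two), default 256.
#' @param dx_mm grid spacing in mm, default 0.1.
#' @param seed integer seed.
#' @param lambda_short_mm short-wavelength cutoff (default 0.5 mm, the
#'   smallest wavelength present on the physical samples).
#' @param lambda_long_mm long-wavelength cutoff (default: half the grid
#'   extent).
#' @return Object of class \code{"height_map"}: list with \code{h}
#'   (n x n matrix, mm), \code{dx_mm}, \code{sq_mm}, \code{hurst} and the
#'   cutoffs.
#' @export
synthesize_self_affine_surface <- function(sq_mm, hurst, n_grid = 256,
                                           dx_mm = 0.1, seed = 1L,
                                           lambda_short_mm = 0.5,
                                           lambda_long_mm = NULL) {
  stopifnot(sq_mm > 0, hurst > 0, hurst < 1, n_grid >= 8)
  if (bitwAnd(n_grid, n_grid - 1L) != 0L)
    stop("n_grid must be a power of two")
  extent <- n_grid * dx_mm
  if (is.null(lambda_long_mm)) lambda_long_mm <- extent / 2
  nyquist_lambda <- 2 * dx_mm
  if (lambda_short_mm < nyquist_lambda || lambda_long_mm > extent)
    stop("wavelength cutoffs outside the resolvable range of the grid")
  if (lambda_short_mm >= lambda_long_mm)
    stop("short-wavelength cutoff must be below the long-wavelength cutoff")

  freq <- c(0:(n_grid / 2), -(n_grid / 2 - 1):-1) / extent  # cycles/mm
  qx <- matrix(2 * pi * freq, n_grid, n_grid)
  qy <- t(qx)
  q <- sqrt(qx^2 + qy^2)
  q_lo <- 2 * pi / lambda_long_mm
  q_hi <- 2 * pi / lambda_short_mm
  amp <- ifelse(q >= q_lo & q <= q_hi, q^(-1 - hurst), 0)  # sqrt of PSD

  set.seed(seed)
  phase <- matrix(stats::rnorm(n_grid^2) + 1i * stats::rnorm(n_grid^2),
                  n_grid, n_grid)
  h <- Re(stats::fft(amp * phase, inverse = TRUE)) / n_grid^2
  h <- h - mean(h)
  rms <- sqrt(mean(h^2))
  if (rms == 0) stop("degenerate spectrum: no power in passband")
  h <- h * (sq_mm / rms)
  structure(list(h = h, dx_mm = dx_mm, sq_mm = sq_mm, hurst = hurst,
                 lambda_short_mm = lambda_short_mm,
                 lambda_long_mm = lambda_long_mm),
            class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf(
    "Self-affine height map: %d x %d grid, dx = %g mm, Sq = %g mm, H = %g\n",
    nrow(x$h), ncol(x$h), x$dx_mm, x$sq_mm, x$hurst))
  cat(sprintf("  RMS curvature %.2f mm^-1\n", rms_curvature(x)))
  invisible(x)
}

#' RMS roughness of a height map
#'
#' @param hm a \code{"height_map"} or a numeric matrix of heights (mm).
#' @return RMS of the mean-centered heights, mm.
#' @export
rms_roughness <- function(hm) {
  h <- if (inherits(hm, "height_map")) hm$h else as.matrix(hm)
  h <- h - mean(h)
  sqrt(mean(h^2))
}

#' RMS curvature of a height map
#'
#' Small-scale roughness measure: the square root of the mean squared
#' second derivative of the height function, estimated by central second
#' differences along each grid axis and combined over the two orthogonal
#' directions, \eqn{\kappa = \sqrt{\langle h_{xx}^2\rangle +
#' \langle h_{yy}^2\rangle}}. For a surface varying along one direction
#' only (e.g. \eqn{h = A \sin qx}) this reduces to the one-dimensional
#' profile value \eqn{A q^2/\sqrt 2}.
#'
#' @param hm a \code{"height_map"} or numeric matrix of heights (mm).
#' @param dx_mm grid spacing in mm (taken from the height map if given).
#' @return RMS curvature in mm^-1.
#' @export
rms_curvature <- function(hm, dx_mm = NULL) {
  if (inherits(hm, "height_map")) {
    h <- hm$h; dx_mm <- hm$dx_mm
  } else {
    h <- as.matrix(hm)
    if (is.null(dx_mm)) stop("dx_mm required for a plain matrix")
  }
  if (nrow(h) < 3 || ncol(h) < 3) stop("grid must be at least 3 x 3")
  n <- nrow(h); m <- ncol(h)
  d2x <- (h[1:(n - 2), ] - 2 * h[2:(n - 1), ] + h[3:n, ]) / dx_mm^2
  d2y <- (h[, 1:(m - 2)] - 2 * h[, 2:(m - 1)] + h[, 3:m]) / dx_mm^2
  sqrt(mean(d2x^2) + mean(d2y^2))
}

#' Radially averaged power spectrum of a height map
#'
#' Utility for verifying the self-affine scaling: returns the isotropic
#' power spectral density binned over wavevector magnitude, suitable for
#' a log-log slope check against -2-2H.
#'
#' @param hm a \code{"height_map"}.
#' @param n_bins number of logarithmic q bins.
#' @return Data frame with columns \code{q} (rad/mm) and \code{psd}.
#' @export
radial_psd <- function(hm, n_bins = 24) {
  stopifnot(inherits(hm, "height_map"))
  h <- hm$h
  n <- nrow(h)
  extent <- n * hm$dx_mm
  spec <- Mod(stats::fft(h))^2 / n^4
  freq <- c(0:(n / 2), -(n / 2 - 1):-1) / extent
  qx <- matrix(2 * pi * freq, n, n)
  q <- sqrt(qx^2 + t(qx)^2)
  q_lo <- 2 * pi / hm$lambda_long_mm
  q_hi <- 2 * pi / hm$lambda_short_mm
  keep <- q > q_lo & q < q_hi
  br <- exp(seq(log(q_lo), log(q_hi), length.out = n_bins + 1))
  bin <- cut(q[keep], br, include.lowest = TRUE)
  out <- data.frame(q = as.numeric(tapply(q[keep], bin, mean)),
                    psd = as.numeric(tapply(spec[keep], bin, mean)))
  out[is.finite(out$q) & is.finite(out$psd) & out$psd > 0, ]
}

#' Write / read a height map as plain-text CSV
#'
#' The matrix is stored row-wise with a small comment header carrying
#' \code{dx_mm}, \code{sq_mm} and \code{hurst}.
#'
#' @param hm a \code{"height_map"}.
#' @param path file path.
#' @return \code{write_height_map} returns the path invisibly;
#'   \code{read_height_map} returns a \code{"height_map"}.
#' @export
write_height_map <- function(hm, path) {
  stopifnot(inherits(hm, "height_map"))
  hdr <- sprintf("# dx_mm=%.10g sq_mm=%.10g hurst=%.10g lambda_short_mm=%.10g lambda_long_mm=%.10g",
                 hm$dx_mm, hm$sq_mm, hm$hurst,
                 hm$lambda_short_mm, hm$lambda_long_mm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(hm$h, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_height_map
#' @export
read_height_map <- function(path) {
  hdr <- readLines(path, n = 1)
  if (!startsWith(hdr, "#")) stop("missing height-map header line")
  kv <- strsplit(trimws(sub("^#", "", hdr)), "\\s+")[[1]]
  meta <- stats::setNames(
    as.numeric(sub(".*=", "", kv)), sub("=.*", "", kv))
  h <- as.matrix(utils::read.csv(path, header = FALSE, skip = 1))
  dimnames(h) <- NULL
  structure(list(h = h, dx_mm = meta[["dx_mm"]], sq_mm = meta[["sq_mm"]],
                 hurst = meta[["hurst"]],
                 lambda_short_mm = meta[["lambda_short_mm"]],
                 lambda_long_mm = meta[["lambda_long_mm"]]),
            class = "height_map")
}
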