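#' Conversion factor between half-height width and standard deviation
#'
#' For a Gaussian peak the full width at half maximum relates to the standard
#' deviation as `omega_half = phi_fwhm * sigma` with
#' `phi_fwhm = 2 * sqrt(2 * log(2))` (about 2.3548).  The same relation is used
#' as an approximation for mildly skewed inverse-Gaussian peak shapes.
#'
#' @format A length-one numeric.
#' @export
phi_fwhm <- 2 * sqrt(2 * log(2))

#' Shifted inverse-Gaussian parameter set
#'
#' The one-dimensional peak model used on both the drift-time (IRM) axis and
#' the retention-time axis is a shifted inverse-Gaussian density with shape
#' parameters `mu` (relative mean, distance of the mean from the offset),
#' `lambda` (shape) and `shift` (offset `o`; the density is zero at and below
#' the offset).
#'
#' @param mu Relative mean, must be positive (axis units).
#' @param lambda Shape parameter, must be positive (axis units).
#' @param shift Offset `o` (axis units); the support is `(shift, Inf)`.
#' @return An object of class `sig_params` (a named list).
#' @seealso [sig_descriptors()], [dsig()]
#' @export
sig_params <- function(mu, lambda, shift = 0) {
  if (!is.numeric(mu) || !is.numeric(lambda) || !is.numeric(shift) ||
      length(mu) != 1L || length(lambda) != 1L || length(shift) != 1L ||
      !is.finite(mu) || !is.finite(lambda) || !is.finite(shift)) {
    stop("mu, lambda and shift must be finite scalars")
  }
  if (mu <= 0) stop("invalid parameter: mu must be > 0")
  if (lambda <= 0) stop("invalid parameter: lambda must be > 0")
  structure(list(mu = mu, lambda = lambda, shift = shift),
            class = "sig_params")
}

#' Shifted inverse-Gaussian descriptor set
#'
#' An equivalent, more intuitive parameterisation of the shifted
#' inverse-Gaussian: absolute mean `mean` (`= mu + shift`), standard deviation
#' `sigma` and mode `mode`.  A right-skewed density always has
#' `mode < mean`.
#'
#' @param mean Absolute mean (axis units).
#' @param sigma Standard deviation, must be positive.
#' @param mode Mode of the density (axis units); must be smaller than `mean`.
#' @return An object of class `sig_descriptors` (a named list).
#' @seealso [sig_params()], [sig_from_descriptors()]
#' @export
sig_descriptors <- function(mean, sigma, mode) {
  if (!all(is.finite(c(mean, sigma, mode)))) {
    stop("mean, sigma and mode must be finite")
  }
  if (sigma <= 0) stop("invalid descriptor: sigma must be > 0")
  if (mode >= mean) stop("invalid descriptor: mode must be < mean (right skew)")
  structure(list(mean = mean, sigma = sigma, mode = mode),
            class = "sig_descriptors")
}

#' Shifted inverse-Gaussian density
#'
#' Density of the shifted inverse-Gaussian distribution, the one-dimensional
#' peak model.  It is zero for `x <= shift` and integrates to one over
#' `(shift, Inf)`.
#'
#' @param x Numeric vector of axis values.
#' @param mu Relative mean (> 0), or a [sig_params()] object (then `lambda`
#'   and `shift` are ignored).
#' @param lambda Shape parameter (> 0).
#' @param shift Offset.
#' @return Numeric vector of densities.
#' @examples
#' dsig(1, mu = 1, lambda = 1, shift = 0)  # exponent vanishes: 1/sqrt(2*pi)
#' @export
dsig <- function(x, mu, lambda = NULL, shift = 0) {
  if (inherits(mu, "sig_params")) {
    p <- mu
    mu <- p$mu; lambda <- p$lambda; shift <- p$shift
  }
  if (mu <= 0 || lambda <= 0) stop("invalid parameter: mu and lambda must be > 0")
  y <- x - shift
  d <- numeric(length(x))
  ok <- is.finite(y) & y > 0
  yy <- y[ok]
  d[ok] <- sqrt(lambda / (2 * pi * yy^3)) *
    exp(-lambda * (yy - mu)^2 / (2 * mu^2 * yy))
  d
}

# log-density gradient of dsig w.r.t. (mu, lambda, shift), used by the
# tailing-function optimiser; returns a list of vectors aligned with x,
# zero outside the support.
dsig_grad_log <- function(x, mu, lambda, shift) {
  y <- x - shift
  ok <- y > 0
  gmu <- glam <- gshift <- numeric(length(x))
  yy <- y[ok]
  gmu[ok] <- lambda * (yy - mu) / mu^3
  glam[ok] <- 1 / (2 * lambda) - (yy - mu)^2 / (2 * mu^2 * yy)
  gshift[ok] <- 3 / (2 * yy) + lambda * (yy^2 - mu^2) / (2 * mu^2 * yy^2)
  list(mu = gmu, lambda = glam, shift = gshift)
}

#' Convert shifted inverse-Gaussian parameters to descriptors
#'
#' @param p A [sig_params()] object.
#' @return A [sig_descriptors()] object with `mean = mu + shift`,
#'   `sigma = sqrt(mu^3 / lambda)` and the closed-form mode.
#' @export
sig_to_descriptors <- function(p) {
  stopifnot(inherits(p, "sig_params"))
  mu <- p$mu; lambda <- p$lambda; o <- p$shift
  m <- mu * (sqrt(1 + (9 * mu^2) / (4 * lambda^2)) - (3 * mu) / (2 * lambda)) + o
  sig_descriptors(mean = mu + o, sigma = sqrt(mu^3 / lambda), mode = m)
}

#' Convert shifted inverse-Gaussian descriptors to parameters
#'
#' Inverts [sig_to_descriptors()].  The offset is a root of a quadratic
#' `o^2 + p*o + q = 0` whose two roots are, in general, *both* exact
#' pre-images: the descriptor map is two-to-one, pairing a mildly skewed
#' shape (`3 mu / (2 lambda) < 1`) with a heavily skewed one sharing the same
#' mean, standard deviation and mode.  The `skew` argument selects the
#' branch: `"min"` (default) returns the flatter, near-Gaussian shape
#' appropriate for peak models; `"max"` returns the spiked, long-tailed
#' shape used for the tailing function, whose offset lies close to the mode.
#' A root is admissible only if it yields `mu > 0`, `lambda > 0`,
#' `shift < mode` and reproduces the descriptors within `tol`; if the
#' preferred branch is inadmissible the other branch is used.
#'
#' @param d A [sig_descriptors()] object.
#' @param tol Relative round-trip tolerance used to validate the conversion.
#' @param skew Branch selection, `"min"` or `"max"`.
#' @return A [sig_params()] object.
#' @export
sig_from_descriptors <- function(d, tol = 1e-6, skew = c("min", "max")) {
  stopifnot(inherits(d, "sig_descriptors"))
  skew <- match.arg(skew)
  mp0 <- d$mean; s <- d$sigma; m0 <- d$mode
  if (m0 >= mp0) stop("conversion failure: mode must be < mean")
  # translate so the mean sits at zero: the quadratic's coefficients are
  # then O(sigma, mode - mean) and free of the catastrophic cancellation
  # that a large absolute position causes
  m <- m0 - mp0
  mp <- 0
  pp <- (-m * (2 * mp + m) + 3 * (mp^2 - s^2)) / (2 * (m - mp))
  qq <- (m * (3 * s^2 + mp * m) - mp^3) / (2 * (m - mp))
  disc <- pp^2 / 4 - qq
  if (!is.finite(disc) || disc < 0) {
    stop("conversion failure: negative discriminant")
  }
  # minus root: smaller offset, larger mu, milder skew; plus root: offset
  # near the mode, heavy skew
  roots <- c(-pp / 2 - sqrt(disc), -pp / 2 + sqrt(disc))
  if (skew == "max") roots <- rev(roots)
  mp <- mp0
  m <- m0
  for (o in roots + mp0) {
    mu <- mp - o
    if (!is.finite(mu) || mu <= 0 || o >= m) next
    lambda <- mu^3 / s^2
    if (!is.finite(lambda) || lambda <= 0) next
    cand <- sig_params(mu, lambda, o)
    back <- sig_to_descriptors(cand)
    scale <- max(abs(c(mp, s, m)), 1e-12)
    err <- max(abs(c(back$mean - mp, back$sigma - s, back$mode - m))) / scale
    if (err <= tol) return(cand)
  }
  stop("conversion failure: no root reproduces the descriptors")
}

#' Convert a half-height width to a standard deviation
#'
#' @param omega_half Full width at half maximum (must be non-negative).
#' @return `omega_half / phi_fwhm`.
#' @export
halfwidth_sigma <- function(omega_half) {
  if (any(omega_half < 0)) stop("omega_half must be >= 0")
  omega_half / phi_fwhm
}

#' Instrument and algorithm configuration
#'
#' Bundles the spectrometer constants and the tunable algorithm parameters
#' used throughout the pipeline.  Drift times are in milliseconds, retention
#' times in seconds and inverse reduced mobilities (IRM) in V s cm^-2;
#' conversions between drift time and IRM always go through `c_t_given_d`.
#'
#' @param c_t_given_d IRM per drift time (V s cm^-2 per ms).
#' @param d_grid Ion-shutter grid opening time (ms).
#' @param d_last Maximum drift time recorded (ms).
#' @param t_last Maximum IRM recorded; defaults to `c_t_given_d * d_last`.
#' @param n_drift Samples per spectrum.
#' @param diffusion_coeff Ion diffusion coefficient (m^2/s).  If `NULL` it is
#'   computed from the Einstein relation `k * k_B * T / q` using
#'   `ion_mobility`, `temperature`, `boltzmann` and `charge`.
#' @param ion_mobility Ion mobility (m^2 V^-1 s^-1).
#' @param temperature Absolute drift-gas temperature (K).
#' @param boltzmann Boltzmann constant (J/K).
#' @param charge Elementary charge (C).
#' @param drift_velocity Mean ion drift velocity (m/s).
#' @param r_width_offset Peak width at half height at retention time 0 (s).
#' @param r_width_factor Slope of the retention peak width (dimensionless).
#' @param t_width Minimum peak standard deviation in IRM (V s cm^-2).
#' @param noise_margin Minimum peak height, in multiples of the noise standard
#'   deviation.
#' @param rho_min Minimum Pearson correlation between a retention peak model
#'   and its quadratic approximation.
#' @param thresh EM convergence threshold on the relative parameter change.
#' @param nllm_max_iter Iteration cap per stage of the tailing-function
#'   gradient descent.
#' @param em_max_iter Iteration cap for the denoising EM.
#' @param cluster_max_iter Iteration cap for the clustering EM.
#' @param scan_shrink Fraction of a scan window in which a parabola vertex is
#'   accepted (condition on peak windows).
#' @param scan_advance Window advance after a detection: `"half"` (half the
#'   window length) or `"alpha"` (the smoothing margin, in samples).
#' @param width_check_mode How the retention width filter compares `sigma` to
#'   the expected width: `"phi_sigma"` uses the half-width relation
#'   `omega = phi * sigma`; `"as_printed"` uses `sigma / phi`.
#' @param weight_volume_sum If `TRUE`, the per-component spectrum-scale sum in
#'   the final volume is membership-weighted instead of running over all chain
#'   members.
#' @param min_chain_length Minimum chain length forwarded to 2-D estimation.
#' @param calib_spectra Number of leading spectra used to calibrate the
#'   spread of the reactant-ion-peak-only spectrum.
#' @param zero_floor Corrected intensities below `zero_floor * sigma_n` are
#'   truncated to exactly zero (numerically negligible signal).
#' @param drop_rip If `TRUE`, 1-D peaks at the reactant ion peak position are
#'   dropped from the per-spectrum peak lists.
#' @param rip_irm Nominal IRM of the reactant ion peak (used with `drop_rip`).
#' @return An object of class `ims_config` (a named list).
#' @export
ims_config <- function(c_t_given_d = 0.029,
                       d_grid = 0.3,
                       d_last = 50,
                       t_last = NULL,
                       n_drift = 12500,
                       diffusion_coeff = NULL,
                       ion_mobility = 2.0e-4,
                       temperature = 313.15,
                       boltzmann = 1.380649e-23,
                       charge = 1.602176634e-19,
                       drift_velocity = 7,
                       r_width_offset = 2.5,
                       r_width_factor = 0.06,
                       t_width = 0.003,
                       noise_margin = 4,
                       rho_min = 0.95,
                       thresh = 0.001,
                       nllm_max_iter = 500,
                       em_max_iter = 100,
                       cluster_max_iter = 500,
                       scan_shrink = 0.8,
                       scan_advance = c("half", "alpha"),
                       width_check_mode = c("phi_sigma", "as_printed"),
                       weight_volume_sum = FALSE,
                       min_chain_length = 2,
                       calib_spectra = 3,
                       zero_floor = 1e-3,
                       drop_rip = FALSE,
                       rip_irm = 0.48) {
  if (is.null(t_last)) t_last <- c_t_given_d * d_last
  if (is.null(diffusion_coeff)) {
    diffusion_coeff <- ion_mobility * boltzmann * temperature / charge
  }
  cfg <- list(
    c_t_given_d = c_t_given_d, d_grid = d_grid, d_last = d_last,
    t_last = t_last, n_drift = n_drift,
    diffusion_coeff = diffusion_coeff, ion_mobility = ion_mobility,
    temperature = temperature, boltzmann = boltzmann, charge = charge,
    drift_velocity = drift_velocity,
    r_width_offset = r_width_offset, r_width_factor = r_width_factor,
    t_width = t_width, noise_margin = noise_margin, rho_min = rho_min,
    thresh = thresh, nllm_max_iter = nllm_max_iter,
    em_max_iter = em_max_iter,
    cluster_max_iter = cluster_max_iter,
    scan_shrink = scan_shrink,
    scan_advance = match.arg(scan_advance),
    width_check_mode = match.arg(width_check_mode),
    weight_volume_sum = isTRUE(weight_volume_sum),
    min_chain_length = min_chain_length,
    calib_spectra = calib_spectra, zero_floor = zero_floor,
    drop_rip = isTRUE(drop_rip), rip_irm = rip_irm
  )
  num <- c("c_t_given_d", "d_grid", "d_last", "t_last", "n_drift",
           "diffusion_coeff", "drift_velocity", "r_width_offset",
           "r_width_factor", "t_width", "noise_margin", "rho_min", "thresh")
  for (f in num) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L ||
        !is.finite(cfg[[f]]) || cfg[[f]] <= 0) {
      stop("invalid config: ", f, " must be a positive scalar")
    }
  }
  structure(cfg, class = "ims_config")
}

#' Read an instrument configuration from a YAML or JSON file
#'
#' The file holds a flat mapping whose keys mirror the [ims_config()]
#' argument names; missing keys fall back to the defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An [ims_config()] object.
#' @export
read_ims_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(ims_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(ims_config, vals)
}

#' Estimate IRM-axis peak descriptors from a drift-time mode
#'
#' Given the drift-time mode `d_star` (ms) of a peak, predicts its descriptors
#' on the IRM axis: the mode is `c_t_given_d * d_star`; the half-height width
#' follows the Spangler broadening formula
#' `omega = sqrt(11.09 * D * d / v_d^2 + d_grid^2)` (with `d`, `d_grid` in
#' seconds), converted to a standard deviation via [halfwidth_sigma()]; the
#' mean uses an empirical instrument relation (see [ims_config()] notes).
#'
#' @param d_star Drift-time mode (ms), positive.
#' @param cfg An [ims_config()].
#' @return A [sig_descriptors()] object in IRM units.
#' @export
drift_to_descriptors <- function(d_star, cfg) {
  stopifnot(inherits(cfg, "ims_config"))
  if (!is.finite(d_star) || d_star <= 0) stop("d_star must be > 0")
  ds <- d_star / 1000                       # s
  omega_s <- sqrt(11.09 * cfg$diffusion_coeff * ds / cfg$drift_velocity^2 +
                    (cfg$d_grid / 1000)^2)  # s
  sigma <- cfg$c_t_given_d * (omega_s * 1000) / phi_fwhm
  mode <- cfg$c_t_given_d * d_star
  mean <- cfg$c_t_given_d *
    (d_star + sqrt((4.246e-5)^2 + d_star^2 / 585048.1633))
  sig_descriptors(mean = mean, sigma = sigma, mode = mode)
}

#' Expected retention-time peak width at half height
#'
#' Peak widths grow approximately linearly with retention time:
#' `xi(r) = r * r_width_factor + r_width_offset` (seconds).
#'
#' @param r Retention time(s) in seconds, non-negative.
#' @param cfg An [ims_config()].
#' @return Width(s) at half height in seconds.
#' @export
ret_width <- function(r, cfg) {
  stopifnot(inherits(cfg, "ims_config"))
  if (any(r < 0)) stop("retention time must be >= 0")
  r * cfg$r_width_factor + cfg$r_width_offset
}
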