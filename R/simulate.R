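#' Random numbers from the shifted inverse-Gaussian distribution
#'
#' Transformation sampler (Michael, Schucany and Haas 1976): a chi-square
#' draw is mapped onto the two roots of the inverse-Gaussian quantile
#' relation and one root is picked with the appropriate probability.
#'
#' @param n Number of draws.
#' @param mu Relative mean (> 0).
#' @param lambda Shape (> 0).
#' @param shift Offset added to every draw.
#' @return Numeric vector of length `n`, all values `> shift`.
#' @export
rsig <- function(n, mu, lambda, shift = 0) {
  if (mu <= 0 || lambda <= 0) stop("mu and lambda must be > 0")
  z <- stats::rnorm(n)^2
  x1 <- mu + (mu^2 * z - mu * sqrt(4 * mu * lambda * z + mu^2 * z^2)) /
    (2 * lambda)
  u <- stats::runif(n)
  x <- ifelse(u <= mu / (mu + x1), x1, mu^2 / x1)
  x + shift
}

#' Simulate a noise + signal intensity mixture
#'
#' Draws `n` intensities from the three-part model assumed for a single IM
#' spectrum: with probability `w_n` Gaussian background noise, otherwise the
#' noise mean plus an inverse-Gaussian signal intensity.  Used to exercise
#' the denoising EM with known ground truth.
#'
#' @param n Sample size.
#' @param w_n Noise weight in `[0, 1]`.
#' @param mu_n,sigma_n Noise Gaussian parameters.
#' @param mu_s,lam_s Signal inverse-Gaussian parameters (relative to the
#'   noise mean).
#' @return An [ims_spectrum()] whose intensities are the sampled mixture (the
#'   IRM axis is an arbitrary unit grid).
#' @export
simulate_intensity_mixture <- function(n = 12500, w_n = 0.7,
                                       mu_n = 5, sigma_n = 1,
                                       mu_s = 10, lam_s = 30) {
  is_noise <- stats::runif(n) < w_n
  s <- numeric(n)
  s[is_noise] <- stats::rnorm(sum(is_noise), mu_n, sigma_n)
  s[!is_noise] <- rsig(sum(!is_noise), mu_s, lam_s, shift = mu_n)
  ims_spectrum(s, seq(0.01, 1.45, length.out = n))
}

#' Build the ground-truth parameter table for simulated 2-D peaks
#'
#' Converts peak positions and apex heights into full seven-parameter 2-D
#' models using the same empirical width relations the extractor assumes:
#' IRM descriptors from the drift-time mode via [drift_to_descriptors()],
#' retention spread `xi(r)/phi` and mean `r + xi(r)/(4 phi)`.
#'
#' @param r_mode,t_mode,height Equal-length vectors of retention modes (s),
#'   IRM modes (V s cm^-2) and apex heights (device units).
#' @param cfg An [ims_config()].
#' @return A data frame with the positions, heights, descriptors and raw
#'   parameters of every peak.
#' @export
peak_truth_table <- function(r_mode, t_mode, height, cfg) {
  stopifnot(length(r_mode) == length(t_mode),
            length(r_mode) == length(height))
  rows <- lapply(seq_along(r_mode), function(i) {
    dt <- drift_to_descriptors(t_mode[i] / cfg$c_t_given_d, cfg)
    pt <- sig_from_descriptors(dt)
    xi_r <- ret_width(r_mode[i], cfg)
    dr <- sig_descriptors(mean = r_mode[i] + xi_r / (4 * phi_fwhm),
                          sigma = xi_r / phi_fwhm, mode = r_mode[i])
    pr <- sig_from_descriptors(dr)
    amp <- height[i] / (dsig(dr$mode, pr) * dsig(dt$mode, pt))
    data.frame(r_mode = r_mode[i], t_mode = t_mode[i], height = height[i],
               amplitude = amp,
               r_mean = dr$mean, r_sigma = dr$sigma,
               t_mean = dt$mean, t_sigma = dt$sigma,
               mu_r = pr$mu, lambda_r = pr$lambda, o_r = pr$shift,
               mu_t = pt$mu, lambda_t = pt$lambda, o_t = pt$shift)
  })
  do.call(rbind, rows)
}

#' Simulate a full IM spectrum-chromatogram
#'
#' Forward model of a measurement: every 2-D peak is a product of two
#' shifted inverse-Gaussians scaled to a stated apex height; each spectrum
#' additionally carries the reactant ion peak (RIP), its right-skewed
#' tailing baseline, a constant intensity offset at the noise mean and
#' additive Gaussian noise.  Deterministic for a given seed.
#'
#' @param peaks Data frame with columns `r` (retention mode, s), `t` (IRM
#'   mode) and `height` (apex height above baseline).  `NULL` gives a
#'   peak-free (RIP-only) measurement.
#' @param n_spectra,n_drift Grid sizes (retention x drift).
#' @param dr Retention spacing between consecutive spectra (s).
#' @param cfg An [ims_config()].
#' @param noise_mu,noise_sigma Gaussian noise parameters (device units).
#' @param rip Include the RIP and its tailing?
#' @param rip_irm RIP position (IRM).
#' @param rip_height RIP apex height.
#' @param tail_height Tailing baseline level a quarter IRM unit right of the
#'   RIP.
#' @param clamp Clamp negative intensities at zero (detector behaviour).
#' @param seed Optional integer seed.
#' @return A list of class `imsc` with `matrix` (`n_spectra x n_drift`),
#'   `retention`, `drift` (ms), `irm`, the `truth` table from
#'   [peak_truth_table()] and the noise parameters.
#' @export
simulate_imsc <- function(peaks = NULL, n_spectra = 200, n_drift = 2500,
                          dr = 0.5, cfg = ims_config(n_drift = n_drift),
                          noise_mu = 5, noise_sigma = 1,
                          rip = TRUE, rip_irm = 0.48, rip_height = 150,
                          tail_height = 8, clamp = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  retention <- seq(0, by = dr, length.out = n_spectra)
  drift <- seq_len(n_drift) / n_drift * cfg$d_last
  irm <- cfg$c_t_given_d * drift
  S <- matrix(0, n_spectra, n_drift)
  truth <- NULL
  if (!is.null(peaks) && nrow(peaks)) {
    truth <- peak_truth_table(peaks$r, peaks$t, peaks$height, cfg)
    for (i in seq_len(nrow(truth))) {
      gr <- dsig(retention, truth$mu_r[i], truth$lambda_r[i], truth$o_r[i])
      gt <- dsig(irm, truth$mu_t[i], truth$lambda_t[i], truth$o_t[i])
      S <- S + truth$amplitude[i] * outer(gr, gt)
    }
  }
  if (rip) {
    rip_desc <- drift_to_descriptors(rip_irm / cfg$c_t_given_d, cfg)
    rip_par <- sig_from_descriptors(rip_desc)
    rip_prof <- rip_height / dsig(rip_desc$mode, rip_par) * dsig(irm, rip_par)
    # tailing: heavily skewed, support rising just left of the RIP, with a
    # slowly decaying right tail that forms a visible baseline under the
    # analyte peaks; tail_height sets the baseline level a quarter IRM unit
    # right of the RIP
    tail_par <- sig_params(mu = 0.2, lambda = 0.05, shift = rip_irm - 0.02)
    tail_prof <- tail_height / dsig(rip_irm + 0.25, tail_par) *
      dsig(irm, tail_par)
    S <- S + matrix(rip_prof + tail_prof, n_spectra, n_drift, byrow = TRUE)
  }
  S <- S + noise_mu +
    matrix(stats::rnorm(n_spectra * n_drift, 0, noise_sigma),
           n_spectra, n_drift)
  if (clamp) S <- pmax(S, 0)
  structure(list(matrix = S, retention = retention, drift = drift, irm = irm,
                 truth = truth, noise_mu = noise_mu,
                 noise_sigma = noise_sigma, cfg = cfg),
            class = "imsc")
}

#' Random well-separated peak positions for a simulated measurement
#'
#' Draws `n` peak positions uniformly over the analyte region (right of the
#' RIP, away from the measurement borders), rejecting draws closer than
#' `min_t` in IRM *and* `min_r` in retention time to an accepted peak.
#'
#' @param n Number of peaks.
#' @param height Apex height given to every peak.
#' @param t_range,r_range Sampling rectangles.
#' @param min_t,min_r Minimum separations.
#' @return A data frame with columns `r`, `t`, `height` for
#'   [simulate_imsc()].
#' @export
random_peak_positions <- function(n = 5, height = 10,
                                  t_range = c(0.6, 1.25),
                                  r_range = c(20, 85),
                                  min_t = 0.05, min_r = 12) {
  r <- t <- numeric(0)
  tries <- 0L
  while (length(r) < n && tries < 10000L) {
    tries <- tries + 1L
    ct <- stats::runif(1, t_range[1L], t_range[2L])
    cr <- stats::runif(1, r_range[1L], r_range[2L])
    if (length(r) == 0L || all(abs(t - ct) > min_t | abs(r - cr) > min_r)) {
      t <- c(t, ct); r <- c(r, cr)
    }
  }
  if (length(r) < n) stop("could not place the requested number of peaks")
  data.frame(r = r, t = t, height = height)
}

# sample one point inside an axis-aligned ellipse, uniformly
runif_ellipse <- function(n, mu_t, nu_t, mu_r, nu_r) {
  ang <- stats::runif(n, 0, 2 * pi)
  rad <- sqrt(stats::runif(n))
  cbind(t = mu_t + nu_t * rad * cos(ang),
        r = mu_r + nu_r * rad * sin(ang))
}

rlaplace <- function(n, rate) {
  u <- stats::runif(n, -0.5, 0.5)
  -sign(u) * log(1 - 2 * abs(u)) / rate
}

#' Simulate peak-location clouds with ground-truth clusters
#'
#' Reproduces the clustering simulation design: cluster centroids drawn
#' uniformly in a dense area (`t` 0.5-0.7, `r` 4-60) and a wider sparse area
#' (`t` 0.5-1.2, `r` 4-450) inside the measurement rectangle
#' (`t` 0-1.45, `r` 0-600); per cluster a random member count and a random
#' spread model — Gaussian (`sigma_t = 0.002`,
#' `sigma_r = mu_r * 0.002 + 0.2`), Laplace product (rates `2500/1.45` in
#' IRM, `1/(mu_r * 0.002 + 0.2)` in retention) or uniform on an ellipse
#' (radii `0.006` and `mu_r * 0.02 + 1`).  Optional uniform noise peaks are
#' singleton blocks.  All points are clipped into the measurement rectangle.
#'
#' @param n_dense,n_sparse Centroid counts (defaults 30 and 20).
#' @param n_noise Number of uniform noise singletons (0 or e.g. 200).
#' @param size_lambda Cluster sizes are `1 + rpois(size_lambda)`.
#' @param shapes Candidate spread models, sampled per cluster.
#' @param seed Optional integer seed.
#' @return A list with `locations` (data frame `t`, `r`, `shape`) and
#'   `truth` (integer block labels; noise points get unique labels).
#' @export
simulate_cluster_locations <- function(n_dense = 30, n_sparse = 20,
                                       n_noise = 0, size_lambda = 10,
                                       shapes = c("normal", "exponential",
                                                  "uniform"),
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  meas_t <- c(0, 1.45); meas_r <- c(0, 600)
  dense_t <- c(0.5, 0.7); dense_r <- c(4, 60)
  sparse_t <- c(0.5, 1.2); sparse_r <- c(4, 450)
  cent_t <- c(stats::runif(n_dense, dense_t[1L], dense_t[2L]),
              stats::runif(n_sparse, sparse_t[1L], sparse_t[2L]))
  cent_r <- c(stats::runif(n_dense, dense_r[1L], dense_r[2L]),
              stats::runif(n_sparse, sparse_r[1L], sparse_r[2L]))
  nc <- n_dense + n_sparse
  pts <- vector("list", nc)
  labs <- vector("list", nc)
  shp <- character(nc)
  for (j in seq_len(nc)) {
    sz <- 1L + stats::rpois(1L, size_lambda)
    shp[j] <- sample(shapes, 1L)
    mu_t <- cent_t[j]; mu_r <- cent_r[j]
    xy <- switch(shp[j],
      normal = cbind(t = stats::rnorm(sz, mu_t, 0.002),
                     r = stats::rnorm(sz, mu_r, mu_r * 0.002 + 0.2)),
      exponential = cbind(t = mu_t + rlaplace(sz, 2500 / 1.45),
                          r = mu_r + rlaplace(sz, 1 / (mu_r * 0.002 + 0.2))),
      uniform = runif_ellipse(sz, mu_t, 0.006, mu_r, mu_r * 0.02 + 1))
    pts[[j]] <- xy
    labs[[j]] <- rep(j, sz)
  }
  xy <- do.call(rbind, pts)
  truth <- unlist(labs)
  shape <- rep(shp, vapply(labs, length, integer(1)))
  if (n_noise > 0) {
    xy <- rbind(xy, cbind(t = stats::runif(n_noise, meas_t[1L], meas_t[2L]),
                          r = stats::runif(n_noise, meas_r[1L], meas_r[2L])))
    truth <- c(truth, nc + seq_len(n_noise))
    shape <- c(shape, rep("noise", n_noise))
  }
  locations <- data.frame(
    t = pmin(pmax(xy[, "t"], meas_t[1L]), meas_t[2L]),
    r = pmin(pmax(xy[, "r"], meas_r[1L]), meas_r[2L]),
    shape = shape)
  list(locations = locations, truth = truth)
}
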