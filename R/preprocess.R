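#' Construct a single IM spectrum
#'
#' @param intensities Numeric vector of measured intensities (device units).
#' @param irm Equidistant, strictly increasing IRM axis (V s cm^-2), same
#'   length as `intensities`.
#' @param retention_time Retention time of the spectrum (s).
#' @return An object of class `ims_spectrum`.
#' @export
ims_spectrum <- function(intensities, irm, retention_time = 0) {
  if (length(intensities) != length(irm)) {
    stop("intensities and irm axis must have equal length")
  }
  if (length(irm) >= 2) {
    dt <- diff(irm)
    if (any(dt <= 0)) stop("irm axis must be strictly increasing")
    if (max(dt) - min(dt) > 1e-6 * mean(dt)) {
      stop("irm axis must be equidistant")
    }
  }
  structure(list(intensities = as.numeric(intensities),
                 irm = as.numeric(irm),
                 retention_time = retention_time),
            class = "ims_spectrum")
}

# smoothing window margin alpha (samples): half the IRM extent of one grid
# opening, expressed in samples of this spectrum's axis
smooth_margin <- function(spec, cfg) {
  n <- length(spec$intensities)
  round(0.5 * cfg$d_grid * cfg$c_t_given_d * n / max(spec$irm))
}

#' Moving-mean smoothing of a spectrum
#'
#' Smooths the intensities with a centred moving mean whose margin is half
#' the IRM extent of one grid opening time (in samples).  Window parts that
#' fall outside the spectrum are truncated (no padding).
#'
#' @param spec An [ims_spectrum()].
#' @param cfg An [ims_config()].
#' @return Numeric vector of smoothed intensities.
#' @export
smooth_spectrum <- function(spec, cfg) {
  stopifnot(inherits(spec, "ims_spectrum"), inherits(cfg, "ims_config"))
  s <- spec$intensities
  a <- smooth_margin(spec, cfg)
  if (a <= 0) return(s)
  n <- length(s)
  cs <- c(0, cumsum(s))
  lo <- pmax(seq_len(n) - a, 1L)
  hi <- pmin(seq_len(n) + a, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Initial noise/signal mixture parameters for a spectrum
#'
#' The background noise Gaussian is moment-estimated from the pooled first
#' and last 10% of samples.  The noise weight is the fraction of samples not
#' exceeding `mu_n + 3 sigma_n`; nearly all of the remaining weight goes to
#' the inverse-Gaussian signal component, whose parameters are
#' maximum-likelihood moment estimates on the complementary high-intensity
#' samples (baseline-subtracted).
#'
#' @param spec An [ims_spectrum()] with at least 20 samples.
#' @return A list of class `ims_noise_model` with elements `mu_n`, `sigma_n`,
#'   `mu_s`, `lam_s`, `w_n`, `w_s`, `w_b` (and later, after EM, `memberships`).
#' @export
noise_init <- function(spec) {
  stopifnot(inherits(spec, "ims_spectrum"))
  s <- spec$intensities
  n <- length(s)
  if (n < 20) stop("spectrum too short for noise initialisation")
  k <- max(1L, floor(0.1 * n))
  edge <- c(s[seq_len(k)], s[seq.int(n - k + 1L, n)])
  mu_n <- mean(edge)
  sigma_n <- max(stats::sd(edge), 1e-12)
  thr <- mu_n + 3 * sigma_n
  w_n <- sum(s <= thr) / n
  w_s <- (1 - w_n) * 0.999
  w_b <- (1 - w_n) * 0.001
  hi <- s[s > thr]
  if (length(hi) >= 2 && any(hi > mu_n)) {
    d <- hi - mu_n
    mu_s <- mean(d)
    inv <- sum(1 / d - 1 / mu_s)
    lam_s <- if (inv > 0) length(d) / inv else 1e6
  } else {
    # flat-signal fallback: no samples clearly above the noise band
    mu_s <- max(max(s) - mu_n, sigma_n, 1e-6)
    lam_s <- mu_s
  }
  structure(list(mu_n = mu_n, sigma_n = sigma_n,
                 mu_s = max(mu_s, 1e-12), lam_s = min(max(lam_s, 1e-12), 1e12),
                 w_n = w_n, w_s = w_s, w_b = w_b,
                 memberships = NULL, loglik = NULL, converged = NA,
                 iterations = 0L),
            class = "ims_noise_model")
}

#' EM denoising of a spectrum
#'
#' Fits a three-component mixture to the spectrum intensities: a Gaussian
#' noise component, a shifted inverse-Gaussian signal component (offset at the
#' noise mean) and a uniform background over the intensity range.  Expected
#' memberships are computed on a mean-smoothed copy of the spectrum while the
#' maximum-likelihood updates use the original intensities.  Iterates until
#' the relative change of every parameter falls below `cfg$thresh` or
#' `cfg$em_max_iter` is reached.
#'
#' @param spec An [ims_spectrum()].
#' @param cfg An [ims_config()].
#' @param init Optional starting `ims_noise_model`; defaults to
#'   [noise_init()].
#' @return An `ims_noise_model` with per-sample memberships (matrix with
#'   columns `noise`, `signal`, `background`), the log-likelihood trace and a
#'   convergence flag.
#' @export
denoise_spectrum <- function(spec, cfg, init = NULL) {
  stopifnot(inherits(spec, "ims_spectrum"), inherits(cfg, "ims_config"))
  s <- spec$intensities
  n <- length(s)
  nm <- if (is.null(init)) noise_init(spec) else init
  rng <- max(s) - min(s)
  if (rng <= 0) {
    # constant spectrum: all noise at that level
    W <- cbind(noise = rep(1, n), signal = 0, background = 0)
    nm$memberships <- W
    nm$w_n <- 1; nm$w_s <- 0; nm$w_b <- 0
    nm$sigma_n <- 1e-12
    nm$converged <- TRUE
    return(nm)
  }
  p_b <- 1 / rng
  x <- smooth_spectrum(spec, cfg)
  # convergence tracks the component distribution parameters; the mixture
  # weights are E-step by-products
  par_names <- c("mu_n", "sigma_n", "mu_s", "lam_s")
  loglik <- numeric(0)
  W <- NULL
  converged <- FALSE
  stalled <- FALSE
  best_kap <- Inf
  stall <- 0L
  iter <- 0L
  while (iter < cfg$em_max_iter) {
    iter <- iter + 1L
    old <- unlist(nm[par_names])
    # E-step on the smoothed intensities
    dn <- nm$w_n * stats::dnorm(x, nm$mu_n, nm$sigma_n)
    dsg <- nm$w_s * dsig(x, nm$mu_s, nm$lam_s, shift = nm$mu_n)
    db <- rep(nm$w_b * p_b, n)
    tot <- dn + dsg + db
    loglik <- c(loglik, sum(log(pmax(tot, 1e-300))))
    bad <- tot <= 0 | !is.finite(tot)
    if (any(bad)) {
      dn[bad] <- 1; dsg[bad] <- 0; db[bad] <- 0; tot[bad] <- 1
    }
    W <- cbind(noise = dn / tot, signal = dsg / tot, background = db / tot)
    w_new <- colMeans(W)
    nm$w_n <- w_new[[1L]]; nm$w_s <- w_new[[2L]]; nm$w_b <- w_new[[3L]]
    # M-step on the original intensities
    swn <- sum(W[, 1L])
    if (swn > 0) {
      nm$mu_n <- sum(W[, 1L] * s) / swn
      nm$sigma_n <- max(sqrt(sum(W[, 1L] * (s - nm$mu_n)^2) / swn), 1e-12)
    }
    sel <- s > nm$mu_n
    sws <- sum(W[sel, 2L])
    if (sws > 0) {
      d <- s[sel] - nm$mu_n
      nm$mu_s <- max(sum(W[sel, 2L] * d) / sws, 1e-12)
      den <- sum(W[sel, 2L] * (1 / d - 1 / nm$mu_s))
      nm$lam_s <- if (den > 0) min(sws / den, 1e12) else 1e12
    }
    new <- unlist(nm[par_names])
    kap <- abs(new - old) / pmax(abs(new), abs(old))
    kap[new == 0 & old == 0] <- 0
    kmax <- max(kap)
    if (kmax < cfg$thresh) {
      converged <- TRUE
      break
    }
    # the E-step works on smoothed data while the M-step uses the raw
    # intensities, so the update can settle into a small limit cycle rather
    # than a fixed point; stop once the parameter change is small and has
    # stopped shrinking
    if (kmax < best_kap * 0.999) {
      best_kap <- kmax
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= 8L && kmax < 0.05) {
        stalled <- TRUE
        break
      }
    }
  }
  if (!converged && !stalled) {
    warning("denoising EM did not converge within the iteration cap")
  }
  nm$memberships <- W
  nm$loglik <- loglik
  nm$converged <- converged
  nm$stalled <- stalled
  nm$iterations <- iter
  nm
}

#' Baseline-correct and denoise a spectrum
#'
#' Subtracts the estimated noise mean and scales each sample by its
#' probability of not being noise:
#' `s_plus = max((1 - W_noise) * (s - mu_n), 0)`.  Samples whose most
#' probable component is noise are set to exactly zero — the soft shrinkage
#' applies to samples that plausibly carry signal — and values below
#' `cfg$zero_floor * sigma_n` are numerically negligible and truncated as
#' well, which keeps corrected noise-only spectra sparse.
#'
#' @param spec An [ims_spectrum()].
#' @param nm An `ims_noise_model` with memberships (from
#'   [denoise_spectrum()]).
#' @param cfg An [ims_config()] (only `zero_floor` is used).
#' @return An [ims_spectrum()] with corrected intensities, axes unchanged.
#' @export
correct_spectrum <- function(spec, nm, cfg = ims_config()) {
  stopifnot(inherits(spec, "ims_spectrum"), inherits(nm, "ims_noise_model"))
  if (is.null(nm$memberships)) stop("noise model carries no memberships; run denoise_spectrum() first")
  s <- spec$intensities
  sp <- pmax((1 - nm$memberships[, "noise"]) * (s - nm$mu_n), 0)
  sp[max.col(nm$memberships, ties.method = "first") == 1L] <- 0
  sp[sp < cfg$zero_floor * nm$sigma_n] <- 0
  ims_spectrum(sp, spec$irm, spec$retention_time)
}

# intensity-weighted standard deviation of the axis: spread of a spectrum
# read as an (unnormalised) density over IRM; used to calibrate the width of
# the reactant-ion-peak-only spectrum
spectrum_axis_sd <- function(spec) {
  w <- pmax(spec$intensities, 0)
  if (sum(w) <= 0) return(NA_real_)
  m <- sum(w * spec$irm) / sum(w)
  sqrt(sum(w * (spec$irm - m)^2) / sum(w))
}
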