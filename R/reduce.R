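#' Asymmetric residual loss for under-fitting curve estimation
#'
#' Quadratic for residuals below the threshold `gamma` (including all
#' negative residuals, which are penalised heavily) and linear above it, so
#' that a fitted curve may stay below the data but not above:
#' `r^2/2` if `r < gamma`, else `gamma * r - gamma^2/2`.  Continuous with
#' continuous derivative at `r = gamma`.
#'
#' @param r Numeric vector of residuals (data minus model).
#' @param gamma Positive threshold.
#' @return Numeric vector of losses.
#' @export
asymmetric_loss <- function(r, gamma) {
  if (gamma <= 0) stop("gamma must be > 0")
  q <- pmin(r, gamma)            # branch-free: q = r on the quadratic side
  q * r - q^2 / 2
}

asymmetric_loss_deriv <- function(r, gamma) {
  pmin(r, gamma)
}

#' Tailing-function model
#'
#' A scaled shifted inverse-Gaussian `f(t) = v * g(t; mu, lambda, o)`
#' describing the right-skewed baseline contributed by the reactant ion peak
#' in each spectrum.
#'
#' @param v Non-negative scale factor.
#' @param params A [sig_params()] object on the IRM axis.
#' @return An object of class `ims_tailing`.
#' @export
tailing_model <- function(v, params) {
  if (v < 0) stop("tailing scale must be >= 0")
  stopifnot(inherits(params, "sig_params"))
  structure(list(v = v, params = params), class = "ims_tailing")
}

tailing_values <- function(tm, irm) {
  if (tm$v <= 0) return(numeric(length(irm)))
  tm$v * dsig(irm, tm$params)
}

# total asymmetric loss of a tailing candidate theta = (v, mu, lambda, o)
tail_loss <- function(theta, irm, s, gamma) {
  g <- dsig(irm, theta[2L], theta[3L], theta[4L])
  sum(asymmetric_loss(s - theta[1L] * g, gamma))
}

# analytic gradient of tail_loss w.r.t. theta
tail_loss_grad <- function(theta, irm, s, gamma) {
  v <- theta[1L]; mu <- theta[2L]; lam <- theta[3L]; o <- theta[4L]
  g <- dsig(irm, mu, lam, o)
  e1 <- asymmetric_loss_deriv(s - v * g, gamma)
  gl <- dsig_grad_log(irm, mu, lam, o)
  c(v = -sum(e1 * g),
    mu = -sum(e1 * v * g * gl$mu),
    lambda = -sum(e1 * v * g * gl$lambda),
    shift = -sum(e1 * v * g * gl$shift))
}

# quasi-Newton descent on a subset of the tailing parameters; v, mu, lambda
# are optimised on the log scale so the search space is unconstrained.  The
# loss is continuously differentiable (the asymmetric loss is C1), so BFGS
# with the analytic gradient converges where plain steepest descent
# zigzags in this poorly conditioned valley.
tail_descent <- function(theta, free, irm, s, gamma, max_iter = 500L) {
  logged <- c(TRUE, TRUE, TRUE, FALSE)
  psi <- theta
  psi[logged] <- log(pmax(theta[logged], 1e-300))
  to_theta <- function(p) {
    th <- p
    th[logged] <- exp(p[logged])
    th
  }
  idx <- which(free)
  fn <- function(pf) {
    p <- psi
    p[idx] <- pf
    tail_loss(to_theta(p), irm, s, gamma)
  }
  gr <- function(pf) {
    p <- psi
    p[idx] <- pf
    th <- to_theta(p)
    g <- tail_loss_grad(th, irm, s, gamma)
    g[logged] <- g[logged] * th[logged]     # chain rule for log params
    g[idx]
  }
  res <- tryCatch(
    stats::optim(psi[idx], fn, gr, method = "BFGS",
                 control = list(maxit = max_iter, reltol = 1e-12)),
    error = function(e) NULL)
  if (is.null(res) || !is.finite(res$value)) {
    return(list(theta = to_theta(psi),
                loss = tail_loss(to_theta(psi), irm, s, gamma)))
  }
  psi[idx] <- res$par
  list(theta = to_theta(psi), loss = res$value)
}

#' Initial tailing-function parameters for a spectrum
#'
#' The initial scale is half the total intensity; the mode is placed at the
#' spectrum maximum (the reactant ion peak) and the standard deviation at the
#' supplied spread of a RIP-only spectrum.  The mean descriptor is stepped
#' through its admissible interval `[m, m + 0.7 sigma]` and converted to
#' parameters; the step whose offset clears the last low-signal IRM left of
#' the mode is kept.
#'
#' @param spec A corrected [ims_spectrum()].
#' @param nm An `ims_noise_model` (its `sigma_n` defines "low signal").
#' @param rip_sigma Standard deviation of a RIP-only spectrum, in IRM units
#'   (e.g. from a calibration prefix).
#' @param cfg An [ims_config()].
#' @return An [tailing_model()]; zero scale if the spectrum is empty.
#' @export
tailing_init <- function(spec, nm, rip_sigma, cfg) {
  stopifnot(inherits(spec, "ims_spectrum"))
  s <- spec$intensities
  irm <- spec$irm
  if (max(s) <= 0) {
    return(tailing_model(0, sig_params(1, 1, 0)))
  }
  if (!is.finite(rip_sigma) || rip_sigma <= 0) {
    rip_sigma <- max(spectrum_axis_sd(spec), diff(range(irm)) / 100)
  }
  m <- irm[which.max(s)]
  # half the total signal mass: the scale of a density model covering half
  # the spectrum's integral
  v <- 0.5 * sum(s) * mean(diff(irm))
  low <- which(irm < m & s < nm$sigma_n)
  if (length(low)) {
    o_prime <- irm[max(low)]
  } else {
    o_prime <- irm[1L]
    warning("no sample below the noise level left of the RIP mode; using the axis start")
  }
  # on the heavy-skew branch the offset decreases from the mode as the mean
  # steps up; keep the least skewed candidate whose support still starts at
  # or right of o_prime
  steps <- m + seq(0.02, 0.7, length.out = 35L) * rip_sigma
  chosen <- NULL
  fallback <- NULL
  for (mp in steps) {
    cand <- tryCatch(
      sig_from_descriptors(sig_descriptors(mp, rip_sigma, m), skew = "max"),
      error = function(e) NULL)
    if (is.null(cand)) next
    if (is.null(fallback)) fallback <- cand
    if (cand$shift >= o_prime) chosen <- cand
  }
  if (is.null(chosen)) chosen <- fallback
  if (is.null(chosen)) {
    # descriptors not invertible anywhere in the interval: fall back to a
    # mildly skewed shape anchored at the mode
    chosen <- sig_params(mu = 2 * rip_sigma, lambda = 8 * rip_sigma,
                         shift = m - 1.8 * rip_sigma)
  }
  tailing_model(v, chosen)
}

#' Fit the tailing function by non-linear loss minimisation
#'
#' Runs the three-stage schedule: (a) with threshold `gamma = sigma_n^2`
#' optimise the scale only; (b) same threshold, optimise all four parameters;
#' (c) with `gamma = sigma_n^2 / 100` re-optimise the scale.  Each stage uses
#' gradient descent with a backtracking line search on the total asymmetric
#' loss; a stage that produces a non-finite loss is reverted.
#'
#' @param spec A corrected [ims_spectrum()].
#' @param nm An `ims_noise_model` supplying `sigma_n`.
#' @param init An initial [tailing_model()] (see [tailing_init()]).
#' @param cfg An [ims_config()].
#' @return The fitted [tailing_model()].
#' @export
tailing_fit <- function(spec, nm, init, cfg) {
  stopifnot(inherits(init, "ims_tailing"))
  if (init$v <= 0) return(init)
  s <- spec$intensities
  irm <- spec$irm
  # the loss is a sum over samples: a thinned grid (~1250 points) gives the
  # same fit at a fraction of the cost on high-resolution spectra
  stride <- max(1L, length(s) %/% 1250L)
  if (stride > 1L) {
    keep <- seq(1L, length(s), by = stride)
    s <- s[keep]
    irm <- irm[keep]
  }
  gamma <- max(nm$sigma_n^2, 1e-12)
  theta <- c(init$v, init$params$mu, init$params$lambda, init$params$shift)
  stages <- list(
    list(free = c(TRUE, FALSE, FALSE, FALSE), gamma = gamma,
         iter = cfg$nllm_max_iter),
    list(free = c(TRUE, TRUE, TRUE, TRUE), gamma = gamma,
         iter = cfg$nllm_max_iter),
    list(free = c(TRUE, FALSE, FALSE, FALSE), gamma = gamma / 100,
         iter = cfg$nllm_max_iter)
  )
  for (st in stages) {
    res <- tail_descent(theta, st$free, irm, s, st$gamma, max_iter = st$iter)
    if (is.finite(res$loss) && res$theta[2L] > 0 && res$theta[3L] > 0) {
      theta <- res$theta
    } else {
      warning("tailing stage produced non-finite loss; reverting")
    }
  }
  tailing_model(max(theta[1L], 0),
                sig_params(theta[2L], theta[3L], theta[4L]))
}

# rolling least-squares quadratic fits: returns a (n-w+1) x 3 matrix of
# coefficients (theta0, theta1, theta2) in local window coordinates centred
# at the window midpoint
rolling_quadratic <- function(s, w) {
  n <- length(s)
  if (w > n) stop("window wider than spectrum")
  xloc <- seq_len(w) - (w + 1) / 2
  X <- cbind(1, xloc, xloc^2)
  P <- solve(crossprod(X), t(X))            # 3 x w
  npos <- n - w + 1L
  idx <- outer(seq_len(npos), seq_len(w) - 1L, `+`)
  Y <- matrix(s[idx], nrow = npos)
  Y %*% t(P)
}

#' Scan a spectrum for peaks and reduce it to 1-D peak models
#'
#' Slides a window of one grid-opening width across the (tailing-subtracted,
#' corrected) spectrum and fits a quadratic polynomial in drift time inside
#' each window.  A window is a peak window when the parabola vertex lies in
#' the (shrunk) window, opens downward, and its height reaches the noise
#' level `sigma_n`.  Each detected peak gets IRM-axis descriptors predicted
#' from its drift-time mode, a scale factor matching the fitted apex height,
#' and is subtracted from the working copy before scanning continues; the
#' window then advances half its length (or by the smoothing margin,
#' depending on `cfg$scan_advance`), otherwise by one sample.
#'
#' @param spec An [ims_spectrum()], already denoised and tailing-subtracted.
#' @param sigma_n Noise standard deviation (detection threshold).
#' @param cfg An [ims_config()].
#' @return A data frame with one row per peak: `r`, `mode`, `mean`, `sigma`,
#'   `mu`, `lambda`, `shift`, `v`, `height`, ordered left to right.
#' @export
scan_peaks <- function(spec, sigma_n, cfg) {
  stopifnot(inherits(spec, "ims_spectrum"), inherits(cfg, "ims_config"))
  s <- spec$intensities
  irm <- spec$irm
  n <- length(s)
  w <- max(5L, round(cfg$d_grid / cfg$d_last * n))
  if (w > n) stop("scan window wider than spectrum")
  drift <- irm / cfg$c_t_given_d            # ms
  dd <- drift[2L] - drift[1L]
  half_span <- cfg$scan_shrink * (w - 1) / 2
  advance <- if (cfg$scan_advance == "half") max(1L, floor(w / 2)) else
    max(1L, smooth_margin(spec, cfg))
  work <- s
  th <- rolling_quadratic(work, w)
  npos <- nrow(th)
  out <- matrix(NA_real_, 32L, 9L)
  np <- 0L
  last_mode <- -Inf
  i <- 1L
  while (i <= npos) {
    t2 <- th[i, 3L]
    if (is.finite(t2) && t2 < 0) {
      xv <- -th[i, 2L] / (2 * t2)
      hv <- th[i, 1L] + th[i, 2L] * xv + t2 * xv^2
      if (abs(xv) <= half_span && hv >= sigma_n) {
        d_star <- drift[i] + (xv + (w - 1) / 2) * dd
        fit <- tryCatch({
          desc <- drift_to_descriptors(d_star, cfg)
          par <- sig_from_descriptors(desc)
          list(desc = desc, par = par)
        }, error = function(e) NULL)
        if (!is.null(fit) && fit$desc$mode > last_mode) {
          gmax <- dsig(fit$desc$mode, fit$par)
          v <- hv / gmax
          np <- np + 1L
          if (np > nrow(out)) out <- rbind(out, matrix(NA_real_, nrow(out), 9L))
          out[np, ] <- c(spec$retention_time, fit$desc$mode, fit$desc$mean,
                         fit$desc$sigma, fit$par$mu, fit$par$lambda,
                         fit$par$shift, v, hv)
          last_mode <- fit$desc$mode
          work <- pmax(work - v * dsig(irm, fit$par), 0)
          # refresh the rolling fits where the subtraction changed the data;
          # beyond ~10 sigma right of the mode the change is negligible
          lo <- max(1L, i - w)
          reach <- ceiling(10 * fit$desc$sigma / (irm[2L] - irm[1L]))
          hi <- min(npos, i + reach + w)
          th[lo:hi, ] <- rolling_quadratic(work[lo:min(n, hi + w - 1L)], w)
          i <- i + advance
          next
        }
      }
    }
    i <- i + 1L
  }
  out <- out[seq_len(np), , drop = FALSE]
  colnames(out) <- c("r", "mode", "mean", "sigma", "mu", "lambda", "shift",
                     "v", "height")
  as.data.frame(out)
}

#' Reduce one corrected spectrum to its peak list
#'
#' Composes the per-spectrum stages: estimate and subtract the tailing
#' function, then scan the remainder for peaks.  The reactant ion peak, if
#' detected, is part of the returned list (it can be dropped via
#' `cfg$drop_rip`).
#'
#' @param spec A corrected [ims_spectrum()] (see [correct_spectrum()]).
#' @param nm The spectrum's `ims_noise_model`.
#' @param cfg An [ims_config()].
#' @param rip_sigma Spread of a RIP-only spectrum in IRM units; if `NA` it is
#'   taken from the spectrum itself.
#' @param tailing_start Optional [tailing_model()] used as the starting
#'   point (e.g. the previous spectrum's fit in online mode); by default the
#'   initialisation recipe runs from scratch.
#' @return A list with `peaks` (data frame as in [scan_peaks()]) and
#'   `tailing` (the fitted [tailing_model()]).
#' @export
reduce_spectrum <- function(spec, nm, cfg, rip_sigma = NA_real_,
                            tailing_start = NULL) {
  stopifnot(inherits(spec, "ims_spectrum"))
  if (max(spec$intensities) <= 0) {
    return(list(peaks = scan_peaks(spec, Inf, cfg),
                tailing = tailing_model(0, sig_params(1, 1, 0))))
  }
  tm0 <- if (!is.null(tailing_start) && tailing_start$v > 0) tailing_start
    else tailing_init(spec, nm, rip_sigma, cfg)
  tm <- tailing_fit(spec, nm, tm0, cfg)
  resid <- pmax(spec$intensities - tailing_values(tm, spec$irm), 0)
  sub <- ims_spectrum(resid, spec$irm, spec$retention_time)
  peaks <- scan_peaks(sub, nm$sigma_n, cfg)
  if (cfg$drop_rip && nrow(peaks)) {
    grid_irm <- cfg$d_grid * cfg$c_t_given_d
    peaks <- peaks[abs(peaks$mode - cfg$rip_irm) > grid_irm, , drop = FALSE]
  }
  list(peaks = peaks, tailing = tm)
}
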