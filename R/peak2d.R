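#' Retention profile of a peak chain
#'
#' Each chain member contributes its retention time and its model height
#' `h_i = v_i * g(m_i; mu_i, lambda_i, o_i)` at the IRM mode.
#'
#' @param chain A data frame of 1-D peak rows (as produced by
#'   [scan_peaks()]).
#' @return A data frame with columns `r` and `h`.
#' @export
chain_profile <- function(chain) {
  if (!nrow(chain)) stop("chain is empty")
  h <- vapply(seq_len(nrow(chain)), function(i) {
    chain$v[i] * dsig(chain$mode[i], chain$mu[i], chain$lambda[i],
                      chain$shift[i])
  }, numeric(1))
  data.frame(r = chain$r, h = h)
}

# quadratic least-squares fit of h over r within one window, in centred
# retention coordinates; returns theta = (t0, t1, t2) in absolute coordinates
fit_quadratic <- function(r, h) {
  rc <- mean(r)
  X <- cbind(1, r - rc, (r - rc)^2)
  th <- tryCatch(solve(crossprod(X), crossprod(X, h)),
                 error = function(e) NULL)
  if (is.null(th)) return(NULL)
  # expand (a + b x + c x^2) around x = r - rc back to absolute r
  a <- th[1L]; b <- th[2L]; cc <- th[3L]
  c(a - b * rc + cc * rc^2, b - 2 * cc * rc, cc)
}

#' Initial retention-axis peak components from a chain profile
#'
#' Slides windows of width `xi(r)` (in profile points) over the retention
#' profile and fits quadratic polynomials.  A window that passes the peak
#' window conditions (vertex inside the shrunk window, opening downward,
#' vertex height at least `sigma_n`) yields initial retention descriptors:
#' apex height `v_r = theta0 - theta1^2/(4 theta2)`, spread
#' `sigma_r = sqrt(v_r / (2 |theta2|))`, mode `m_r = -theta1/(2 theta2)` and
#' mean `m_r + xi(m_r)/(4 phi)`.
#'
#' @param profile Data frame from [chain_profile()] (at least 3 points).
#' @param sigma_n Noise standard deviation.
#' @param cfg An [ims_config()].
#' @return A list of components, each with `v_r`, `desc`
#'   ([sig_descriptors()]), `params` ([sig_params()]) and the window
#'   polynomial `theta` (absolute retention coordinates).
#' @export
retention_windows <- function(profile, sigma_n, cfg) {
  n <- nrow(profile)
  if (n < 3L) return(list())
  r <- profile$r
  h <- profile$h
  dr <- stats::median(diff(r))
  if (!is.finite(dr) || dr <= 0) return(list())
  comps <- list()
  i <- 1L
  while (i <= n - 2L) {
    w <- max(3L, round(ret_width(r[i], cfg) / dr))
    hi <- i + w - 1L
    if (hi > n) hi <- n
    if (hi - i + 1L < 3L) break
    idx <- i:hi
    th <- fit_quadratic(r[idx], h[idx])
    accepted <- FALSE
    if (!is.null(th) && is.finite(th[3L]) && th[3L] < 0) {
      m_r <- -th[2L] / (2 * th[3L])
      v_r <- th[1L] - th[2L]^2 / (4 * th[3L])
      centre <- (r[i] + r[hi]) / 2
      span <- cfg$scan_shrink * (r[hi] - r[i]) / 2
      if (abs(m_r - centre) <= span && v_r >= sigma_n && m_r > 0) {
        sigma_r <- sqrt(v_r / (2 * abs(th[3L])))
        mean_r <- m_r + ret_width(m_r, cfg) / (4 * phi_fwhm)
        comp <- tryCatch({
          desc <- sig_descriptors(mean_r, sigma_r, m_r)
          list(v_r = v_r, desc = desc,
               params = sig_from_descriptors(desc), theta = th)
        }, error = function(e) NULL)
        if (!is.null(comp)) {
          comps[[length(comps) + 1L]] <- comp
          accepted <- TRUE
        }
      }
    }
    i <- i + if (accepted) max(1L, floor(w / 2)) else 1L
  }
  comps
}

#' EM deconvolution of a chain profile into retention components
#'
#' Apportions the profile mass among the window-fitted retention components:
#' the profile is treated as a mass-weighted sample (point `r_i` carries
#' mass `h_i`) from a mixture of the k shifted inverse-Gaussian component
#' densities plus a small uniform background over the profile's retention
#' range.  The component shapes stay at their window estimates — the EM's
#' task here is the deconvolution itself, i.e. the mixture weights and the
#' membership matrix that splits overlapping peaks; the background absorbs
#' baseline residue that rides along in a chain (the same role the uniform
#' component plays in the spectrum mixture model).  Weights start from the
#' normalised window apex heights and iterate until their relative change
#' falls below `cfg$thresh`; components whose weight vanishes are dropped.
#'
#' @param profile Data frame from [chain_profile()].
#' @param inits Component list from [retention_windows()].
#' @param cfg An [ims_config()].
#' @return A list with `components` (as in `inits`, plus weight `w`
#'   renormalised over the peak components) and `memberships` (an `n x k`
#'   matrix of peak-component memberships).
#' @export
deconvolute_profile <- function(profile, inits, cfg) {
  k <- length(inits)
  n <- nrow(profile)
  if (k == 0L) return(list(components = list(), memberships = NULL))
  r <- profile$r
  h <- pmax(profile$h, 0)
  rng <- diff(range(r))
  p_bg <- if (rng > 0) 1 / rng else 0
  comps <- inits
  dens <- vapply(comps, function(cp) dsig(r, cp$params), numeric(n))
  dens <- cbind(matrix(dens, nrow = n), p_bg)
  # the background weight is held fixed (contamination model): it claims
  # profile points only where every peak density is negligible
  w_bg <- 0.01
  wts <- vapply(comps, `[[`, numeric(1), "v_r")
  wts <- wts / sum(wts)
  e_step <- function(w, d) {
    num <- sweep(d, 2L, c(w * (1 - w_bg), w_bg), `*`)
    tot <- rowSums(num)
    M <- num / ifelse(tot > 0, tot, 1)
    M[tot <= 0, ] <- c(rep(0, ncol(d) - 1L), 1)
    M
  }
  for (iter in seq_len(200L)) {
    M <- e_step(wts, dens)
    mass <- colSums(h * M)[seq_along(comps)]
    new <- if (sum(mass) > 0) mass / sum(mass) else
      rep(1 / length(comps), length(comps))
    drop <- new < 1e-8
    if (any(drop)) {
      sel <- which(!drop)
      comps <- comps[sel]
      if (!length(comps)) return(list(components = list(), memberships = NULL))
      dens <- dens[, c(sel, ncol(dens)), drop = FALSE]
      wts <- new[sel] / sum(new[sel])
      next
    }
    kap <- abs(new - wts) / pmax(abs(new), abs(wts))
    kap[new == 0 & wts == 0] <- 0
    wts <- new
    if (all(kap < cfg$thresh)) break
  }
  for (j in seq_along(comps)) comps[[j]]$w <- wts[j]
  M <- e_step(wts, dens)
  list(components = comps,
       memberships = M[, seq_along(comps), drop = FALSE])
}

#' Membership-weighted IRM descriptors per retention component
#'
#' Averages the chain members' IRM-axis descriptors (mean, sigma, mode) with
#' the membership weights of each retention component and converts the
#' averaged descriptors back into shifted inverse-Gaussian parameters.
#' Components whose averaged descriptors are not invertible are dropped.
#'
#' @param chain A chain data frame.
#' @param M Membership matrix from [deconvolute_profile()] (rows = chain
#'   members, columns = components).
#' @return A list per surviving component with `desc`, `params` and the
#'   originating column index `j`.
#' @export
chain_irm_descriptors <- function(chain, M) {
  if (nrow(chain) != nrow(M)) stop("membership matrix inconsistent with chain length")
  out <- list()
  for (j in seq_len(ncol(M))) {
    mbar <- sum(M[, j])
    if (mbar <= 0) next
    mean_t <- sum(M[, j] * chain$mean) / mbar
    sigma_t <- sum(M[, j] * chain$sigma) / mbar
    mode_t <- sum(M[, j] * chain$mode) / mbar
    comp <- tryCatch({
      desc <- sig_descriptors(mean_t, sigma_t, mode_t)
      list(desc = desc, params = sig_from_descriptors(desc), j = j)
    }, error = function(e) NULL)
    if (is.null(comp)) {
      warning("IRM descriptor conversion failed; component discarded")
      next
    }
    out[[length(out) + 1L]] <- comp
  }
  out
}

#' Final 2-D peak models from a deconvoluted chain
#'
#' Combines the retention components with their IRM descriptors into
#' seven-parameter 2-D peak models and applies the three acceptance filters:
#' (1) the retention width is of the expected size
#' (`xi(m_r)/2 <= phi * sigma_r < 2 xi(m_r)` by default; see
#' `width_check_mode`); (2) the model height at the 2-D mode reaches
#' `noise_margin * sigma_n`; (3) the retention model correlates with its
#' quadratic approximation (Pearson rho over a 50-point grid on
#' `[m_r - xi/phi, m_r + xi/phi]`) at least `rho_min`.
#'
#' @param ret_components Components from [deconvolute_profile()].
#' @param irm_components Matching list from [chain_irm_descriptors()].
#' @param chain The chain data frame.
#' @param sigma_n Noise standard deviation.
#' @param cfg An [ims_config()].
#' @param M Optional membership matrix (used when `cfg$weight_volume_sum` is
#'   `TRUE` to restrict the spectrum-scale sum to each component).
#' @return A data frame of accepted 2-D peaks with columns `r_mode`,
#'   `t_mode`, `r_mean`, `t_mean`, `r_sigma`, `t_sigma`, `volume` and the raw
#'   parameters `mu_r`, `lambda_r`, `o_r`, `mu_t`, `lambda_t`, `o_t`.
#' @export
finalize_peaks <- function(ret_components, irm_components, chain, sigma_n, cfg,
                           M = NULL) {
  rows <- list()
  vsum_all <- sum(chain$v)
  for (comp in irm_components) {
    j <- comp$j
    rc <- ret_components[[j]]
    m_r <- rc$desc$mode
    if (!is.finite(m_r) || m_r <= 0) next   # drifted outside the measurement
    sigma_r <- rc$desc$sigma
    xi_r <- ret_width(m_r, cfg)
    width_stat <- if (cfg$width_check_mode == "phi_sigma") {
      phi_fwhm * sigma_r
    } else {
      sigma_r / phi_fwhm
    }
    vsum <- if (cfg$weight_volume_sum && !is.null(M)) {
      sum(chain$v * M[, j])
    } else {
      vsum_all
    }
    v_star <- rc$w * vsum
    ok1 <- width_stat >= xi_r / 2 && width_stat < 2 * xi_r
    height <- v_star * dsig(comp$desc$mode, comp$params) *
      dsig(m_r, rc$params)
    ok2 <- is.finite(height) && height >= cfg$noise_margin * sigma_n
    grid <- seq(m_r - xi_r / phi_fwhm, m_r + xi_r / phi_fwhm,
                length.out = 50L)
    G <- dsig(grid, rc$params)
    B <- rc$theta[1L] + rc$theta[2L] * grid + rc$theta[3L] * grid^2
    ok3 <- stats::sd(G) > 0 && stats::sd(B) > 0 &&
      stats::cor(G, B) >= cfg$rho_min
    if (ok1 && ok2 && ok3) {
      rows[[length(rows) + 1L]] <- data.frame(
        r_mode = m_r, t_mode = comp$desc$mode,
        r_mean = rc$desc$mean, t_mean = comp$desc$mean,
        r_sigma = sigma_r, t_sigma = comp$desc$sigma,
        volume = v_star,
        mu_r = rc$params$mu, lambda_r = rc$params$lambda,
        o_r = rc$params$shift,
        mu_t = comp$params$mu, lambda_t = comp$params$lambda,
        o_t = comp$params$shift)
    }
  }
  if (!length(rows)) {
    return(data.frame(r_mode = numeric(0), t_mode = numeric(0),
                      r_mean = numeric(0), t_mean = numeric(0),
                      r_sigma = numeric(0), t_sigma = numeric(0),
                      volume = numeric(0), mu_r = numeric(0),
                      lambda_r = numeric(0), o_r = numeric(0),
                      mu_t = numeric(0), lambda_t = numeric(0),
                      o_t = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Convert a closed peak chain into accepted 2-D peak models
#'
#' Composition of [chain_profile()], [retention_windows()],
#' [deconvolute_profile()], [chain_irm_descriptors()] and
#' [finalize_peaks()].  Chains shorter than `cfg$min_chain_length` (or than
#' the three points needed for a window fit) yield no peaks.
#'
#' @param chain A chain data frame.
#' @param sigma_n Noise standard deviation.
#' @param cfg An [ims_config()].
#' @return A data frame of accepted 2-D peaks (possibly empty).
#' @export
chain_to_peaks <- function(chain, sigma_n, cfg) {
  if (nrow(chain) < max(cfg$min_chain_length, 3L)) {
    return(finalize_peaks(list(), list(), chain[0, ], sigma_n, cfg))
  }
  profile <- chain_profile(chain)
  inits <- retention_windows(profile, sigma_n, cfg)
  if (!length(inits)) {
    return(finalize_peaks(list(), list(), chain[0, ], sigma_n, cfg))
  }
  dec <- deconvolute_profile(profile, inits, cfg)
  if (!length(dec$components)) {
    return(finalize_peaks(list(), list(), chain[0, ], sigma_n, cfg))
  }
  irm <- chain_irm_descriptors(chain, dec$memberships)
  finalize_peaks(dec$components, irm, chain, sigma_n, cfg,
                 M = dec$memberships)
}
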