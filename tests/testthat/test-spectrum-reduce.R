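test_that("asymmetric loss is continuous with continuous derivative", {
  g <- 1.5
  expect_equal(asymmetric_loss(g, g), g^2 / 2)                 # both branches
  expect_equal(asymmetric_loss(g - 1e-12, g), g^2 / 2, tolerance = 1e-9)
  expect_equal(asymmetric_loss(-2, 1), 2)                      # quadratic side
  expect_equal(asymmetric_loss(4, 1), 4 - 0.5)                 # linear side
  # derivative continuity at the threshold by finite differences
  eps <- 1e-7
  d_lo <- (asymmetric_loss(g, g) - asymmetric_loss(g - eps, g)) / eps
  d_hi <- (asymmetric_loss(g + eps, g) - asymmetric_loss(g, g)) / eps
  expect_equal(d_lo, g, tolerance = 1e-5)
  expect_equal(d_hi, g, tolerance = 1e-5)
  expect_error(asymmetric_loss(1, 0), "gamma")
})

test_that("tailing fit recovers a pure scaled shifted inverse Gaussian", {
  cfg <- test_config()
  n <- 2500
  irm <- seq_len(n) / n * cfg$t_last
  par <- sig_params(mu = 0.2, lambda = 0.05, shift = 0.46)
  v_true <- 12
  sp <- ims_spectrum(v_true * dsig(irm, par), irm)
  nm <- structure(list(mu_n = 0, sigma_n = 0.05), class = "ims_noise_model")
  init <- tailing_init(sp, nm, rip_sigma = imspeaks:::spectrum_axis_sd(sp), cfg)
  fit <- tailing_fit(sp, nm, init, cfg)
  expect_equal(fit$v, v_true, tolerance = 0.01 * v_true)
  # initial model already beats the flat-zero model
  gamma <- nm$sigma_n^2
  loss0 <- sum(asymmetric_loss(sp$intensities, gamma))
  loss_init <- imspeaks:::tail_loss(c(init$v, init$params$mu,
                                      init$params$lambda, init$params$shift),
                                    irm, sp$intensities, gamma)
  expect_lt(loss_init, loss0)
})

test_that("fitted tailing under-fits data with superimposed peaks", {
  cfg <- test_config()
  n <- 2500
  irm <- seq_len(n) / n * cfg$t_last
  par <- sig_params(mu = 0.2, lambda = 0.05, shift = 0.46)
  pk <- drift_to_descriptors(0.9 / cfg$c_t_given_d, cfg)
  pkp <- sig_from_descriptors(pk)
  set.seed(21)
  s <- 12 * dsig(irm, par) + 0.08 * dsig(irm, pkp) +
    pmax(rnorm(n, 0, 0.05), -0.2)
  sp <- ims_spectrum(pmax(s, 0), irm)
  nm <- structure(list(mu_n = 0, sigma_n = 0.05), class = "ims_noise_model")
  init <- tailing_init(sp, nm, rip_sigma = imspeaks:::spectrum_axis_sd(sp), cfg)
  fit <- tailing_fit(sp, nm, init, cfg)
  resid <- sp$intensities - fit$v * dsig(irm, fit$params)
  expect_lt(mean(resid < -3 * nm$sigma_n), 0.01)
})

test_that("tailing initialisation anchors at the spectrum maximum", {
  cfg <- test_config()
  n <- 1000
  irm <- seq_len(n) / n * cfg$t_last
  par <- sig_params(mu = 0.2, lambda = 0.05, shift = 0.46)
  sp <- ims_spectrum(10 * dsig(irm, par), irm)
  nm <- structure(list(mu_n = 0, sigma_n = 0.01), class = "ims_noise_model")
  init <- tailing_init(sp, nm, 0.06, cfg)
  m_init <- sig_to_descriptors(init$params)$mode
  expect_equal(m_init, irm[which.max(sp$intensities)], tolerance = 1e-6)
  expect_equal(init$v, 0.5 * sum(sp$intensities) * mean(diff(irm)))
  # offset clears the last low-signal sample left of the mode
  low <- which(irm < m_init & sp$intensities < nm$sigma_n)
  expect_gte(init$params$shift, irm[max(low)] - 0.06 * 0.6)
})

test_that("peak scanning finds isolated peaks in order and rejects noise", {
  cfg <- test_config()
  n <- 2500
  irm <- seq_len(n) / n * cfg$t_last
  flat <- ims_spectrum(rep(0, n), irm)
  expect_equal(nrow(scan_peaks(flat, 1, cfg)), 0)
  # a single peak ten sigma above the noise threshold
  set.seed(31)
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    t0 <- runif(1, 0.6, 1.3)
    desc <- drift_to_descriptors(t0 / cfg$c_t_given_d, cfg)
    par <- sig_from_descriptors(desc)
    s <- 10 * dsig(irm, par) / dsig(desc$mode, par)
    sp <- ims_spectrum(s, irm)
    res <- scan_peaks(sp, 1, cfg)
    w_irm <- cfg$d_grid / cfg$d_last * n * (irm[2] - irm[1])
    if (nrow(res) == 1 && abs(res$mode - desc$mode) < w_irm) hits <- hits + 1
  }
  expect_gte(hits, 19)
  # two well-separated peaks arrive left to right
  d1 <- drift_to_descriptors(0.7 / cfg$c_t_given_d, cfg)
  d2 <- drift_to_descriptors(1.1 / cfg$c_t_given_d, cfg)
  p1 <- sig_from_descriptors(d1); p2 <- sig_from_descriptors(d2)
  s2 <- 12 * dsig(irm, p1) / dsig(d1$mode, p1) +
    9 * dsig(irm, p2) / dsig(d2$mode, p2)
  res2 <- scan_peaks(ims_spectrum(s2, irm), 1, cfg)
  expect_equal(nrow(res2), 2)
  expect_true(all(diff(res2$mode) > 0))
  expect_equal(res2$mode, c(d1$mode, d2$mode), tolerance = 0.01)
  expect_error(scan_peaks(ims_spectrum(rep(0, 3), irm[1:3] ), 1, cfg),
               "window wider")
})

test_that("rolling quadratic fits equal the closed-form regression", {
  set.seed(32)
  s <- rnorm(200)
  w <- 15
  th <- imspeaks:::rolling_quadratic(s, w)
  for (i in c(1, 57, 186)) {
    x <- seq_len(w) - (w + 1) / 2
    ref <- stats::lm.fit(cbind(1, x, x^2), s[i:(i + w - 1)])$coefficients
    expect_equal(th[i, ], ref, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("spectrum reduction recovers tailing plus peaks", {
  cfg <- test_config()
  n <- 2500
  irm <- seq_len(n) / n * cfg$t_last
  tail_par <- sig_params(mu = 0.2, lambda = 0.05, shift = 0.46)
  modes <- c(0.75, 0.95, 1.2)
  s <- 12 * dsig(irm, tail_par)
  for (m in modes) {
    d <- drift_to_descriptors(m / cfg$c_t_given_d, cfg)
    p <- sig_from_descriptors(d)
    s <- s + 10 * dsig(irm, p) / dsig(d$mode, p)
  }
  sp <- ims_spectrum(s, irm)
  # the spectrum is noiseless, so a small noise scale is the consistent state
  nm <- structure(list(mu_n = 0, sigma_n = 0.3), class = "ims_noise_model")
  red <- suppressWarnings(reduce_spectrum(sp, nm, cfg))
  found <- vapply(modes, function(m) any(abs(red$peaks$mode - m) < 0.01),
                  logical(1))
  expect_true(all(found))
  expect_true(all(diff(red$peaks$mode) > 0))
  # reconstruction: peaks + tailing approximate the input
  recon <- red$tailing$v * dsig(irm, red$tailing$params)
  for (i in seq_len(nrow(red$peaks))) {
    recon <- recon + red$peaks$v[i] *
      dsig(irm, red$peaks$mu[i], red$peaks$lambda[i], red$peaks$shift[i])
  }
  expect_lt(sqrt(sum((recon - s)^2) / sum(s^2)), 0.15)
  # all-zero input reduces to nothing
  red0 <- reduce_spectrum(ims_spectrum(rep(0, n), irm), nm, cfg)
  expect_equal(nrow(red0$peaks), 0)
  expect_equal(red0$tailing$v, 0)
})
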