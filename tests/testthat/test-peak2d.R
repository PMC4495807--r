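# build a clean synthetic chain from a known 2-D peak: one 1-D peak row per
# retention step, heights following the retention-axis model
synthetic_chain <- function(r_mode, t_mode, height, cfg, dr = 0.5,
                            span = 3, noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  xi_r <- ret_width(r_mode, cfg)
  rd <- sig_descriptors(mean = r_mode + xi_r / (4 * phi_fwhm),
                        sigma = xi_r / phi_fwhm, mode = r_mode)
  rp <- sig_from_descriptors(rd)
  td <- drift_to_descriptors(t_mode / cfg$c_t_given_d, cfg)
  tp <- sig_from_descriptors(td)
  r <- seq(r_mode - span * rd$sigma, r_mode + span * rd$sigma, by = dr)
  h <- height * dsig(r, rp) / dsig(rd$mode, rp)
  if (noise > 0) h <- pmax(h + rnorm(length(r), 0, noise), 0)
  v <- h / dsig(td$mode, tp)
  data.frame(r = r, mode = td$mode, mean = td$mean, sigma = td$sigma,
             mu = tp$mu, lambda = tp$lambda, shift = tp$shift,
             v = v, height = h)
}

test_that("retention profiles report positive model heights per member", {
  cfg <- test_config()
  ch <- synthetic_chain(60, 0.9, 12, cfg)
  prof <- chain_profile(ch)
  expect_equal(nrow(prof), nrow(ch))
  expect_true(all(prof$h > 0))
  expect_equal(prof$h, ch$height, tolerance = 1e-9)
  one <- chain_profile(ch[5, ])
  expect_equal(nrow(one), 1)
  expect_error(chain_profile(ch[0, ]), "empty")
})

test_that("window formulas recover the parabola vertex quantities", {
  # theta = (1, 8, -2): vertex at 2, apex 9, sigma = 1.5
  th2 <- -2; th1 <- 8; th0 <- 1
  m <- -th1 / (2 * th2)
  v <- th0 - th1^2 / (4 * th2)
  expect_equal(m, 2)
  expect_equal(v, 9)
  expect_equal(sqrt(v / (2 * abs(th2))), 1.5)
  # retention_windows reproduces them from sampled data
  cfg <- test_config()
  r <- seq(0.5, 3.5, by = 0.25)
  h <- th0 + th1 * r + th2 * r^2
  prof <- data.frame(r = r, h = h)
  wins <- retention_windows(prof, sigma_n = 0.5,
                            ims_config(r_width_offset = 3,
                                       r_width_factor = 0.0001))
  expect_gte(length(wins), 1)
  expect_equal(wins[[1]]$desc$mode, 2, tolerance = 0.05)
  expect_equal(wins[[1]]$v_r, 9, tolerance = 0.05)
  # too-short profiles yield nothing
  expect_length(retention_windows(prof[1:2, ], 0.5, cfg), 0)
})

test_that("profile deconvolution keeps memberships normalised and splits bumps", {
  cfg <- test_config()
  # single clean bump: one component takes essentially all mass
  ch <- synthetic_chain(60, 0.9, 12, cfg)
  prof <- chain_profile(ch)
  wins <- retention_windows(prof, 1, cfg)
  expect_gte(length(wins), 1)
  dec <- deconvolute_profile(prof, wins, cfg)
  expect_equal(sum(vapply(dec$components, `[[`, numeric(1), "w")), 1,
               tolerance = 1e-9)
  core <- abs(prof$r - 60) < 2
  expect_true(all(rowSums(dec$memberships)[core] > 0.95))
  # two well-separated bumps resolve into two components
  ch2 <- synthetic_chain(40, 0.9, 12, cfg)
  ch3 <- synthetic_chain(70, 0.9, 12, cfg)
  chb <- rbind(ch2, ch3)
  profb <- chain_profile(chb)
  winsb <- retention_windows(profb, 1, cfg)
  decb <- deconvolute_profile(profb, winsb, cfg)
  modes <- vapply(decb$components, function(cp) cp$desc$mode, numeric(1))
  expect_true(any(abs(modes - 40) < ret_width(40, cfg) / 2))
  expect_true(any(abs(modes - 70) < ret_width(70, cfg) / 2))
})

test_that("membership-weighted IRM descriptors average the chain", {
  cfg <- test_config()
  ch <- synthetic_chain(60, 0.9, 12, cfg)
  n <- nrow(ch)
  # uniform memberships on one component: plain averages
  M <- matrix(1, n, 1)
  out <- chain_irm_descriptors(ch, M)
  expect_length(out, 1)
  expect_equal(out[[1]]$desc$mode, mean(ch$mode), tolerance = 1e-9)
  expect_equal(out[[1]]$desc$sigma, mean(ch$sigma), tolerance = 1e-9)
  # identical members reproduce the member's descriptors
  expect_equal(out[[1]]$desc$mean, ch$mean[1], tolerance = 1e-9)
  expect_error(chain_irm_descriptors(ch, M[-1, , drop = FALSE]),
               "inconsistent")
})

test_that("acceptance filters pass clean peaks and reject boundary violations", {
  cfg <- test_config()
  sigma_n <- 1
  ch <- synthetic_chain(60, 0.9, 10, cfg)
  out <- chain_to_peaks(ch, sigma_n, cfg)
  expect_equal(nrow(out), 1)
  expect_equal(out$r_mode, 60, tolerance = ret_width(60, cfg) / 4)
  expect_equal(out$t_mode, 0.9, tolerance = cfg$d_grid * cfg$c_t_given_d)
  # the window-parabola spread estimate carries a known upward bias
  expect_equal(out$r_sigma, ret_width(60, cfg) / phi_fwhm, tolerance = 0.35)
  expect_equal(out$t_sigma,
               drift_to_descriptors(0.9 / cfg$c_t_given_d, cfg)$sigma,
               tolerance = 0.1)
  # height filter: the same chain against a large noise floor is rejected
  # (model height just below noise_margin * sigma_n)
  h_model <- out$volume * dsig(out$t_mode, out$mu_t, out$lambda_t, out$o_t) *
    dsig(out$r_mode, out$mu_r, out$lambda_r, out$o_r)
  too_high <- h_model / cfg$noise_margin / 0.99
  expect_equal(nrow(chain_to_peaks(ch, too_high, cfg)), 0)
  # width filter: force the retention spread outside the admissible band
  prof <- chain_profile(ch)
  wins <- retention_windows(prof, sigma_n, cfg)
  dec <- deconvolute_profile(prof, wins, cfg)
  irm <- chain_irm_descriptors(ch, dec$memberships)
  narrow <- dec$components
  nd <- narrow[[1]]$desc
  narrow[[1]]$desc <- sig_descriptors(nd$mode + 0.3 * ret_width(60, cfg) /
                                        phi_fwhm / 4, ret_width(60, cfg) /
                                        phi_fwhm * 0.3, nd$mode)
  expect_equal(nrow(finalize_peaks(narrow, irm, ch, sigma_n, cfg)), 0)
  # chains below the minimum length produce nothing
  expect_equal(nrow(chain_to_peaks(ch[1:2, ], sigma_n, cfg)), 0)
})

test_that("low correlation with the quadratic approximation rejects a model", {
  cfg <- test_config()
  ch <- synthetic_chain(60, 0.9, 10, cfg)
  prof <- chain_profile(ch)
  wins <- retention_windows(prof, 1, cfg)
  dec <- deconvolute_profile(prof, wins, cfg)
  irm <- chain_irm_descriptors(ch, dec$memberships)
  # sabotage the stored parabola: replace with an upward-sloping line so the
  # correlation over the mode window collapses
  dec$components[[1]]$theta <- c(0, 1, -1e-9)
  out <- finalize_peaks(dec$components, irm, ch, 1, cfg)
  expect_equal(nrow(out), 0)
})

test_that("accepted peak count never exceeds the component count", {
  cfg <- test_config()
  set.seed(9)
  for (i in 1:5) {
    ch <- synthetic_chain(runif(1, 30, 80), runif(1, 0.7, 1.2),
                          runif(1, 6, 15), cfg, noise = 0.3, seed = i)
    prof <- chain_profile(ch)
    wins <- retention_windows(prof, 1, cfg)
    out <- chain_to_peaks(ch, 1, cfg)
    expect_lte(nrow(out), max(length(wins), 0))
  }
})

test_that("volume matches the numerically integrated reconstructed model", {
  cfg <- test_config()
  ch <- synthetic_chain(60, 0.9, 10, cfg)
  out <- chain_to_peaks(ch, 1, cfg)
  g2 <- function(r, t) {
    out$volume * dsig(r, out$mu_r, out$lambda_r, out$o_r) *
      dsig(t, out$mu_t, out$lambda_t, out$o_t)
  }
  rs <- seq(out$o_r + 1e-6, out$r_mode + 40, length.out = 2000)
  ts <- seq(out$o_t + 1e-9, out$t_mode + 0.2, length.out = 2000)
  vol <- sum(outer(dsig(rs, out$mu_r, out$lambda_r, out$o_r),
                   dsig(ts, out$mu_t, out$lambda_t, out$o_t))) *
    diff(rs[1:2]) * diff(ts[1:2]) * out$volume
  expect_gt(out$volume, 0)
  expect_lt(abs(vol - out$volume) / out$volume, 1)   # within 2x
})
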