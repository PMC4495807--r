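test_that("shifted inverse-Gaussian density has the right support and values", {
  # zero at and below the offset
  expect_identical(dsig(0, 1, 1, 0), 0)
  expect_identical(dsig(-3, 1, 1, 0), 0)
  expect_identical(dsig(2, 1, 1, 2), 0)
  # at x - o = mu the exponent vanishes
  expect_equal(dsig(1, 1, 1, 0), 1 / sqrt(2 * pi), tolerance = 1e-12)
  expect_equal(dsig(3.5, 1.5, 1.5, 2), sqrt(1.5 / (2 * pi * 1.5^3)),
               tolerance = 1e-12)
  expect_error(dsig(1, -1, 1), "invalid parameter")
  expect_error(dsig(1, 1, 0), "invalid parameter")
})

test_that("density integrates to one over its support", {
  grid <- expand.grid(mu = c(0.1, 1, 4), lambda = c(0.5, 2, 50),
                      shift = c(-2, 0, 3))
  for (i in seq_len(nrow(grid))) {
    p <- sig_params(grid$mu[i], grid$lambda[i], grid$shift[i])
    s <- sqrt(p$mu^3 / p$lambda)
    q <- stats::integrate(dsig, p$shift, p$shift + p$mu + 50 * s,
                          mu = p$mu, lambda = p$lambda, shift = p$shift,
                          rel.tol = 1e-9)$value
    expect_equal(q, 1, tolerance = 1e-6)
  }
})

test_that("parameter-to-descriptor conversion matches closed forms and argmax", {
  d <- sig_to_descriptors(sig_params(1, 1, 0))
  expect_equal(d$mean, 1)
  expect_equal(d$sigma, 1)
  expect_equal(d$mode, sqrt(3.25) - 1.5, tolerance = 1e-12)
  expect_equal(sig_to_descriptors(sig_params(4, 2, 0))$sigma, sqrt(32),
               tolerance = 1e-12)
  # translation equivariance of the offset
  d0 <- sig_to_descriptors(sig_params(2, 5, 0))
  d7 <- sig_to_descriptors(sig_params(2, 5, 7))
  expect_equal(d7$mean, d0$mean + 7)
  expect_equal(d7$mode, d0$mode + 7)
  expect_equal(d7$sigma, d0$sigma)
  # numerical argmax agrees with the mode formula
  for (p in list(sig_params(1, 1, 0), sig_params(0.5, 8, -1),
                 sig_params(3, 0.7, 2))) {
    dd <- sig_to_descriptors(p)
    opt <- stats::optimize(function(x) -dsig(x, p), lower = p$shift + 1e-9,
                           upper = dd$mean + 5 * dd$sigma, tol = 1e-10)
    expect_equal(opt$minimum, dd$mode, tolerance = 1e-5)
  }
})

test_that("descriptor conversion round-trips and respects the skew branches", {
  # descriptor-space roundtrip identity on a parameter grid spanning both
  # skew branches
  grid <- expand.grid(mu = c(0.05, 0.3, 1, 3, 9),
                      lambda = c(0.05, 0.4, 2, 20, 90),
                      shift = c(-4, 0, 4.5))
  for (i in seq_len(nrow(grid))) {
    p <- sig_params(grid$mu[i], grid$lambda[i], grid$shift[i])
    d <- sig_to_descriptors(p)
    for (branch in c("min", "max")) {
      p2 <- sig_from_descriptors(d, skew = branch)
      d2 <- sig_to_descriptors(p2)
      scale <- max(abs(unlist(d)))
      expect_equal(d2$mean, d$mean, tolerance = 1e-6 * scale)
      expect_equal(d2$sigma, d$sigma, tolerance = 1e-6 * scale)
      expect_equal(d2$mode, d$mode, tolerance = 1e-6 * scale)
    }
    # parameter-space identity on the matching branch
    z <- 3 * p$mu / (2 * p$lambda)
    branch <- if (z < 1) "min" else "max"
    p2 <- sig_from_descriptors(d, skew = branch)
    expect_equal(p2$mu, p$mu, tolerance = 1e-5)
    expect_equal(p2$lambda, p$lambda, tolerance = 1e-4)
    expect_equal(p2$shift, p$shift, tolerance = 1e-5)
  }
})

test_that("the two skew branches are distinct pre-images of one descriptor set", {
  d <- sig_descriptors(mean = 1, sigma = 1, mode = 0.30278)
  lo <- sig_from_descriptors(d, skew = "min")
  hi <- sig_from_descriptors(d, skew = "max")
  expect_equal(hi$shift, 0, tolerance = 1e-4)
  expect_equal(hi$mu, 1, tolerance = 1e-4)
  expect_equal(hi$lambda, 1, tolerance = 1e-3)
  expect_equal(lo$shift, -0.5, tolerance = 1e-3)
  # both reproduce the descriptors
  for (p in list(lo, hi)) {
    d2 <- sig_to_descriptors(p)
    expect_equal(unlist(d2), unlist(d), tolerance = 1e-4)
  }
  expect_error(sig_from_descriptors(sig_descriptors(1, 1, 0.9)),
               NA)  # valid: mode < mean
  expect_error(sig_descriptors(1, 1, 1.5), "mode must be < mean")
})

test_that("mean lies between mode and mode + 0.7177 sigma for all valid shapes", {
  set.seed(42)
  for (i in 1:200) {
    p <- sig_params(runif(1, 0.01, 10), runif(1, 0.01, 100), runif(1, -5, 5))
    d <- sig_to_descriptors(p)
    expect_lt(d$mode, d$mean)
    expect_lt(d$mean, d$mode + 0.7177 * d$sigma)
  }
})

test_that("half-width conversion uses the Gaussian relation", {
  expect_equal(halfwidth_sigma(phi_fwhm), 1)
  expect_identical(halfwidth_sigma(0), 0)
  expect_error(halfwidth_sigma(-1), ">= 0")
  # measure a unit Gaussian's half-height width by root finding
  half <- stats::uniroot(function(x) stats::dnorm(x) - stats::dnorm(0) / 2,
                         c(0.5, 2), tol = 1e-12)$root
  expect_equal(halfwidth_sigma(2 * half), 1, tolerance = 1e-6)
})

test_that("drift-mode descriptors follow the broadening model", {
  cfg <- ims_config()
  d1 <- drift_to_descriptors(10, cfg)
  d2 <- drift_to_descriptors(20, cfg)
  expect_equal(d2$mode, 2 * d1$mode, tolerance = 1e-12)
  # vanishing diffusion: half-width reduces to the grid opening time
  cfg0 <- ims_config(diffusion_coeff = 1e-30)
  d0 <- drift_to_descriptors(15, cfg0)
  expect_equal(d0$sigma, cfg0$c_t_given_d * cfg0$d_grid / phi_fwhm,
               tolerance = 1e-6)
  # mean exceeds mode everywhere
  for (ds in seq(1, 49, by = 4)) {
    dd <- drift_to_descriptors(ds, cfg)
    expect_gt(dd$mean, dd$mode)
  }
  expect_error(drift_to_descriptors(-1, cfg), "d_star")
})

test_that("retention width grows linearly from the offset", {
  cfg <- ims_config()
  expect_equal(ret_width(0, cfg), 2.5)
  expect_equal(ret_width(100, cfg), 8.5)
  r <- seq(0, 500, by = 50)
  expect_true(all(diff(ret_width(r, cfg)) > 0))
  expect_error(ret_width(-2, cfg), ">= 0")
})

test_that("configuration files round-trip through YAML and JSON", {
  cfg <- ims_config(t_width = 0.004, noise_margin = 5)
  yml <- tempfile(fileext = ".yaml")
  writeLines(yaml::as.yaml(list(t_width = 0.004, noise_margin = 5)), yml)
  got <- read_ims_config(yml)
  expect_equal(got$t_width, cfg$t_width)
  expect_equal(got$noise_margin, 5)
  expect_equal(got$rho_min, 0.95)       # untouched default
  js <- tempfile(fileext = ".json")
  writeLines('{"r_width_offset": 3.0}', js)
  expect_equal(read_ims_config(js)$r_width_offset, 3.0)
  bad <- tempfile(fileext = ".yaml")
  writeLines("nonsense_field: 1", bad)
  expect_error(read_ims_config(bad), "unknown config field")
})
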