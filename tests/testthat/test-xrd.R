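test_that("d-spacings follow the closed crystallographic forms", {
  expect_equal(d_spacing(unit_cell("cubic", a = 1), 1, 0, 0), 1.0)
  cao <- unit_cell("cubic", a = 4.8152)
  expect_equal(d_spacing(cao, 2, 0, 0), 4.8152 / 2)
  ha <- unit_cell("hexagonal", a = 9.424, c = 6.879)
  inv_d2 <- (4 / 3) * 7 / 9.424^2 + 1 / 6.879^2
  expect_equal(d_spacing(ha, 2, 1, 1), 1 / sqrt(inv_d2))
  expect_equal(d_spacing(ha, 2, 1, 1), 2.8147, tolerance = 1e-4)
  ortho <- unit_cell("orthorhombic", a = 20.397, b = 5.412, c = 9.161)
  expect_equal(d_spacing(ortho, 1, 1, 1),
               1 / sqrt(1 / 20.397^2 + 1 / 5.412^2 + 1 / 9.161^2))
  expect_error(d_spacing(ha, 0, 0, 0), "zero")
  expect_error(unit_cell("hexagonal", a = 9.4), "needs c")
})

test_that("Bragg angles match geometry, including the trace-phase positions", {
  expect_equal(bragg_two_theta(CU_KALPHA1, CU_KALPHA1), 60.0)
  cao200 <- bragg_two_theta(d_spacing(unit_cell("cubic", a = 4.8152), 2, 0, 0))
  expect_equal(cao200, 37.3192, tolerance = 1e-4)
  expect_lt(abs(cao200 - 37.5), 0.5)   # the CaO shoulder near 37.5 deg
  ha <- unit_cell("hexagonal", a = 9.424, c = 6.879)
  ha211 <- bragg_two_theta(d_spacing(ha, 2, 1, 1))
  expect_equal(ha211, 31.77, tolerance = 1e-3)
  expect_error(bragg_two_theta(0.5, 1.54), "unobservable")
})

test_that("profile integral breadths match numerical quadrature", {
  # Lorentzian: beta = (pi/2) FWHM
  fw <- 0.13
  num <- integrate(lorentz_profile, -2000, 2000, fwhm = fw,
                   rel.tol = 1e-12)$value
  expect_equal(beta_lorentzian(fw), num, tolerance = 1e-4)
  # Gaussian: beta = (FWHM/2) sqrt(pi/ln 2)
  num_g <- integrate(gauss_profile, -Inf, Inf, fwhm = fw)$value
  expect_equal(beta_gaussian(fw), num_g, tolerance = 1e-9)
  # Voigt: area/height from quadrature equals the closed-form combination
  sigma <- 0.03; gamma <- 0.02
  area <- integrate(function(x) voigt(x, sigma, gamma), -Inf, Inf,
                    rel.tol = 1e-10)$value
  expect_equal(beta_voigt(sigma, gamma), area / voigt(0, sigma, gamma),
               tolerance = 1e-6)
})

test_that("simulated patterns are seeded and degrade to the instrument profile", {
  pks <- data.frame(two_theta = c(25.9, 31.77), intensity = c(400, 1000))
  p1 <- simulate_pattern(pks, cs_nm = 120, noise_sd = 5, seed = 77,
                         grid = seq(20, 40, by = 0.02))
  p2 <- simulate_pattern(pks, cs_nm = 120, noise_sd = 5, seed = 77,
                         grid = seq(20, 40, by = 0.02))
  expect_identical(p1$intensity, p2$intensity)

  # crystallite-size broadening vanishes as CS grows: the profile converges
  # to the pure instrumental Gaussian (the residual Lorentzian fraction
  # scales as 1/CS, so the deviation shrinks accordingly)
  grid <- seq(31, 32.5, by = 0.002)
  dev_at <- function(cs) {
    pv <- simulate_pattern(data.frame(two_theta = 31.77, intensity = 1),
                           cs_nm = cs, instrument_fwhm = 0.05, noise_sd = 0,
                           grid = grid, background = c(0, 0))
    max(abs(pv$intensity - gauss_profile(grid - 31.77, 0.05)))
  }
  devs <- vapply(c(1e4, 1e6, 1e8), dev_at, 0)
  expect_true(all(diff(devs) < 0))
  expect_lt(devs[3], 1e-6)

  # single noise-free peak: values match an independent Gaussian-Lorentzian
  # convolution by quadrature, and the area/height breadth matches the
  # closed-form Voigt combination
  sigma <- 0.05 / (2 * sqrt(2 * log(2)))
  fwl <- (2 / pi) * (CU_KALPHA1 / 10) / (60 * cos(31.77 / 2 * pi / 180)) *
    180 / pi
  gam <- fwl / 2
  vconv <- function(x) vapply(x, function(xi)
    integrate(function(u) exp(-u^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi)) *
                (gam / pi) / ((xi - u)^2 + gam^2),
              -Inf, Inf, rel.tol = 1e-11)$value, 0)
  grid2 <- seq(31, 32.5, by = 0.1)
  ps <- simulate_pattern(data.frame(two_theta = 31.77, intensity = 1),
                         cs_nm = 60, instrument_fwhm = 0.05, noise_sd = 0,
                         grid = grid2, background = c(0, 0))
  ref <- vconv(grid2 - 31.77) / vconv(0)
  expect_equal(ps$intensity, ref, tolerance = 1e-8)
  expect_equal(beta_voigt(sigma, gam), 1 / vconv(0), tolerance = 1e-4)

  expect_warning(
    simulate_pattern(data.frame(two_theta = 80, intensity = 1), cs_nm = 100,
                     grid = seq(3, 70, 0.02)),
    "outside grid")
})

test_that("peak fitting recovers planted widths and flags flat windows", {
  # exact model class, no noise: near-exact recovery
  grid <- seq(29, 35, by = 0.01)
  ps <- simulate_pattern(data.frame(two_theta = 31.77, intensity = 800),
                         cs_nm = 29, instrument_fwhm = 0.05, noise_sd = 0,
                         grid = grid)
  fit <- fit_peak(ps, c(29.5, 34), instrument_fwhm = 0.05)
  fwl_planted <- (2 / pi) * (CU_KALPHA1 / 10) /
    (29 * cos(31.77 / 2 * pi / 180)) * 180 / pi
  expect_equal(fit$fwhm_l_deg, fwl_planted, tolerance = 1e-6)
  expect_equal(fit$center_deg, 31.77, tolerance = 1e-6)
  expect_equal(fit$cs_nm, 29, tolerance = 1e-6)
  expect_equal(fit$beta_rad, (pi / 2) * fit$fwhm_l_rad)

  flat <- diffraction_pattern(seq(40, 45, 0.02),
                              rep(10, length(seq(40, 45, 0.02))))
  expect_error(fit_peak(flat, c(41, 44)), "flat background|converge")
})

test_that("fitted width grows as planted crystallite size shrinks", {
  widths <- vapply(c(230, 120, 29), function(cs) {
    ps <- simulate_pattern(data.frame(two_theta = 31.77, intensity = 1000),
                           cs_nm = cs, instrument_fwhm = 0.05, noise_sd = 0,
                           grid = seq(30, 34, by = 0.005))
    fit_peak(ps, c(30.5, 33.5), instrument_fwhm = 0.05)$fwhm_l_deg
  }, 0)
  expect_true(all(diff(widths) > 0))
})

test_that("the Scherrer relation round-trips exactly and is monotone", {
  theta <- 31.77 / 2 * pi / 180
  for (cs0 in c(29, 120, 230)) {
    beta <- (CU_KALPHA1 / 10) / (cs0 * cos(theta))
    expect_equal(crystallite_size(beta, theta), cs0)
  }
  # strictly decreasing in beta at fixed theta, lambda
  betas <- seq(1e-4, 1e-2, length.out = 50)
  cs <- crystallite_size(betas, theta)
  expect_true(all(diff(cs) < 0))
  # brute-force grid against direct formula evaluation
  for (b in c(5e-4, 2e-3, 8e-3)) for (th in c(0.1, 0.3, 0.6)) {
    expect_equal(crystallite_size(b, th, 1.540598),
                 1.540598 / (b * cos(th)) / 10)
  }
  expect_error(crystallite_size(0, theta), "positive")
  expect_error(crystallite_size(1e-3, 2), "theta")
})

test_that("phase matching assigns peaks by nearest computed reflection", {
  ha <- phase("hydroxyapatite", unit_cell("hexagonal", a = 9.424, c = 6.879),
              rbind(c(0, 0, 2), c(2, 1, 1), c(3, 0, 0), c(2, 0, 2)))
  cao <- phase("CaO", unit_cell("cubic", a = 4.8152),
               rbind(c(1, 1, 1), c(2, 0, 0), c(2, 2, 0)))
  ha211 <- bragg_two_theta(d_spacing(ha$cell, 2, 1, 1))
  res <- match_phases(ha211, list(ha, cao), tolerance = 0.2)
  expect_equal(res$phase, "hydroxyapatite")
  expect_equal(unlist(res[c("h", "k", "l")]), c(2, 1, 1), ignore_attr = TRUE)
  # the ~37.5 deg shoulder matches CaO (200), not any listed apatite line
  res2 <- match_phases(37.35, list(ha, cao), tolerance = 0.5)
  expect_equal(res2$phase, "CaO")
  expect_equal(unlist(res2[c("h", "k", "l")]), c(2, 0, 0), ignore_attr = TRUE)
  # no candidate within tolerance
  res3 <- match_phases(50.0, list(ha, cao), tolerance = 0.2)
  expect_true(is.na(res3$phase))
})

test_that("XY traces and phase YAML round-trip through disk", {
  p <- simulate_pattern(data.frame(two_theta = 31.77, intensity = 100),
                        cs_nm = 120, noise_sd = 2, seed = 5,
                        grid = seq(30, 34, by = 0.02))
  path <- tempfile(fileext = ".xy")
  write_xy(p, path)
  p2 <- read_xy(path)
  expect_equal(p2$two_theta, p$two_theta, tolerance = 1e-6)
  expect_equal(p2$intensity, p$intensity, tolerance = 1e-6)
  unlink(path)

  ypath <- tempfile(fileext = ".yaml")
  writeLines(
"- name: CaO
  system: cubic
  a: 4.8152
  hkl:
    - [1, 1, 1]
    - [2, 0, 0]
", ypath)
  phs <- read_phases_yaml(ypath)
  expect_length(phs, 1)
  expect_equal(phs[[1]]$name, "CaO")
  expect_equal(nrow(phs[[1]]$hkl), 2)
  unlink(ypath)
})
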