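# Binning and maximum-likelihood diffusivity fitting.

test_that("binning follows the half-open convention and conserves records", {
  lat <- bin_lattice(origin = c(0, 0), bin_size = 0.4, n_rows = 4, n_cols = 4)
  tab <- data.frame(x0_um = c(0, 0.4, 1.59, 2.0), y0_um = c(0, 0.4, 1.59, 0.1),
                    dx_um = 0, dy_um = 0)
  b <- bin_displacements(tab, lat)
  expect_equal(b$row[1:3], c(1L, 2L, 4L))
  expect_equal(b$col[1:3], c(1L, 2L, 4L))
  # x = 2.0 lies on the outer boundary -> out of field under [lo, hi)
  expect_true(is.na(b$row[4]))
  expect_identical(b$n_out_of_field, 1L)

  set.seed(1)
  tab2 <- data.frame(x0_um = runif(100, 0, 1.6), y0_um = runif(100, 0, 1.6),
                     dx_um = 0, dy_um = 0)
  b2 <- bin_displacements(tab2, lat)
  expect_identical(length(b2$bin_id) - b2$n_out_of_field, 100L)
  expect_warning(bin_displacements(tab2[0, ], lat), "empty")
})

test_that("MLE reproduces the closed-form estimator", {
  s0 <- acquisition_settings(dt = 1e-3, sigma_loc = 0, seed = 1L)
  # four displacements of 0.1 um: D = sum(r^2) / (4 N dt) = 2.5 um^2/s
  f <- fit_diffusivity(rep(0.1, 4), s0, n_min = 1L)
  expect_equal(f$D_hat, 2.5, tolerance = 1e-9)
  # all-zero magnitudes: frozen limit D = 0
  expect_equal(fit_diffusivity(rep(0, 20), s0)$D_hat, 0)
  expect_error(fit_diffusivity(c(0.1, NaN), s0), "finite")
  expect_error(fit_diffusivity(c(0.1, -0.2), s0), ">= 0")
})

test_that("MLE matches sum(r^2)/(4 N dt) to 1e-9 over 100 seeded instances", {
  s0 <- acquisition_settings(dt = 1e-3, sigma_loc = 0, seed = 1L)
  set.seed(42)
  for (i in 1:100) {
    D_true <- runif(1, 0.5, 9)
    r <- rayleigh_r(200, D_true)
    D_cf <- sum(r^2) / (4 * length(r) * 1e-3)
    expect_equal(fit_diffusivity(r, s0)$D_hat, D_cf, tolerance = 1e-9)
  }
})

test_that("fitter recovers D with localization error, and masks small bins", {
  s <- fast_settings(sigma_loc = 0.02)
  set.seed(7)
  r <- rayleigh_r(5000, 7, sigma_loc = 0.02)
  expect_lt(abs(fit_diffusivity(r, s)$D_hat - 7) / 7, 0.05)

  small <- fit_diffusivity(rayleigh_r(5, 7), s, n_min = 10L)
  expect_false(small$converged)
  expect_true(is.na(small$D_hat))
})

test_that("D_hat is nondecreasing in the empirical mean squared displacement", {
  s0 <- acquisition_settings(dt = 1e-3, sigma_loc = 0.01, seed = 1L)
  set.seed(3)
  sets <- lapply(1:12, function(i) rayleigh_r(300, runif(1, 0.2, 9),
                                              sigma_loc = 0.01))
  msd <- vapply(sets, function(r) mean(r^2), 0)
  D_hat <- vapply(sets, function(r) fit_diffusivity(r, s0)$D_hat, 0)
  expect_false(is.unsorted(D_hat[order(msd)]))
})

test_that("joint background fit recovers both D and phi", {
  s <- fast_settings(sigma_loc = 0)
  set.seed(21)
  n <- 8000; phi_true <- 0.25
  n_bg <- rbinom(1, n, phi_true)
  r <- c(rayleigh_r(n - n_bg, 2), 0.8 * sqrt(runif(n_bg)))  # uniform in area
  fit <- fit_diffusivity(r, s, background = TRUE)
  expect_true(fit$converged)
  expect_lt(abs(fit$D_hat - 2) / 2, 0.1)
  expect_lt(abs(fit$phi - phi_true), 0.08)
  # and the background model should beat phi = 0 on likelihood
  expect_gt(fit$log_likelihood, fit_diffusivity(r, s)$log_likelihood)
})

test_that("map recovers uniform ground truth and two-region contrast", {
  s <- fast_settings(seed = 31L)
  # uniform D = 1.5 at the filament-state value
  f15 <- uniform_field(D = 1.5)
  sim <- simulate_displacements(f15, s, 2e5)
  m <- map_diffusivity(sim$records, lattice_from_field(f15), s)
  expect_lt(abs(m$median_D - 1.5) / 1.5, 0.10)
  expect_true(all(m$n[!m$masked] >= 10))

  # two-region field: >2-fold separation between on- and off-mask medians
  f2 <- two_region_field()
  sim2 <- simulate_displacements(f2, fast_settings(seed = 32L), 2e5)
  m2 <- map_diffusivity(sim2$records, lattice_from_field(f2), s)
  in_mask <- median(m2$D_hat[f2$mask & !m2$masked])
  out_mask <- median(m2$D_hat[!f2$mask & !m2$masked])
  expect_lt(in_mask, out_mask)
  expect_gt(out_mask / in_mask, 2)

  expect_warning(
    m0 <- map_diffusivity(sim$records[0, ], lattice_from_field(f15), s),
    "empty")
  expect_true(all(m0$masked))
})

test_that("displacement histogram is normalized with the Rayleigh mode", {
  s <- fast_settings(sigma_loc = 0.02)
  set.seed(5)
  r <- rayleigh_r(4000, 3, sigma_loc = 0.02)
  fit <- fit_diffusivity(r, s)
  h <- displacement_histogram(r, fit, s, n_bins = 30)
  expect_equal(sum(h$histogram$count), length(r))
  # histogram density integrates to 1 over its breaks
  expect_equal(sum(h$histogram$density * diff(h$breaks)), 1, tolerance = 1e-9)
  # fitted curve integrates to ~1 on [0, R_cap] by quadrature
  pdf_fun <- approxfun(h$curve$r, h$curve$pdf)
  expect_equal(integrate(pdf_fun, 0, s$capture_radius)$value, 1,
               tolerance = 1e-3)
  # mode of the single-population curve sits at r = s = sqrt(2 D dt + 2 sig^2)
  mode_hat <- h$curve$r[which.max(h$curve$pdf)]
  s_expected <- sqrt(2 * fit$D_hat * s$dt + 2 * s$sigma_loc^2)
  expect_lt(abs(mode_hat - s_expected), diff(h$curve$r[1:2]) * 1.5)

  expect_error(displacement_histogram(r, fit, s, n_bins = 1), "n_bins")
  expect_error(displacement_histogram(numeric(0), fit, s), "no displacement")
})

test_that("histogram and map render to a graphics device", {
  pdf(NULL)
  on.exit(dev.off())
  s <- fast_settings()
  set.seed(6)
  r <- rayleigh_r(500, 2)
  h <- displacement_histogram(r, fit_diffusivity(r, s), s)
  expect_invisible(plot(h))
  f <- two_region_field()
  sim <- simulate_displacements(f, s, 3e4)
  m <- map_diffusivity(sim$records, lattice_from_field(f), s)
  expect_invisible(plot(m))
})
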