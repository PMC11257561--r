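# Synthetic displacement generator: field construction, sampling statistics,
# conservation and determinism.

test_that("filament field handles empty, degenerate and invalid inputs", {
  f0 <- make_filament_field(c(8L, 8L), n_filaments = 0L, D_free = 7)
  expect_false(any(f0$mask))
  expect_true(all(f0$D == 7))

  fd <- make_filament_field(c(8L, 8L), n_filaments = 5L, D_bound = 5,
                            D_free = 5, seed = 2L)
  expect_true(all(fd$D == 5))  # degenerate equality ignores the mask

  expect_error(make_filament_field(c(0L, 8L), 1L), "positive")
  expect_error(make_filament_field(c(8L, 8L), 1L, bound_fraction = 1.2),
               "\\[0, 1\\]")
})

test_that("field generation is deterministic under a fixed seed", {
  f1 <- make_filament_field(c(64L, 64L), 10L, seed = 1L)
  f2 <- make_filament_field(c(64L, 64L), 10L, seed = 1L)
  expect_identical(f1, f2)
  f3 <- make_filament_field(c(64L, 64L), 10L, seed = 2L)
  expect_false(identical(f1$mask, f3$mask))
})

test_that("zero-diffusivity, zero-error limit gives zero displacements", {
  f <- uniform_field(D = 0)
  sim <- simulate_displacements(f, fast_settings(sigma_loc = 0), 500)
  expect_true(all(sim$records$dx_um == 0))
  expect_true(all(sim$records$dy_um == 0))
})

test_that("displacement moments match 2 D dt + 2 sigma^2 per axis", {
  # MSD identity <r^2> = 4 D dt at sigma = 0, within 3 standard errors
  f <- uniform_field(D = 7)
  s <- fast_settings(sigma_loc = 0, seed = 11L)
  sim <- simulate_displacements(f, s, 5e4)
  r2 <- sim$records$dx_um^2 + sim$records$dy_um^2
  se <- sd(r2) / sqrt(length(r2))
  expect_lt(abs(mean(r2) - 4 * 7 * 1e-3), 3 * se)

  # per-axis variance including localization error, and isotropy
  s2 <- fast_settings(sigma_loc = 0.02, seed = 12L)
  sim2 <- simulate_displacements(f, s2, 5e4)
  expected <- 2 * 7 * 1e-3 + 2 * 0.02^2
  for (ax in c("dx_um", "dy_um")) {
    v <- sim2$records[[ax]]^2
    expect_lt(abs(mean(v) - expected), 3 * sd(v) / sqrt(length(v)))
  }
  ct <- cor.test(sim2$records$dx_um, sim2$records$dy_um)
  expect_lt(abs(ct$estimate), 3 / sqrt(nrow(sim2$records)))
})

test_that("records plus discards conserve n_molecules exactly", {
  f <- uniform_field(D = 7)
  # tight capture radius forces discards
  s <- fast_settings(seed = 4L, capture_radius = 0.15)
  sim <- simulate_displacements(f, s, 20000)
  expect_gt(sim$n_discarded, 0)
  expect_identical(nrow(sim$records) + sim$n_discarded, 20000L)
  expect_true(all(sqrt(sim$records$dx_um^2 + sim$records$dy_um^2) <= 0.15))
})

test_that("bound molecules sit on the mask and carry the bound D", {
  f <- two_region_field()
  s <- fast_settings(seed = 5L)
  sim <- simulate_displacements(f, s, 20000)
  b <- sim$records[sim$records$label == "bound", ]
  col <- 1L + floor(b$x0_um / f$bin_size)
  row <- 1L + floor(b$y0_um / f$bin_size)
  expect_true(all(f$mask[cbind(row, col)]))
  # bound fraction of requested molecules ~ binomial around 0.6
  p_hat <- sum(sim$records$label == "bound") / nrow(sim$records)
  expect_lt(abs(p_hat - 0.6), 0.03)
  expect_error(
    simulate_displacements(uniform_field(bound_fraction = 0.5), s, 10),
    "mask is empty")
})

test_that("CSV output is byte-identical under identical seed and settings", {
  f <- two_region_field()
  s <- fast_settings(seed = 9L)
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_displacements(simulate_displacements(f, s, 3000), p1)
  write_displacements(simulate_displacements(f, s, 3000), p2)
  expect_identical(tools::md5sum(p1)[[1]], tools::md5sum(p2)[[1]])
  meta <- jsonlite::read_json(paste0(p1, ".json"))
  expect_identical(meta$n_records + meta$n_discarded, 3000L)
})

test_that("timecourse interpolates bound_fraction linearly and reproducibly", {
  f1 <- two_region_field(); f1$bound_fraction <- 1
  f0 <- f1; f0$bound_fraction <- 0
  tc <- simulate_timecourse(f1, f0, n_steps = 5, fast_settings(seed = 2L), 200)
  expect_equal(tc$bound_fractions, c(1, 0.75, 0.5, 0.25, 0))
  tc2 <- simulate_timecourse(f1, f0, n_steps = 5, fast_settings(seed = 2L), 200)
  expect_identical(lapply(tc$steps, `[[`, "records"),
                   lapply(tc2$steps, `[[`, "records"))

  tc_ends <- simulate_timecourse(f1, f0, n_steps = 2, fast_settings(), 100)
  expect_equal(tc_ends$bound_fractions, c(1, 0))

  f_bad <- make_filament_field(c(4L, 4L), 0L)
  expect_error(simulate_timecourse(f1, f_bad, 3, fast_settings(), 10),
               "congruent")
})

test_that("fitted D rises monotonically along a disassembly timecourse", {
  f1 <- two_region_field(); f1$bound_fraction <- 1
  f0 <- f1; f0$bound_fraction <- 0
  s <- fast_settings(seed = 17L)
  tc <- simulate_timecourse(f1, f0, n_steps = 4, s, 2e4)
  pooled <- vapply(tc$steps, function(st) {
    r <- sqrt(st$records$dx_um^2 + st$records$dy_um^2)
    fit_diffusivity(r, s)$D_hat
  }, 0)
  expect_false(is.unsorted(pooled))
  expect_lt(pooled[1], 2.5)   # near the bound state
  expect_gt(pooled[4], 5)     # near the dispersed state
})
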