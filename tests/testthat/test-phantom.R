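test_that("planted split territories reproduce the requested gap", {
  g <- fixture_grid(48L)
  u <- make_territory("split", c(24, 24), list(radius_mm = 3.2, gap_mm = 4.3), g)
  expect_equal(max(label_components(u$territory)), 2L)
  expect_lt(abs(component_gap(u$territory, g$voxel_size_mm) - 4.3), 0.75 + 1e-9)
})

test_that("pixelated ellipse area approximates the analytic area and converges", {
  # at 1.5 mm the thin minor axis makes the pixelated area phase-dependent;
  # tolerance 4 voxel-areas, shrinking to 1 voxel-area on a 3x finer grid
  g <- fixture_grid(48L)
  u <- make_territory("ellipse", c(24, 24), list(axes_mm = c(10, 4)), g)
  err_coarse <- abs(sum(u$territory) * 2.25 - pi * 5 * 2)
  expect_lt(err_coarse, 4 * 2.25)
  gf <- fixture_grid(144L, voxel = 0.5)
  uf <- make_territory("ellipse", c(72, 72), list(axes_mm = c(10, 4)), gf)
  err_fine <- abs(sum(uf$territory) * 0.25 - pi * 5 * 2)
  expect_lt(err_fine, err_coarse)
  expect_lt(err_fine / (pi * 10), 0.06)
})

test_that("circular territories are near-isotropic", {
  g <- fixture_grid(48L)
  u <- make_territory("circular", c(24, 24), list(radius_mm = 4.5), g)
  fer <- compute_feret(u$territory, g$voxel_size_mm)
  expect_lt(fer[["feret_max_mm"]] / fer[["feret_min_mm"]], 1.2)
})

test_that("shapes that do not fit the grid raise a geometry error", {
  g <- fixture_grid(16L)
  expect_error(
    make_territory("circular", c(8, 8), list(radius_mm = 14), g),
    class = "mumri_geometry_error")
})

test_that("firing probability is a logistic with the stated conventions", {
  expect_equal(firing_probability(10, 10, 0.05), 0.5)
  expect_equal(firing_probability(1e6, 10, 0.05), 1.0)
  expect_equal(firing_probability(10, 10, 0), 0.5)     # step-limit convention
  expect_equal(firing_probability(10.01, 10, 0), 1.0)
  expect_equal(firing_probability(9.99, 10, 0), 0.0)
  # monotone non-decreasing in current
  p <- firing_probability(seq(9, 11, 0.01), 10, 0.05)
  expect_true(all(diff(p) >= 0))
  expect_error(firing_probability(10, 10, -1), class = "mumri_parameter_error")
})

test_that("noise-free simulation has exact void depth and baselines", {
  g <- fixture_grid(32L)
  mask <- square_mask(32L)
  u <- make_territory("circular", c(16, 16), list(radius_mm = 5), g,
                      threshold_mA = 5, firing_width_mA = 0.01,
                      void_fraction = 0.4)
  ph <- phantom(mask, list(u), baseline_intensity = 100, noise_sigma = 0)
  # all currents far above threshold: the unit fires in every dynamic
  sched <- plan_coarse_schedule(20, 0.1, 8)
  sim <- simulate_series(ph, sched, seed = 1)
  expect_true(all(sim$firing == 1L))
  inside <- u$territory & mask$labels > 0L
  outside <- !u$territory & mask$labels > 0L
  for (t in 1:8) {
    expect_true(all(sim$series$pixels[, , t][inside] == 40))
    expect_true(all(sim$series$pixels[, , t][outside] == 100))
  }

  # no units, zero noise: constant baseline
  ph0 <- phantom(mask, list(), baseline_intensity = 100, noise_sigma = 0)
  sim0 <- simulate_series(ph0, sched, seed = 1)
  expect_true(all(sim0$series$pixels[, , 1][mask$labels > 0] == 100))
  expect_equal(sim0$series$pixels[, , 1], sim0$series$pixels[, , 8])
})

test_that("coupling dilation extends the void by the requested halo", {
  g <- fixture_grid(32L)
  mask <- square_mask(32L)
  u <- make_territory("circular", c(16, 16), list(radius_mm = 4.5), g,
                      threshold_mA = 5, coupling_dilation_vox = 1L)
  ph <- phantom(mask, list(u), noise_sigma = 0)
  sched <- plan_coarse_schedule(20, 0.1, 2)
  sim <- simulate_series(ph, sched, seed = 1)
  halo <- dilate_binary(u$territory, 1L) & !u$territory
  expect_true(all(sim$series$pixels[, , 1][halo] == 40))
  beyond <- !dilate_binary(u$territory, 1L) & mask$labels > 0L
  expect_true(all(sim$series$pixels[, , 1][beyond] == 100))
})

test_that("seeded simulations are bit-reproducible", {
  g <- fixture_grid(24L)
  mask <- square_mask(24L)
  u <- make_territory("circular", c(12, 12), list(radius_mm = 4.5), g,
                      threshold_mA = 10)
  ph <- phantom(mask, list(u), noise_sigma = 0.03)
  sched <- plan_fine_schedule(10.2, n_levels = 20L)
  a <- simulate_series(ph, sched, seed = 7)
  b <- simulate_series(ph, sched, seed = 7)
  expect_identical(a$series$pixels, b$series$pixels)
  expect_identical(a$firing, b$firing)
  c <- simulate_series(ph, sched, seed = 8)
  expect_false(identical(a$series$pixels, c$series$pixels))
})

test_that("empirical firing frequency converges to the logistic probability", {
  g <- fixture_grid(16L)
  mask <- square_mask(16L)
  u <- make_territory("circular", c(8, 8), list(radius_mm = 3), g,
                      threshold_mA = 10, firing_width_mA = 0.05)
  ph <- phantom(mask, list(u), noise_sigma = 0)
  for (cur in c(9.95, 10.0, 10.05)) {
    n <- 600L
    sched <- stim_schedule(
      tibble::tibble(dynamic_index = 0:(n - 1L), current_mA = cur,
                     level_index = 0L, repeat_index = 0:(n - 1L)),
      step_mA = 0.01)
    sim <- simulate_series(ph, sched, seed = round(cur * 100))
    p <- firing_probability(cur, 10, 0.05)
    expect_lt(abs(mean(sim$firing) - p), 4 * sqrt(p * (1 - p) / n) + 1e-9)
  }
})

test_that("width zero confines mixed outcomes to at most one level", {
  g <- fixture_grid(16L)
  mask <- square_mask(16L)
  u <- make_territory("circular", c(8, 8), list(radius_mm = 3), g,
                      threshold_mA = 10.003, firing_width_mA = 0)
  ph <- phantom(mask, list(u), noise_sigma = 0)
  sched <- plan_fine_schedule(10.2, n_levels = 40L)
  sim <- simulate_series(ph, sched, seed = 1)
  per_level <- tapply(sim$firing[1, ], sched$level_index, mean)
  mixed <- per_level > 0 & per_level < 1
  expect_lte(sum(mixed), 1L)
})

test_that("territories must stay inside one muscle", {
  g <- fixture_grid(32L)
  lab <- matrix(0L, 32, 32); lab[3:30, 3:15] <- 1L; lab[3:30, 17:30] <- 2L
  mask <- muscle_mask(lab, c("1" = "TA", "2" = "EDL"))
  u_cross <- make_territory("circular", c(16, 16), list(radius_mm = 4.5), g)
  expect_error(phantom(mask, list(u_cross)), class = "mumri_consistency_error")
  u_ok <- make_territory("circular", c(16, 9), list(radius_mm = 4.5), g)
  expect_s3_class(phantom(mask, list(u_ok)), "mumri_phantom")
})
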