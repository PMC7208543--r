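test_that("CSA is voxel count times voxel area", {
  m <- matrix(0, 8, 8); m[2:4, 2:5] <- 1  # 12 voxels
  expect_equal(compute_csa(m, c(1.5, 1.5)), 27.0)
  expect_equal(compute_csa(matrix(1, 10, 10), c(1, 1)), 100)
  expect_warning(z <- compute_csa(matrix(0, 4, 4)), class = "mumri_empty_warning")
  expect_equal(z, 0)
})

test_that("Feret diameters match hand-derived values for simple maps", {
  # a single 1.5 mm voxel: max = diagonal, min = edge
  f1 <- compute_feret(matrix(1, 1, 1), c(1.5, 1.5))
  expect_equal(f1[["feret_max_mm"]], 1.5 * sqrt(2), tolerance = 1e-12)
  expect_equal(f1[["feret_min_mm"]], 1.5, tolerance = 1e-12)
  # 1 x 4 voxel row = 6.0 x 1.5 mm rectangle
  f2 <- compute_feret(matrix(1, 1, 4), c(1.5, 1.5))
  expect_equal(f2[["feret_max_mm"]], sqrt(36 + 2.25), tolerance = 1e-12)
  expect_equal(f2[["feret_min_mm"]], 1.5, tolerance = 1e-12)
  expect_error(compute_feret(matrix(0, 3, 3)), class = "mumri_input_error")
})

test_that("calipers agree with the projection-sweep oracle on random masks", {
  withr::local_seed(101)
  for (i in 1:40) {
    m <- random_mask(8L)
    cal <- compute_feret(m, c(1.5, 1.5))
    ora <- feret_sweep_oracle(m, c(1.5, 1.5), step_deg = 0.01)
    expect_lt(abs(cal[["feret_max_mm"]] - ora[["max"]]), 1e-6)
    expect_lt(abs(cal[["feret_min_mm"]] - ora[["min"]]), 1e-6)
  }
})

test_that("Feret values are invariant to translation and 90-degree rotation", {
  withr::local_seed(7)
  m <- matrix(0, 14, 14)
  m[4:9, 5:8][which(random_mask(6L, 0.6)[, 1:4])] <- 1
  if (!any(m != 0)) m[5, 5] <- 1
  base <- compute_feret(m, c(1.5, 1.5))
  shifted <- matrix(0, 14, 14); shifted[6:11, 7:10] <- m[4:9, 5:8]
  expect_equal(compute_feret(shifted, c(1.5, 1.5)), base, tolerance = 1e-9)
  rot <- t(m[nrow(m):1, ])
  expect_equal(compute_feret(rot, c(1.5, 1.5)), base, tolerance = 1e-9)
  # diagonal of the bounding box bounds the max Feret
  bb <- range(which(m != 0, arr.ind = TRUE)[, 1])
  expect_lte(base[["feret_max_mm"]],
             1.5 * sqrt(2) * max(dim(m)))
})

test_that("the CSA never exceeds the caliper rectangle", {
  withr::local_seed(55)
  for (i in 1:25) {
    m <- random_mask(9L)
    fer <- compute_feret(m, c(1.5, 1.5))
    expect_lte(fer[["feret_min_mm"]], fer[["feret_max_mm"]] + 1e-12)
    expect_lte(compute_csa(m, c(1.5, 1.5)),
               fer[["feret_max_mm"]] * fer[["feret_min_mm"]] + 1e-9)
  }
})

test_that("component gap matches planted separations", {
  g <- fixture_grid(48L)
  u <- make_territory("split", c(24, 24), list(radius_mm = 3.2, gap_mm = 4.3), g)
  expect_lt(abs(component_gap(u$territory) - 4.3), 0.75 + 1e-9)

  # vertically separated 1-voxel gap: boundary-to-boundary 1.5 mm
  m <- matrix(0, 10, 10); m[2:3, 4:6] <- 1; m[5:6, 4:6] <- 1
  expect_equal(component_gap(m, c(1.5, 1.5)), 1.5)
  # diagonally touching components are 8-connected: single component
  m2 <- matrix(0, 6, 6); m2[2, 2] <- 1; m2[3, 3] <- 1
  expect_warning(gp <- component_gap(m2), class = "mumri_undefined_warning")
  expect_true(is.na(gp))
  # 4-adjacent blocks merged into one component likewise
  expect_warning(component_gap(matrix(1, 3, 3)),
                 class = "mumri_undefined_warning")
})

test_that("all canonical fixtures classify into their own class", {
  fixtures <- canonical_fixtures()
  got <- vapply(fixtures, function(u) classify_shape(u$territory), character(1))
  want <- vapply(fixtures, function(u) u$shape_class, character(1))
  expect_identical(got, want)
})

test_that("classification catches handmade degenerate maps", {
  # two disjoint blocks are split
  m <- matrix(0, 12, 12); m[2:4, 2:4] <- 1; m[8:10, 8:10] <- 1
  expect_equal(classify_shape(m), "split")
  # a filled disc of radius 5 voxels is circular
  g <- fixture_grid(32L)
  disc <- make_territory("circular", c(16, 16), list(radius_mm = 7.5), g)
  expect_equal(classify_shape(disc$territory), "circular")
  # half-annulus (outer 6, inner 4 voxels) is a crescent
  half <- make_territory("crescent", c(24, 24),
                         list(outer_mm = 9, inner_mm = 6, arc_deg = 180),
                         fixture_grid(48L))
  sol <- compute_solidity(half$territory)
  expect_gt(sol, 0.5); expect_lt(sol, 0.75)
  expect_equal(classify_shape(half$territory), "crescent")
})

test_that("co-firing r2 behaves on identical, independent and planted traces", {
  arr <- array(0, dim = c(4, 4, 500))
  withr::local_seed(77)
  tr <- rnorm(500, 100, 5)
  arr[1, 1, ] <- tr; arr[1, 2, ] <- tr           # identical
  arr[2, 1, ] <- rnorm(500, 100, 5)              # independent
  arr[2, 2, ] <- 100                             # constant
  arr[arr < 0] <- 0
  s <- dynamic_series(arr)
  expect_equal(cofire_r2(s, c(1, 1), c(1, 2)), 1.0)
  expect_lt(cofire_r2(s, c(1, 1), c(2, 1)), 0.05)
  expect_warning(r0 <- cofire_r2(s, c(1, 1), c(2, 2)),
                 class = "mumri_undefined_warning")
  expect_true(is.na(r0))
  expect_error(cofire_r2(s, c(1, 1), c(1, 2), window = 1:2),
               class = "mumri_input_error")
})

test_that("unit_metrics assembles a consistent one-row summary", {
  g <- fixture_grid(48L)
  u <- make_territory("split", c(24, 24), list(radius_mm = 3.2, gap_mm = 4.3), g)
  m <- unit_metrics(u$territory)
  expect_equal(nrow(m), 1L)
  expect_equal(m$shape_class, "split")
  expect_equal(m$n_components, 2L)
  expect_false(is.na(m$component_gap_mm))
  expect_lte(m$feret_min_mm, m$feret_max_mm)
  expect_lte(m$csa_mm2, m$feret_max_mm * m$feret_min_mm)
})
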