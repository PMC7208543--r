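# Shared fixture builders. Everything is generated in code; no stored data.

fixture_grid <- function(n = 48L, voxel = 1.5) {
  list(shape = c(n, n), voxel_size_mm = c(voxel, voxel))
}

square_mask <- function(n = 48L, margin = 3L, name = "TA") {
  lab <- matrix(0L, n, n)
  lab[(margin):(n - margin + 1L), (margin):(n - margin + 1L)] <- 1L
  muscle_mask(lab, c("1" = name))
}

# The 15 canonical shape fixtures: 3 instances per class, on a 48 x 48
# grid at 1.5 mm voxels.
canonical_fixtures <- function() {
  g <- fixture_grid(48L)
  list(
    make_territory("ellipse", c(24, 24), list(axes_mm = c(10, 4)), g),
    make_territory("ellipse", c(23, 25), list(axes_mm = c(12, 5), angle_deg = 20), g),
    make_territory("ellipse", c(24, 24), list(axes_mm = c(14, 6), angle_deg = 60), g),
    make_territory("circular", c(24, 24), list(radius_mm = 4.5), g),
    make_territory("circular", c(23.5, 24.5), list(radius_mm = 6), g),
    make_territory("circular", c(24, 24), list(radius_mm = 7.5), g),
    make_territory("crescent", c(24, 24), list(outer_mm = 9, inner_mm = 4.5, arc_deg = 150), g),
    make_territory("crescent", c(24, 24), list(outer_mm = 9, inner_mm = 6, arc_deg = 180), g),
    make_territory("crescent", c(24, 24), list(outer_mm = 10.5, inner_mm = 6, arc_deg = 150, angle_deg = 45), g),
    make_territory("spider", c(24, 24), list(core_mm = 3, n_arms = 4, arm_length_mm = 9, arm_width_mm = 2), g, seed = 1),
    make_territory("spider", c(24, 24), list(core_mm = 3, n_arms = 5, arm_length_mm = 10, arm_width_mm = 2), g, seed = 2),
    make_territory("spider", c(24, 24), list(core_mm = 2.5, n_arms = 4, arm_length_mm = 8, arm_width_mm = 1.8), g, seed = 3),
    make_territory("split", c(24, 24), list(radius_mm = 3.2, gap_mm = 4.3), g),
    make_territory("split", c(24, 24), list(radius_mm = 3.0, gap_mm = 1.5, angle_deg = 90), g),
    make_territory("split", c(24, 24), list(radius_mm = c(3, 4.5), gap_mm = 3, angle_deg = 45), g)
  )
}

# Recover a fixture's territory from a noisy simulation using the planted
# firing draws (isolates difference-map + threshold robustness from the
# detection stage).
noisy_recovered_territory <- function(u, mask, seed, noise_sigma = 0.03) {
  ph <- phantom(mask, list(u), noise_sigma = noise_sigma)
  sched <- plan_fine_schedule(u$threshold_mA + 0.2, n_levels = 40L)
  sim <- simulate_series(ph, sched, seed = seed)
  fv <- structure(list(states = ifelse(sim$firing[1, ] == 1L, "fired", "not_fired"),
                       alternating = TRUE, unit_id = 1L),
                  class = "firing_vector")
  dm <- build_difference_map(sim$series, fv, mask)
  threshold_map(dm, 0.5)$territory
}

# Ground-truth alternation stats from the planted firing draws.
truth_alternation <- function(firing_row, schedule) {
  fv <- structure(list(states = ifelse(firing_row == 1L, "fired", "not_fired"),
                       alternating = TRUE, unit_id = NA),
                  class = "firing_vector")
  alternation_stats(fv, schedule)
}

# Independent projection-sweep Feret oracle: corners built directly from
# voxel indices (no package geometry helpers), extent of the projection onto
# a set of directions: a dense angle grid augmented with every pairwise
# point orientation and its normal. The width function has a kink at its
# minimum, so a pure grid converges only first-order there; the pairwise
# orientations contain every hull-edge normal, which makes the sweep exact
# while keeping the computation (plain projections) independent of the
# rotating-calipers implementation.
feret_sweep_oracle <- function(territory, voxel_size_mm = c(1.5, 1.5),
                               step_deg = 0.01) {
  idx <- which(territory != 0, arr.ind = TRUE)
  wy <- voxel_size_mm[1]; wx <- voxel_size_mm[2]
  x <- c(idx[, 2] - 1, idx[, 2], idx[, 2] - 1, idx[, 2]) * wx
  y <- c(idx[, 1] - 1, idx[, 1] - 1, idx[, 1], idx[, 1]) * wy
  pts <- unique(cbind(x, y))
  th <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  if (nrow(pts) > 1L) {
    dx <- outer(pts[, 1], pts[, 1], "-")
    dy <- outer(pts[, 2], pts[, 2], "-")
    keep <- upper.tri(dx) & (dx != 0 | dy != 0)
    pair_th <- atan2(dy[keep], dx[keep])
    th <- c(th, pair_th %% pi, (pair_th + pi / 2) %% pi)
  }
  pr <- outer(pts[, 1], cos(th)) + outer(pts[, 2], sin(th))
  ext <- apply(pr, 2, max) - apply(pr, 2, min)
  c(max = max(ext), min = min(ext))
}

# Random small binary mask (possibly multiple components) for oracle tests.
random_mask <- function(n = 10L, p = 0.35) {
  m <- matrix(runif(n * n) < p, n, n)
  if (!any(m)) m[sample(n * n, 1L)] <- TRUE
  m
}
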