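# Shared noisy single-unit simulation for several blocks below.
single_unit_sim <- function(seed, width = 0.05, noise = 0.03, n = 32L,
                            threshold = 10, n_levels = 90L, i_max = 10.4) {
  g <- fixture_grid(n)
  mask <- square_mask(n)
  u <- make_territory("ellipse", c(n / 2, n / 2), list(axes_mm = c(9, 5)), g,
                      threshold_mA = threshold, firing_width_mA = width)
  ph <- phantom(mask, list(u), noise_sigma = noise)
  sched <- plan_fine_schedule(i_max, n_levels = n_levels)
  sim <- simulate_series(ph, sched, seed = seed)
  list(sim = sim, unit = u, mask = mask, sched = sched)
}

test_that("zero-noise candidates recover the planted territory exactly", {
  x <- single_unit_sim(seed = 1, noise = 0)
  cand <- detect_candidate_voxels(x$sim$series, x$mask, x$sched)
  expect_identical(cand$candidate_mask, x$unit$territory)
})

test_that("pure-noise series yields no candidates or units", {
  mask <- square_mask(32L)
  ph <- phantom(mask, list(), noise_sigma = 0.03)
  sched <- plan_fine_schedule(10.4, n_levels = 30L)
  sim <- simulate_series(ph, sched, seed = 5)
  un <- extract_units(sim$series, mask, sched)
  expect_length(un$units, 0L)
})

test_that("candidates cover the planted unit without leaking outside", {
  hits <- 0L
  for (i in 1:10) {
    x <- single_unit_sim(seed = 400 + i)
    cand <- detect_candidate_voxels(x$sim$series, x$mask, x$sched)
    dil <- dilate_binary(x$unit$territory, 1L)
    cover <- sum(cand$candidate_mask & x$unit$territory) / sum(x$unit$territory)
    leak <- sum(cand$candidate_mask & !dil)
    if (cover >= 0.8 && leak == 0L) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("frame grouping matches the ground-truth firing draws", {
  # zero noise: exact recovery
  x0 <- single_unit_sim(seed = 2, noise = 0)
  seed_region <- which(x0$unit$territory, arr.ind = TRUE)
  fv0 <- group_frames(x0$sim$series, seed_region, x0$sched)
  expect_true(fv0$alternating)
  expect_identical(fv0$states == "fired", x0$sim$firing[1, ] == 1L)

  # noise 0.03: >= 99% agreement across runs
  agree <- vapply(1:10, function(i) {
    x <- single_unit_sim(seed = 500 + i)
    fv <- group_frames(x$sim$series,
                       which(x$unit$territory, arr.ind = TRUE), x$sched)
    mean((fv$states == "fired") == (x$sim$firing[1, ] == 1L))
  }, numeric(1))
  expect_true(all(agree >= 0.99))
})

test_that("a region that never fires gives the no-alternation signal", {
  mask <- square_mask(24L)
  ph <- phantom(mask, list(), noise_sigma = 0.03)
  sched <- plan_fine_schedule(10.4, n_levels = 20L)
  sim <- simulate_series(ph, sched, seed = 9)
  expect_warning(
    fv <- group_frames(sim$series, cbind(12, 12), sched),
    class = "mumri_no_alternation")
  expect_false(fv$alternating)
})

test_that("co-firing clustering separates units and joins identical voxels", {
  g <- fixture_grid(48L)
  mask <- square_mask(48L)
  u1 <- make_territory("circular", c(14, 14), list(radius_mm = 5), g,
                       threshold_mA = 10.3, firing_width_mA = 0.05)
  u2 <- make_territory("circular", c(34, 34), list(radius_mm = 5), g,
                       threshold_mA = 10.0, firing_width_mA = 0.05)
  ph <- phantom(mask, list(u1, u2), noise_sigma = 0.03)
  sched <- plan_fine_schedule(10.55, n_levels = 90L)
  sim <- simulate_series(ph, sched, seed = 21)
  cand <- detect_candidate_voxels(sim$series, mask, sched)
  groups <- cluster_into_units(cand)
  expect_length(groups, 2L)
  in1 <- vapply(groups, function(gm) mean(u1$territory[gm]), numeric(1))
  expect_setequal(round(sort(in1)), c(0, 1))

  # identical firing vectors always join (r^2 = 1)
  cand2 <- structure(list(
    voxels = cbind(c(5L, 6L), c(5L, 5L)),
    states = rbind(c(TRUE, FALSE, TRUE, FALSE), c(TRUE, FALSE, TRUE, FALSE)),
    window = 1:4, candidate_mask = NULL), class = "mumri_candidates")
  expect_length(cluster_into_units(cand2, min_unit_voxels = 1L), 1L)
})

test_that("difference maps subtract group means within the mask", {
  nd <- 6L
  arr <- array(100, dim = c(12, 12, nd))
  terr <- matrix(FALSE, 12, 12); terr[4:6, 4:6] <- TRUE
  for (t in c(2, 4, 6)) arr[, , t][terr] <- 30
  s <- dynamic_series(arr)
  fv <- structure(list(states = rep(c("not_fired", "fired"), 3),
                       alternating = TRUE, unit_id = 1),
                  class = "firing_vector")
  dm <- build_difference_map(s, fv)
  expect_true(all(dm[terr] == 70))
  expect_true(all(dm[!terr] == 0))

  # identical groups give an all-zero map
  fv2 <- fv; arr2 <- array(55, dim = c(12, 12, nd))
  dm2 <- build_difference_map(dynamic_series(arr2), fv2)
  expect_true(all(dm2 == 0))

  # linearity: scaling the series scales the map
  s3 <- dynamic_series(arr * 2.5)
  expect_equal(build_difference_map(s3, fv), dm * 2.5)

  # one empty group is an input error
  fv3 <- fv; fv3$states <- rep("fired", nd)
  expect_error(build_difference_map(s, fv3), class = "mumri_input_error")
})

test_that("threshold_map keeps voxels at or above the normalised fraction", {
  m <- matrix(0, 10, 10)
  m[3, 3] <- 200; m[3, 4] <- 150; m[4, 3] <- 100; m[4, 4] <- 99; m[8, 8] <- 50
  tm <- threshold_map(m, 0.5, min_unit_voxels = 1L)
  expect_identical(which(tm$territory), which(m >= 100))
  expect_equal(max(tm$normalized_map), 1)

  # fraction 1 keeps only the argmax
  tm1 <- threshold_map(m, 1, min_unit_voxels = 1L)
  expect_identical(which(tm1$territory), which(m == 200))

  # uniform positive map keeps everything
  tmu <- threshold_map(matrix(5, 4, 4), 0.5, min_unit_voxels = 1L)
  expect_true(all(tmu$territory))

  # negatives are clipped before normalisation
  mneg <- m; mneg[1, 1] <- -300
  tmn <- threshold_map(mneg, 0.5, min_unit_voxels = 1L)
  expect_equal(max(tmn$normalized_map), 1)
  expect_true(all(tmn$normalized_map >= 0))
  expect_false(tmn$territory[1, 1])

  # non-positive map signals no activity
  expect_warning(tm0 <- threshold_map(matrix(-1, 4, 4), 0.5),
                 class = "mumri_no_activity")
  expect_null(tm0$territory)

  # small components are dropped
  tms <- threshold_map(m, 0.2, min_unit_voxels = 3L)
  expect_false(tms$territory[8, 8])
})

test_that("territories shrink monotonically as the fraction rises", {
  set.seed(30)
  m <- matrix(pmax(rnorm(400, 50, 30), 0), 20, 20)
  prev <- NULL
  for (f in c(0.2, 0.4, 0.6, 0.8, 1.0)) {
    terr <- threshold_map(m, f, min_unit_voxels = 1L)$territory
    if (!is.null(prev)) expect_true(all(prev | !terr))  # terr subset of prev
    prev <- terr
  }
})

test_that("threshold sweep reports monotone CSA and matches threshold_map", {
  x <- single_unit_sim(seed = 3)
  fv <- group_frames(x$sim$series, which(x$unit$territory, arr.ind = TRUE),
                     x$sched)
  dm <- build_difference_map(x$sim$series, fv, x$mask)
  sw <- threshold_sweep(dm, c(0.3, 0.5, 0.7))
  expect_true(all(diff(sw$csa_mm2) <= 0))
  tm <- threshold_map(dm, 0.5)
  expect_equal(sw$csa_mm2[sw$fraction == 0.5],
               compute_csa(tm$territory, c(1.5, 1.5)))
  # the best fraction of the sweep recovers the planted CSA closely
  sw2 <- threshold_sweep(dm, seq(0.1, 0.9, 0.1))
  planted <- compute_csa(x$unit$territory, c(1.5, 1.5))
  best_csa <- sw2$csa_mm2[which.min(abs(sw2$csa_mm2 - planted))]
  expect_lte(abs(best_csa - planted), 3 * 2.25)
})

test_that("alternation statistics summarise mixed levels", {
  # constructed staircase: levels 5.00..5.40, mixed only at 5.10..5.30
  sched <- plan_fine_schedule(5.40, n_levels = 41L)
  fired <- ifelse(sched$current_mA > 5.305, TRUE,
                  ifelse(sched$current_mA < 5.095, FALSE,
                         sched$repeat_index %in% c(0, 2)))
  fv <- structure(list(states = ifelse(fired, "fired", "not_fired"),
                       alternating = TRUE, unit_id = 1),
                  class = "firing_vector")
  st <- alternation_stats(fv, sched)
  expect_equal(st$alternation_range_mA, 0.20)
  expect_equal(st$activation_threshold_mA, 5.10)
  expect_false(st$censored)

  # deterministic unit: range at most one step
  fired2 <- sched$current_mA > 5.20
  fv2 <- fv; fv2$states <- ifelse(fired2, "fired", "not_fired")
  st2 <- alternation_stats(fv2, sched)
  expect_lte(st2$alternation_range_mA, 0.01 + 1e-12)

  # fires at every level: right-censored
  fv3 <- fv; fv3$states[] <- "fired"; fv3$states[c(1, 7)] <- "not_fired"
  st3 <- alternation_stats(fv3, sched)
  expect_true(st3$censored)
})

test_that("extracted alternation range grows with the planted logistic width", {
  widths <- seq(0.01, 0.1, length.out = 12)
  ranges <- vapply(seq_along(widths), function(i) {
    x <- single_unit_sim(seed = 700 + i, width = widths[i], n_levels = 120L,
                         i_max = 10.6)
    un <- extract_units(x$sim$series, x$mask, x$sched)
    if (length(un$units) != 1L) return(NA_real_)
    un$metrics$alternation_range_mA
  }, numeric(1))
  expect_true(all(is.finite(ranges)))
  expect_gt(cor(widths, ranges), 0.8)
})

test_that("same-unit co-firing exceeds cross-unit co-firing", {
  g <- fixture_grid(48L)
  mask <- square_mask(48L)
  wins <- 0L
  for (i in 1:10) {
    u1 <- make_territory("circular", c(14, 14), list(radius_mm = 5), g,
                         threshold_mA = 10.3, firing_width_mA = 0.05)
    u2 <- make_territory("circular", c(34, 34), list(radius_mm = 5), g,
                         threshold_mA = 10.0, firing_width_mA = 0.05)
    ph <- phantom(mask, list(u1, u2), noise_sigma = 0.03)
    sched <- plan_fine_schedule(10.55, n_levels = 90L)
    sim <- simulate_series(ph, sched, seed = 800 + i)
    r2_same <- cofire_r2(sim$series, c(14, 14), c(13, 15))
    r2_diff <- cofire_r2(sim$series, c(14, 14), c(34, 34))
    if (isTRUE(r2_same > r2_diff)) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})
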