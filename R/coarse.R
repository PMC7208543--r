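#' ROI current-intensity profile from a coarse ramp
#'
#' Averages the signal over an ROI (one muscle label) for every current
#' level of the schedule. With the coarse ramp's one dynamic per level this
#' is the raw ROI trace against current.
#'
#' @param series A [dynamic_series()].
#' @param mask A [muscle_mask()].
#' @param roi_label Positive integer label selecting the ROI muscle.
#' @param schedule A [stim_schedule()] covering all dynamics.
#' @return A tibble of class `mumri_profile` with columns `level_index`,
#'   `current_mA`, `mean_intensity`, `n_dynamics`, currents strictly
#'   increasing; attribute `roi_label`.
#' @export
roi_profile <- function(series, mask, roi_label, schedule) {
  check_consistency(series, mask, schedule)
  roi <- mask$labels == as.integer(roi_label)
  if (!any(roi)) stop_input(sprintf("ROI label %s is empty or absent", roi_label))
  nd <- n_dynamics(series)
  flat <- matrix(series$pixels, nrow = prod(dim(series$pixels)[1:2]), ncol = nd)
  trace <- colMeans(flat[as.vector(roi), , drop = FALSE])
  prof <- tibble(level_index = schedule$level_index,
                 current_mA = schedule$current_mA,
                 intensity = trace) |>
    dplyr::group_by(.data$level_index, .data$current_mA) |>
    dplyr::summarise(mean_intensity = mean(.data$intensity),
                     n_dynamics = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$current_mA)
  structure(prof, roi_label = as.integer(roi_label),
            class = c("mumri_profile", class(prof)))
}

#' Simulate a coarse-ramp recruitment profile
#'
#' Generates the ROI intensity-current profile of an ascending coarse ramp
#' with a known activation level: flat at `baseline` until the activation
#' current, then declining linearly as progressively more units recruit,
#' reaching `final_fraction` of baseline at the end of the ramp (the ramp is
#' run until clear contrast, i.e. a pronounced signal drop). Gaussian noise
#' of `noise_sigma * baseline` is added per level.
#'
#' @param activation_level 1-based index of the first active level.
#' @param n_levels Number of ramp levels; default 60.
#' @param start_mA,step_mA Ramp start and step; defaults 8 and 0.1 mA.
#' @param baseline Baseline ROI intensity; default 100.
#' @param final_fraction ROI intensity at ramp end as a fraction of
#'   baseline; default 0.5.
#' @param noise_sigma Noise SD as a fraction of baseline; default 0.02.
#' @param seed Integer seed.
#' @return A `mumri_profile` tibble as from [roi_profile()].
#' @export
simulate_recruitment_profile <- function(activation_level, n_levels = 60L,
                                         start_mA = 8, step_mA = 0.1,
                                         baseline = 100, final_fraction = 0.5,
                                         noise_sigma = 0.02, seed = 1L) {
  if (activation_level < 1L || activation_level >= n_levels) {
    stop_parameter("`activation_level` must lie inside the ramp")
  }
  x <- start_mA + step_mA * (seq_len(n_levels) - 1L)
  post <- n_levels - activation_level
  slope <- baseline * (1 - final_fraction) / post
  y <- c(rep(baseline, activation_level),
         baseline - slope * seq_len(post))
  y <- y + withr::with_seed(seed, rnorm(n_levels, sd = noise_sigma * baseline))
  prof <- tibble(level_index = seq_len(n_levels) - 1L, current_mA = x,
                 mean_intensity = y, n_dynamics = 1L)
  structure(prof, roi_label = NA_integer_,
            class = c("mumri_profile", class(prof)))
}

#' Detect the inflection point of a recruitment profile
#'
#' Finds the current at which muscle activity first becomes visible in the
#' ROI profile: the breakpoint of a continuous two-segment piecewise-linear
#' least-squares fit, snapped to the nearest measured current level. Below
#' the first recruitment the ROI intensity does not depend on the current,
#' so the first segment is constrained to a constant baseline; the second
#' segment is a descending line joined continuously at the breakpoint (an
#' unconstrained first segment systematically anticipates the knee of an
#' accelerating decline). The breakpoint is accepted only when the fitted
#' decline of the second segment over its span exceeds `margin` times the
#' residual SD of the first segment (so the decision is invariant to affine
#' rescaling of the intensities); otherwise the profile is declared to have
#' no inflection.
#'
#' @param profile A [roi_profile()] tibble (or any data frame with
#'   `current_mA` and `mean_intensity`), at least 4 points.
#' @param margin Significance margin for the slope change, default 3.
#' @return An object of class `mumri_inflection`: list with
#'   `inflection_mA` (`NA` if no inflection), `significant`, `slope1`,
#'   `slope2`, `rss`, `drop`, `noise_sd`, and the input `profile` with a
#'   `fitted` column. Use [tidy()] / [glance()] for tabular summaries.
#' @examples
#' prof <- tibble::tibble(current_mA = seq(8, 12, 0.5),
#'                        mean_intensity = c(rep(100, 5), 90, 80, 70, 60))
#' detect_inflection(prof)$inflection_mA  # 10.0
#' @export
detect_inflection <- function(profile, margin = 3) {
  x <- profile$current_mA
  y <- profile$mean_intensity
  n <- length(x)
  if (n < 4L) stop_input("inflection detection needs at least 4 profile points")
  if (is.unsorted(x, strictly = TRUE)) stop_input("profile currents must be strictly increasing")

  # exhaustive search over measured breakpoint levels; per breakpoint the
  # constant-then-line model has a 2x2 closed-form least-squares solution
  best <- NULL
  fallback <- NULL
  for (k in 2:(n - 1L)) {
    b <- x[k]
    u <- pmax(0, x - b)
    su <- sum(u); su2 <- sum(u^2)
    A <- rbind(c(n, su), c(su, su2))
    rhs <- c(sum(y), sum(u * y))
    theta <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (is.null(theta)) next
    fitted <- theta[1] + theta[2] * u
    rss <- sum((y - fitted)^2)
    cand <- list(k = k, b = b, level = theta[1], slope = theta[2],
                 rss = rss, fitted = fitted)
    if (is.null(fallback) || rss < fallback$rss) fallback <- cand
    if (theta[2] < 0 && (is.null(best) || rss < best$rss)) best <- cand
  }
  if (is.null(best)) best <- fallback
  slope1 <- 0
  slope2 <- unname(best$slope)
  seg1 <- x <= best$b
  # noise scale: residual SD of the first segment around its baseline
  res1 <- y[seg1] - best$level
  noise_sd <- sd(res1)
  if (!is.finite(noise_sd)) noise_sd <- 0
  drop <- -slope2 * (x[n] - best$b)
  significant <- slope2 < 0 && drop > margin * noise_sd
  out <- profile
  out$fitted <- best$fitted
  structure(
    list(inflection_mA = if (significant) best$b else NA_real_,
         significant = significant, slope1 = slope1, slope2 = slope2,
         rss = best$rss, drop = drop, noise_sd = noise_sd, margin = margin,
         profile = out),
    class = "mumri_inflection")
}

#' @export
print.mumri_inflection <- function(x, ...) {
  if (x$significant) {
    cat(sprintf("<mumri_inflection> inflection at %.3g mA (slopes %.3g -> %.3g)\n",
                x$inflection_mA, x$slope1, x$slope2))
  } else {
    cat("<mumri_inflection> no inflection (slope change below margin)\n")
  }
  invisible(x)
}

#' @export
tidy.mumri_inflection <- function(x, ...) {
  tibble(term = c("inflection_mA", "slope1", "slope2"),
         estimate = c(x$inflection_mA, x$slope1, x$slope2))
}

#' @export
glance.mumri_inflection <- function(x, ...) {
  tibble(inflection_mA = x$inflection_mA, significant = x$significant,
         slope1 = x$slope1, slope2 = x$slope2, rss = x$rss,
         drop = x$drop, noise_sd = x$noise_sd)
}

#' Fine-scan starting current
#'
#' The fine-grain staircase starts five coarse current steps above the
#' inflection point.
#'
#' @param inflection_mA Inflection current (mA).
#' @param step_mA Coarse ramp step (mA), > 0.
#' @param n_steps Number of steps above the inflection, default 5.
#' @return Starting current `I_MAX` in mA.
#' @examples
#' compute_i_max(11.5, 0.1)  # 12.0
#' @export
compute_i_max <- function(inflection_mA, step_mA, n_steps = 5L) {
  if (!is.finite(step_mA) || step_mA <= 0) stop_parameter("`step_mA` must be > 0")
  inflection_mA + n_steps * step_mA
}
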