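# Alternation-based motor-unit extraction: candidate voxels -> co-firing
# clusters -> frame grouping -> difference maps -> thresholded territories.

# Exact 1D two-means partition of a numeric vector. Returns the cluster
# boundary (midpoint of the two cluster means), the cluster means, and a
# separation statistic (gap over pooled within-cluster SD; Inf for a clean
# two-valued split).
two_means_split <- function(x) {
  n <- length(x)
  xs <- sort(x)
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  k <- seq_len(n - 1L)
  ss_lo <- cs2[k] - cs[k]^2 / k
  nk <- n - k
  ss_hi <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / nk
  tot <- ss_lo + ss_hi
  kbest <- which.min(tot)
  mu_lo <- cs[kbest] / kbest
  mu_hi <- (cs[n] - cs[kbest]) / (n - kbest)
  pooled <- if (n > 2L) sqrt(max(tot[kbest], 0) / (n - 2L)) else 0
  separation <- if (pooled > 0) (mu_hi - mu_lo) / pooled
    else if (mu_hi > mu_lo) Inf else 0
  list(boundary = (mu_lo + mu_hi) / 2, mu_lo = mu_lo, mu_hi = mu_hi,
       n_lo = kbest, n_hi = n - kbest, separation = separation,
       drop = if (mu_hi > 0) (mu_hi - mu_lo) / mu_hi else 0)
}

#' Detect candidate alternating voxels
#'
#' Scans every masked voxel's time course over the analysis window for
#' bimodality: an exact two-means split must separate a low (void) and a
#' high (baseline) intensity cluster by at least `separation_min` pooled
#' within-cluster SDs, with a relative signal drop of at least `min_drop`,
#' and the low state must recur on at least `min_events` dynamics (and the
#' high state likewise). Voxels passing all tests are candidates for motor
#' unit territories.
#'
#' @param series A [dynamic_series()].
#' @param mask A [muscle_mask()].
#' @param schedule A [stim_schedule()].
#' @param window Integer vector of 1-based dynamic indices to analyse;
#'   default all.
#' @param separation_min Minimum two-cluster separation statistic; default 5.
#' @param min_drop Minimum relative intensity drop `(hi - lo) / hi`;
#'   default 0.15.
#' @param min_events Minimum dynamics in each state; default 3.
#' @return A list of class `mumri_candidates`: `voxels` (integer matrix with
#'   columns row, col), `states` (logical candidates x window matrix, TRUE =
#'   low/fired), `window`, `candidate_mask` (logical image). The voxel set
#'   may be empty.
#' @export
detect_candidate_voxels <- function(series, mask, schedule, window = NULL,
                                    separation_min = 5, min_drop = 0.15,
                                    min_events = 3L) {
  check_consistency(series, mask, schedule)
  window <- window %||% seq_len(n_dynamics(series))
  idx <- which(mask$labels > 0L, arr.ind = TRUE)
  nr <- nrow(series$pixels)
  keep <- logical(nrow(idx))
  states <- matrix(FALSE, nrow(idx), length(window))
  for (i in seq_len(nrow(idx))) {
    tr <- series$pixels[idx[i, 1], idx[i, 2], window]
    sp <- two_means_split(tr)
    if (sp$separation >= separation_min && sp$drop >= min_drop &&
        sp$n_lo >= min_events && sp$n_hi >= min_events) {
      keep[i] <- TRUE
      states[i, ] <- tr <= sp$boundary
    }
  }
  voxels <- idx[keep, , drop = FALSE]
  cand_mask <- matrix(FALSE, nr, ncol(series$pixels))
  cand_mask[voxels] <- TRUE
  structure(list(voxels = voxels, states = states[keep, , drop = FALSE],
                 window = window, candidate_mask = cand_mask),
            class = "mumri_candidates")
}

#' Group candidate voxels into putative units by co-firing
#'
#' Builds a co-firing graph over candidate voxels: an edge joins two voxels
#' when the squared Pearson correlation of their binary firing vectors is at
#' least `cofire_r2`. Connected groups of the graph (transitive closure of
#' the relation) are putative motor units; groups smaller than
#' `min_unit_voxels` are dropped.
#'
#' @param candidates A [detect_candidate_voxels()] result.
#' @param cofire_r2 Co-firing criterion on r^2; default 0.6.
#' @param min_unit_voxels Minimum voxels per unit; default 3.
#' @return List of integer matrices (row, col), one per putative unit,
#'   ordered by decreasing size.
#' @export
cluster_into_units <- function(candidates, cofire_r2 = 0.6,
                               min_unit_voxels = 3L) {
  nv <- nrow(candidates$voxels)
  if (nv == 0L) return(list())
  if (nv == 1L) {
    grp <- list(candidates$voxels)
  } else {
    s <- candidates$states * 1
    r2 <- suppressWarnings(cor(t(s)))^2
    r2[!is.finite(r2)] <- 0
    adj <- r2 >= cofire_r2
    diag(adj) <- TRUE
    comp <- integer(nv)
    k <- 0L
    for (v in seq_len(nv)) {
      if (comp[v] != 0L) next
      k <- k + 1L
      queue <- v
      comp[v] <- k
      while (length(queue)) {
        u <- queue[[1]]
        queue <- queue[-1]
        nb <- which(adj[u, ] & comp == 0L)
        comp[nb] <- k
        queue <- c(queue, nb)
      }
    }
    grp <- lapply(seq_len(k), function(i) {
      candidates$voxels[comp == i, , drop = FALSE]
    })
  }
  grp <- grp[vapply(grp, nrow, 1L) >= min_unit_voxels]
  grp[order(vapply(grp, nrow, 1L), decreasing = TRUE)]
}

#' Group dynamics into fired / not-fired frames
#'
#' Automates the manual step of sorting dynamic images into frames with and
#' without a signal void: the mean intensity of the seed region is two-means
#' partitioned, the lower cluster being the fired frames. Dynamics outside
#' the analysis window are marked `excluded`. When the two clusters are not
#' separable (separation below `separation_min` or relative drop below
#' `min_drop`) the region shows no alternation and the returned object has
#' `alternating = FALSE`.
#'
#' @param series A [dynamic_series()].
#' @param seed_region Integer matrix (row, col) of seed voxels, non-empty.
#' @param schedule A [stim_schedule()] (kept with the result for downstream
#'   alternation statistics).
#' @param window 1-based dynamic indices to analyse; default all.
#' @param separation_min,min_drop Degeneracy criteria as in
#'   [detect_candidate_voxels()].
#' @param unit_id Optional identifier stored on the result.
#' @return An object of class `firing_vector`: list with `states` (character
#'   per dynamic: `"fired"`, `"not_fired"`, `"excluded"`), `alternating`,
#'   `separation`, `boundary`, `unit_id`.
#' @export
group_frames <- function(series, seed_region, schedule = NULL, window = NULL,
                         separation_min = 5, min_drop = 0.15, unit_id = NA) {
  stopifnot(inherits(series, "dynamic_series"))
  seed_region <- rbind(seed_region)
  if (nrow(seed_region) == 0L) stop_input("seed region is empty")
  window <- window %||% seq_len(n_dynamics(series))
  nd <- n_dynamics(series)
  flat <- matrix(series$pixels, nrow = prod(dim(series$pixels)[1:2]), ncol = nd)
  lin <- (seed_region[, 2] - 1L) * dim(series$pixels)[1] + seed_region[, 1]
  trace <- colMeans(flat[lin, , drop = FALSE])
  sp <- two_means_split(trace[window])
  alternating <- sp$separation >= separation_min && sp$drop >= min_drop
  states <- rep("excluded", nd)
  if (alternating) {
    states[window] <- ifelse(trace[window] <= sp$boundary, "fired", "not_fired")
  } else {
    rlang::warn("seed region shows no alternation",
                class = "mumri_no_alternation")
    states[window] <- "not_fired"
  }
  structure(list(states = states, alternating = alternating,
                 separation = sp$separation, boundary = sp$boundary,
                 trace = trace, unit_id = unit_id),
            class = "firing_vector")
}

#' @export
print.firing_vector <- function(x, ...) {
  cat(sprintf("<firing_vector> %d dynamics: %d fired, %d not fired, %d excluded%s\n",
              length(x$states), sum(x$states == "fired"),
              sum(x$states == "not_fired"), sum(x$states == "excluded"),
              if (x$alternating) "" else " (no alternation)"))
  invisible(x)
}

#' Motor-unit difference map
#'
#' Averages the not-fired and fired frames separately and subtracts them
#' (`mean(not fired) - mean(fired)`), revealing the territory as positive
#' values. With a mask given, the map is zeroed outside the muscles.
#'
#' @param series A [dynamic_series()].
#' @param firing A [group_frames()] result (both states must be non-empty).
#' @param mask Optional [muscle_mask()].
#' @return Numeric matrix difference map.
#' @export
build_difference_map <- function(series, firing, mask = NULL) {
  stopifnot(inherits(series, "dynamic_series"), inherits(firing, "firing_vector"))
  fired <- which(firing$states == "fired")
  quiet <- which(firing$states == "not_fired")
  if (length(fired) == 0L || length(quiet) == 0L) {
    stop_input("difference map needs at least one fired and one not-fired dynamic")
  }
  m_quiet <- apply(series$pixels[, , quiet, drop = FALSE], c(1, 2), mean)
  m_fired <- apply(series$pixels[, , fired, drop = FALSE], c(1, 2), mean)
  dm <- m_quiet - m_fired
  if (!is.null(mask)) dm[mask$labels == 0L] <- 0
  dm
}

#' Threshold a difference map into a binary territory
#'
#' The map is normalised to its maximum (negatives clipped to 0) and voxels
#' at or above `fraction` of the maximum are retained; connected components
#' (8-connectivity) smaller than `min_unit_voxels` are dropped. The default
#' fraction of 0.5 removes interference from nearby units while preserving
#' the territory.
#'
#' @param difference_map Numeric matrix from [build_difference_map()].
#' @param fraction Threshold fraction in (0, 1]; default 0.5.
#' @param min_unit_voxels Minimum component size; default 3.
#' @return List with `normalized_map` (in `[0, 1]`) and `territory` (logical
#'   matrix), or both `NULL` (with a `mumri_no_activity` warning) when the
#'   map has no positive values.
#' @export
threshold_map <- function(difference_map, fraction = 0.5, min_unit_voxels = 3L) {
  if (fraction <= 0 || fraction > 1) stop_parameter("`fraction` must be in (0, 1]")
  mx <- max(difference_map)
  if (!is.finite(mx) || mx <= 0) {
    rlang::warn("difference map has no positive values: no activity",
                class = "mumri_no_activity")
    return(list(normalized_map = NULL, territory = NULL))
  }
  norm <- pmax(difference_map, 0) / mx
  terr <- norm >= fraction
  if (any(terr)) {
    lab <- label_components(terr, 8L)
    sizes <- tabulate(lab[lab > 0L])
    drop <- which(sizes < min_unit_voxels)
    if (length(drop)) terr[lab %in% drop] <- FALSE
  }
  list(normalized_map = norm, territory = terr)
}

#' Sweep the threshold fraction
#'
#' Recomputes the territory and its morphometrics for a list of threshold
#' fractions, for threshold-choice QC.
#'
#' @inheritParams threshold_map
#' @param fractions Numeric vector of fractions in (0, 1].
#' @param voxel_size_mm In-plane voxel size for the metrics.
#' @return A tibble with one row per fraction: `fraction`, `csa_mm2`,
#'   `feret_max_mm`, `feret_min_mm`, `n_voxels`, `n_components`.
#' @export
threshold_sweep <- function(difference_map, fractions,
                            voxel_size_mm = c(1.5, 1.5),
                            min_unit_voxels = 3L) {
  purrr::map_dfr(fractions, function(f) {
    tm <- threshold_map(difference_map, f, min_unit_voxels)
    terr <- tm$territory
    if (is.null(terr) || !any(terr)) {
      return(tibble(fraction = f, csa_mm2 = 0, feret_max_mm = NA_real_,
                    feret_min_mm = NA_real_, n_voxels = 0L, n_components = 0L))
    }
    fer <- compute_feret(terr, voxel_size_mm)
    tibble(fraction = f,
           csa_mm2 = compute_csa(terr, voxel_size_mm),
           feret_max_mm = fer[[1]], feret_min_mm = fer[[2]],
           n_voxels = sum(terr),
           n_components = max(label_components(terr, 8L)))
  })
}

#' Activation threshold and alternation range of a unit
#'
#' Summarises a firing vector against the stimulation schedule. The
#' activation threshold is the lowest current level with at least one fired
#' repeat. Levels with mixed outcomes (some repeats fired, some not) form
#' the alternation zone; the alternation range is the current span of that
#' zone (0 when no level is mixed). When the unit fires at every measured
#' level the range is right-censored.
#'
#' @param firing A [group_frames()] result.
#' @param schedule A [stim_schedule()] with one entry per dynamic.
#' @return A one-row tibble: `activation_threshold_mA`,
#'   `alternation_range_mA`, `n_mixed_levels`, `censored`. The per-level
#'   summary is attached as attribute `per_level`.
#' @export
alternation_stats <- function(firing, schedule) {
  stopifnot(inherits(firing, "firing_vector"))
  if (length(firing$states) != nrow(schedule)) {
    stop_consistency("firing vector and schedule lengths differ")
  }
  if (!any(firing$states == "fired")) {
    stop_input("firing vector has no fired dynamics")
  }
  lv <- tibble(current_mA = schedule$current_mA,
               level_index = schedule$level_index,
               state = firing$states) |>
    dplyr::filter(.data$state != "excluded") |>
    dplyr::group_by(.data$level_index, .data$current_mA) |>
    dplyr::summarise(n_fired = sum(.data$state == "fired"),
                     n_not = sum(.data$state == "not_fired"),
                     .groups = "drop") |>
    dplyr::arrange(.data$current_mA)
  active <- lv$n_fired >= 1L
  mixed <- lv$n_fired >= 1L & lv$n_not >= 1L
  threshold <- min(lv$current_mA[active])
  range_mA <- if (any(mixed)) {
    max(lv$current_mA[mixed]) - min(lv$current_mA[mixed])
  } else 0
  censored <- all(active)
  out <- tibble(activation_threshold_mA = threshold,
                alternation_range_mA = range_mA,
                n_mixed_levels = sum(mixed),
                censored = censored)
  attr(out, "per_level") <- lv
  out
}

# Dynamics (1-based) belonging to the unit's own alternation zone: the
# levels with mixed outcomes. Restricting the difference map to this zone
# keeps other units' contributions constant within the averaged groups so
# they cancel; outside the zone a unit with a different threshold changes
# state together with the current and would bleed into the map.
alternation_zone_dynamics <- function(firing, schedule) {
  lv <- attr(alternation_stats(firing, schedule), "per_level")
  mixed <- lv$level_index[lv$n_fired >= 1L & lv$n_not >= 1L]
  which(schedule$level_index %in% mixed)
}

#' Extract motor units from a fine-grain series
#'
#' Full extraction pipeline: candidate alternating voxels are detected,
#' grouped into putative units by co-firing correlation, each unit's frames
#' are grouped into fired / not-fired, difference maps built, thresholded
#' into territories, and per-unit morphometrics and alternation statistics
#' computed. Units are returned in decreasing order of activation threshold.
#'
#' Each unit's difference map is averaged only over the dynamics of its own
#' alternation zone (the current levels where its outcomes are mixed): there
#' the fired and not-fired groups sample the same currents, so any other
#' unit is in a constant state within the comparison and cancels in the
#' subtraction. When the zone holds too few frames of either kind the whole
#' window is used instead.
#'
#' @inheritParams detect_candidate_voxels
#' @param threshold_fraction Difference-map threshold fraction; default 0.5.
#' @param cofire_r2 Co-firing r^2 criterion; default 0.6.
#' @param min_unit_voxels Minimum voxels per unit; default 3.
#' @return An object of class `mumri_units`: list with `units` (per-unit
#'   list: `firing`, `difference_map`, `normalized_map`, `territory`,
#'   `seed_region`, `metrics`) and `metrics` (tibble, one row per unit with
#'   morphometrics and alternation statistics).
#' @export
extract_units <- function(series, mask, schedule, window = NULL,
                          threshold_fraction = 0.5, cofire_r2 = 0.6,
                          min_unit_voxels = 3L, separation_min = 5,
                          min_drop = 0.15, min_events = 3L) {
  cand <- detect_candidate_voxels(series, mask, schedule, window,
                                  separation_min, min_drop, min_events)
  groups <- cluster_into_units(cand, cofire_r2, min_unit_voxels)
  units <- list()
  for (g in groups) {
    fv <- withCallingHandlers(
      group_frames(series, g, schedule, window = cand$window,
                   separation_min = separation_min, min_drop = min_drop,
                   unit_id = length(units) + 1L),
      mumri_no_alternation = function(w) invokeRestart("muffleWarning"))
    if (!fv$alternating) next
    alt <- alternation_stats(fv, schedule)
    zone <- alternation_zone_dynamics(fv, schedule)
    fvz <- fv
    if (length(zone)) {
      fvz$states[setdiff(seq_along(fv$states), zone)] <- "excluded"
    }
    if (sum(fvz$states == "fired") < 2L || sum(fvz$states == "not_fired") < 2L) {
      fvz <- fv
    }
    dm <- build_difference_map(series, fvz, mask)
    tm <- withCallingHandlers(
      threshold_map(dm, threshold_fraction, min_unit_voxels),
      mumri_no_activity = function(w) invokeRestart("muffleWarning"))
    if (is.null(tm$territory) || !any(tm$territory)) next
    met <- unit_metrics(tm$territory, series$voxel_size_mm)
    units[[length(units) + 1L]] <- list(
      firing = fv, difference_map = dm, normalized_map = tm$normalized_map,
      territory = tm$territory, seed_region = g,
      metrics = dplyr::bind_cols(met, alt))
  }
  if (length(units)) {
    ord <- order(vapply(units, function(u) u$metrics$activation_threshold_mA, 1),
                 decreasing = TRUE)
    units <- units[ord]
    for (i in seq_along(units)) {
      units[[i]]$firing$unit_id <- i
      units[[i]]$metrics <- dplyr::bind_cols(tibble(unit_id = i),
                                             units[[i]]$metrics)
    }
    metrics <- dplyr::bind_rows(lapply(units, function(u) u$metrics))
  } else {
    metrics <- tibble()
  }
  structure(list(units = units, metrics = metrics), class = "mumri_units")
}

#' @export
print.mumri_units <- function(x, ...) {
  cat(sprintf("<mumri_units> %d unit(s) extracted\n", length(x$units)))
  if (length(x$units)) print(x$metrics)
  invisible(x)
}

#' @export
tidy.mumri_units <- function(x, ...) x$metrics
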