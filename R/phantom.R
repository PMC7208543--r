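#' Synthetic motor-unit territories
#'
#' Builds a binary territory of one of the five canonical shape classes seen
#' in motor-unit imaging: `ellipse`, `circular`, `crescent`, `spider` and
#' `split`. Voxels are included when their centre falls inside the analytic
#' shape. All dimensions are physical (mm); the grid supplies the voxel
#' geometry.
#'
#' Shape-specific `size_params`:
#' \describe{
#'   \item{ellipse}{`axes_mm` (length 2, full axis lengths), optional
#'     `angle_deg` (major-axis orientation, default 0).}
#'   \item{circular}{`radius_mm`.}
#'   \item{crescent}{`outer_mm`, `inner_mm` (radii), `arc_deg` (angular span,
#'     default 150), optional `angle_deg` (orientation of the sector centre).}
#'   \item{spider}{`core_mm` (core radius), `n_arms` (>= 3, default 4),
#'     `arm_length_mm`, `arm_width_mm`; arm directions are evenly spaced with
#'     a small seeded jitter.}
#'   \item{split}{`radius_mm` (per component, scalar or length 2), `gap_mm`
#'     (border-to-border distance), optional `angle_deg` (axis between the
#'     components, default 0).}
#' }
#'
#' @param shape_class One of `"ellipse"`, `"circular"`, `"crescent"`,
#'   `"spider"`, `"split"`.
#' @param center Numeric `(row, col)` centre in voxel coordinates (may be
#'   fractional).
#' @param size_params Named list of shape dimensions, see Details.
#' @param grid List with `shape` `(n_row, n_col)` and `voxel_size_mm`
#'   `(row_mm, col_mm)`.
#' @param threshold_mA Activation threshold of the planted unit (mA).
#' @param firing_width_mA Logistic width of the firing probability (mA);
#'   larger widths give wider alternation ranges.
#' @param void_fraction Multiplicative signal level inside an active
#'   territory, in (0, 1); e.g. 0.4 means the signal drops to 40%.
#' @param coupling_dilation_vox Mechanical-coupling halo: the signal void
#'   extends this many voxels beyond the territory.
#' @param seed Integer seed for the arm-angle jitter of spider shapes.
#' @return An object of class `unit_territory`: list with `shape_class`,
#'   `territory` (logical matrix), `threshold_mA`, `firing_width_mA`,
#'   `void_fraction`, `coupling_dilation_vox`.
#' @examples
#' grid <- list(shape = c(48, 48), voxel_size_mm = c(1.5, 1.5))
#' u <- make_territory("ellipse", center = c(24, 24),
#'                     size_params = list(axes_mm = c(10, 4)), grid = grid)
#' sum(u$territory) * 1.5^2  # pixelated CSA close to pi * 5 * 2
#' @export
make_territory <- function(shape_class, center, size_params, grid,
                           threshold_mA = 10, firing_width_mA = 0.05,
                           void_fraction = 0.4, coupling_dilation_vox = 0L,
                           seed = 1L) {
  shape_class <- match.arg(shape_class,
                           c("ellipse", "circular", "crescent", "spider", "split"))
  nr <- grid$shape[1]; nc <- grid$shape[2]
  wy <- grid$voxel_size_mm[1]; wx <- grid$voxel_size_mm[2]
  # voxel-centre physical coordinates relative to the requested centre
  cy <- (center[1] - 0.5) * wy
  cx <- (center[2] - 0.5) * wx
  yy <- matrix((seq_len(nr) - 0.5) * wy - cy, nr, nc)
  xx <- matrix((seq_len(nc) - 0.5) * wx - cx, nr, nc, byrow = TRUE)

  p <- size_params
  territory <- switch(
    shape_class,
    ellipse = {
      a <- p$axes_mm[1] / 2; b <- p$axes_mm[2] / 2
      th <- (p$angle_deg %||% 0) * pi / 180
      u <- xx * cos(th) + yy * sin(th)
      v <- -xx * sin(th) + yy * cos(th)
      (u / a)^2 + (v / b)^2 <= 1
    },
    circular = xx^2 + yy^2 <= p$radius_mm^2,
    crescent = {
      rad <- sqrt(xx^2 + yy^2)
      th0 <- (p$angle_deg %||% 0) * pi / 180
      half <- (p$arc_deg %||% 150) * pi / 360
      ang <- atan2(yy, xx)
      dang <- atan2(sin(ang - th0), cos(ang - th0))
      rad >= p$inner_mm & rad <= p$outer_mm & abs(dang) <= half
    },
    spider = {
      n_arms <- p$n_arms %||% 4L
      if (n_arms < 3L) stop_parameter("spider needs at least 3 arms")
      jitter <- withr::with_seed(seed, runif(n_arms, -0.15, 0.15))
      angles <- 2 * pi * (seq_len(n_arms) - 1L) / n_arms + jitter
      m <- xx^2 + yy^2 <= p$core_mm^2
      for (a in angles) {
        ux <- cos(a); uy <- sin(a)
        along <- xx * ux + yy * uy
        across <- -xx * uy + yy * ux
        m <- m | (along >= 0 & along <= p$arm_length_mm &
                    abs(across) <= p$arm_width_mm / 2)
      }
      m
    },
    split = {
      r <- rep(p$radius_mm, length.out = 2L)
      th <- (p$angle_deg %||% 0) * pi / 180
      sep <- r[1] + r[2] + p$gap_mm
      c1 <- c(-sep / 2 * cos(th), -sep / 2 * sin(th))
      c2 <- c(sep / 2 * cos(th), sep / 2 * sin(th))
      ((xx - c1[1])^2 + (yy - c1[2])^2 <= r[1]^2) |
        ((xx - c2[1])^2 + (yy - c2[2])^2 <= r[2]^2)
    })

  if (!any(territory)) stop_geometry("territory is empty on this grid")
  edge <- any(territory[1, ]) || any(territory[nr, ]) ||
    any(territory[, 1]) || any(territory[, nc])
  if (edge) stop_geometry("territory touches the grid edge; it does not fit")
  structure(
    list(shape_class = shape_class, territory = territory,
         threshold_mA = threshold_mA, firing_width_mA = firing_width_mA,
         void_fraction = void_fraction,
         coupling_dilation_vox = as.integer(coupling_dilation_vox)),
    class = "unit_territory")
}

#' Logistic firing probability of a motor unit
#'
#' Near its activation threshold a motor unit fires probabilistically in an
#' all-or-none fashion. The probability is modelled as a logistic function of
#' the stimulation current: exactly 0.5 at the threshold, rising with
#' current, with `firing_width_mA` the logistic scale parameter. Width 0
#' degenerates to a step function (0.5 at the threshold by convention).
#'
#' @param current_mA Stimulation current (vectorised).
#' @param threshold_mA Activation threshold.
#' @param firing_width_mA Logistic scale (mA), >= 0.
#' @return Firing probability in `[0, 1]`.
#' @examples
#' firing_probability(10, 10, 0.05)   # 0.5
#' firing_probability(11, 10, 0.05)   # ~1
#' @export
firing_probability <- function(current_mA, threshold_mA, firing_width_mA) {
  if (firing_width_mA < 0) stop_parameter("`firing_width_mA` must be >= 0")
  if (firing_width_mA == 0) {
    out <- as.numeric(current_mA > threshold_mA)
    out[current_mA == threshold_mA] <- 0.5
    return(out)
  }
  stats::plogis((current_mA - threshold_mA) / firing_width_mA)
}

#' Assemble a phantom
#'
#' A phantom bundles a muscle mask, planted unit territories, per-muscle
#' baseline intensities, and a Rician noise level. Every territory must lie
#' inside a single positive mask label.
#'
#' @param mask A [muscle_mask()].
#' @param units List of [make_territory()] objects.
#' @param baseline_intensity Baseline signal per muscle label: scalar
#'   (recycled) or named by label.
#' @param noise_sigma Rician noise scale as a fraction of the (mean) muscle
#'   baseline; default 0.03.
#' @return An object of class `mumri_phantom`.
#' @export
phantom <- function(mask, units = list(), baseline_intensity = 100,
                    noise_sigma = 0.03) {
  stopifnot(inherits(mask, "muscle_mask"))
  for (u in units) {
    stopifnot(inherits(u, "unit_territory"))
    labs <- unique(mask$labels[u$territory])
    if (any(labs == 0L)) {
      stop_consistency("a unit territory extends outside the muscle mask")
    }
    if (length(labs) > 1L) {
      stop_consistency("a unit territory spans more than one muscle label")
    }
  }
  labels <- sort(unique(mask$labels[mask$labels > 0L]))
  base <- if (length(base::names(baseline_intensity))) {
    vals <- baseline_intensity[as.character(labels)]
    if (anyNA(vals)) stop_input("baseline_intensity missing for some labels")
    as.numeric(vals)
  } else {
    rep(as.numeric(baseline_intensity), length.out = length(labels))
  }
  structure(
    list(mask = mask, units = units,
         baseline_intensity = stats::setNames(base, labels),
         noise_sigma = noise_sigma),
    class = "mumri_phantom")
}

#' Simulate a dynamic series from a phantom
#'
#' For each dynamic the stimulation current is looked up in the schedule and
#' every planted unit independently draws fire / no-fire from its logistic
#' [firing_probability()]. Firing is all-or-none and spatially uniform: a
#' fired unit multiplies the signal by its `void_fraction` over its whole
#' territory (dilated by `coupling_dilation_vox` voxels to emulate mechanical
#' coupling of adjacent fibres). Rician noise is then applied voxel-wise:
#' `sqrt((S + sigma*N1)^2 + (sigma*N2)^2)` with `sigma = noise_sigma * mean
#' muscle baseline`. Identical seeds give bit-identical output.
#'
#' @param phantom A [phantom()].
#' @param schedule A [stim_schedule()].
#' @param seed Integer seed; all randomness (firing draws and noise) derives
#'   from it.
#' @param voxel_size_mm,tr_s Geometry passed through to the returned series.
#' @return A list with `series` (a [dynamic_series()]) and `firing` (integer
#'   matrix units x dynamics of the ground-truth draws, 1 = fired).
#' @export
simulate_series <- function(phantom, schedule, seed = 1L,
                            voxel_size_mm = c(1.5, 1.5), tr_s = 1.0) {
  stopifnot(inherits(phantom, "mumri_phantom"), inherits(schedule, "stim_schedule"))
  if (nrow(schedule) < 1L) stop_input("schedule is empty")
  lab <- phantom$mask$labels
  nr <- nrow(lab); nc <- ncol(lab)
  nd <- nrow(schedule)
  nu <- length(phantom$units)
  base_map <- matrix(0, nr, nc)
  for (l in base::names(phantom$baseline_intensity)) {
    base_map[lab == as.integer(l)] <- phantom$baseline_intensity[[l]]
  }
  sigma <- phantom$noise_sigma *
    (if (length(phantom$baseline_intensity)) mean(phantom$baseline_intensity) else 1)
  currents <- schedule$current_mA

  void_maps <- lapply(phantom$units, function(u) {
    terr <- if (u$coupling_dilation_vox > 0L) {
      dilate_binary(u$territory, u$coupling_dilation_vox)
    } else u$territory
    ifelse(terr, u$void_fraction, 1)
  })

  withr::with_seed(seed, {
    firing <- matrix(0L, nrow = max(nu, 0L), ncol = nd)
    if (nu > 0L) {
      for (i in seq_len(nu)) {
        p <- firing_probability(currents, phantom$units[[i]]$threshold_mA,
                                phantom$units[[i]]$firing_width_mA)
        firing[i, ] <- as.integer(runif(nd) < p)
      }
    }
    pix <- array(0, dim = c(nr, nc, nd))
    for (t in seq_len(nd)) {
      s <- base_map
      if (nu > 0L) {
        for (i in seq_len(nu)) {
          if (firing[i, t] == 1L) s <- s * void_maps[[i]]
        }
      }
      pix[, , t] <- s
    }
    if (sigma > 0) {
      n1 <- array(rnorm(length(pix), sd = sigma), dim = dim(pix))
      n2 <- array(rnorm(length(pix), sd = sigma), dim = dim(pix))
      pix <- sqrt((pix + n1)^2 + n2^2)
    }
  })
  list(series = dynamic_series(pix, voxel_size_mm = voxel_size_mm, tr_s = tr_s),
       firing = firing)
}
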