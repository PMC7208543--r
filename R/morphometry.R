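#' Cross-sectional area of a territory
#'
#' CSA is the voxel count times the in-plane voxel area.
#'
#' @param territory Logical or 0/1 matrix.
#' @param voxel_size_mm Length-2 `(row_mm, col_mm)`.
#' @return Area in mm^2; 0 (with a warning) for an empty map.
#' @examples
#' compute_csa(matrix(1, 3, 4), c(1.5, 1.5))  # 27
#' @export
compute_csa <- function(territory, voxel_size_mm = c(1.5, 1.5)) {
  n <- sum(territory != 0)
  if (n == 0L) {
    rlang::warn("empty territory: CSA is 0", class = "mumri_empty_warning")
    return(0)
  }
  n * voxel_size_mm[1] * voxel_size_mm[2]
}

#' Feret (caliper) diameters of a territory
#'
#' The Feret dimension at an orientation is the distance between the two
#' parallel lines of that orientation that just enclose the object. Both
#' extremes are computed by rotating calipers on the convex hull of the
#' voxel-corner polygon (the union of voxel squares): the maximum Feret is
#' the hull diameter, the minimum Feret is the smallest width across any
#' hull edge. Working on voxel corners rather than centres makes a single
#' voxel measure its physical size. For multi-component maps the calipers
#' enclose all components jointly.
#'
#' @inheritParams compute_csa
#' @return Named numeric `c(feret_max_mm, feret_min_mm)`.
#' @examples
#' compute_feret(matrix(1, 1, 1), c(1.5, 1.5))  # c(2.1213, 1.5)
#' @export
compute_feret <- function(territory, voxel_size_mm = c(1.5, 1.5)) {
  pts <- voxel_corners(territory, voxel_size_mm)
  if (nrow(pts) == 0L) stop_input("empty territory: Feret undefined")
  hull <- convex_hull(pts)
  n <- nrow(hull)
  if (n == 1L) return(c(feret_max_mm = 0, feret_min_mm = 0))
  # max Feret: hull diameter (hulls here are small; all pairs is exact)
  d2 <- as.matrix(stats::dist(hull))
  fmax <- max(d2)
  # min Feret: smallest width across a hull edge
  fmin <- Inf
  for (i in seq_len(n)) {
    a <- hull[i, ]; b <- hull[if (i == n) 1L else i + 1L, ]
    e <- b - a
    len <- sqrt(sum(e^2))
    if (len == 0) next
    # distance of every hull vertex from the edge's supporting line
    w <- max(abs((hull[, 1] - a[1]) * e[2] - (hull[, 2] - a[2]) * e[1]) / len)
    if (w < fmin) fmin <- w
  }
  if (!is.finite(fmin)) fmin <- 0
  c(feret_max_mm = fmax, feret_min_mm = fmin)
}

#' Border-to-border gap between split-territory components
#'
#' Minimum Euclidean distance between the boundary polygons of the two
#' nearest connected components (8-connectivity) of a split territory.
#'
#' @inheritParams compute_csa
#' @return Gap in mm (0 if components touch); `NA` with a warning when the
#'   map has fewer than two components.
#' @export
component_gap <- function(territory, voxel_size_mm = c(1.5, 1.5)) {
  lab <- label_components(territory != 0, 8L)
  k <- max(lab)
  if (k < 2L) {
    rlang::warn("territory has a single component: gap undefined",
                class = "mumri_undefined_warning")
    return(NA_real_)
  }
  segs <- lapply(seq_len(k), function(i) boundary_segments(lab == i, voxel_size_mm))
  best <- Inf
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      for (sa in segs[[i]]) {
        for (sb in segs[[j]]) {
          d <- seg_seg_dist(sa[1, ], sa[2, ], sb[1, ], sb[2, ])
          if (d < best) best <- d
        }
      }
    }
  }
  best
}

#' Classify a territory into the five-shape taxonomy
#'
#' Motor-unit territories fall into five outline classes: elliptical,
#' crescent, circular, spider and split. Classification is a rule cascade on
#' component count, solidity (area / convex-hull area) and aspect ratio
#' (Feret max / Feret min):
#' split when there are >= 2 components of at least `min_component_voxels`;
#' spider when solidity < `spider_solidity` (radiating processes leave large
#' concavities); crescent for intermediate solidity; otherwise circular when
#' the aspect ratio is below `circular_aspect`, else ellipse. The cutoffs
#' are package defaults chosen to separate the canonical geometries and are
#' configurable.
#'
#' @inheritParams compute_csa
#' @param spider_solidity Solidity below which a single-component shape is a
#'   spider; default 0.5.
#' @param crescent_solidity Solidity below which (and above
#'   `spider_solidity`) the shape is a crescent; default 0.75.
#' @param circular_aspect Aspect ratio below which a compact shape is
#'   circular rather than elliptical; default 1.3.
#' @param min_component_voxels Components smaller than this are ignored when
#'   counting parts; default 3.
#' @return Character scalar, one of `"split"`, `"spider"`, `"crescent"`,
#'   `"circular"`, `"ellipse"`.
#' @export
classify_shape <- function(territory, voxel_size_mm = c(1.5, 1.5),
                           spider_solidity = 0.5, crescent_solidity = 0.75,
                           circular_aspect = 1.3, min_component_voxels = 3L) {
  m <- territory != 0
  if (!any(m)) stop_input("empty territory: shape undefined")
  lab <- label_components(m, 8L)
  sizes <- tabulate(lab[lab > 0L])
  if (sum(sizes >= min_component_voxels) >= 2L) return("split")
  area <- sum(m) * voxel_size_mm[1] * voxel_size_mm[2]
  hull <- convex_hull(voxel_corners(m, voxel_size_mm))
  hull_area <- polygon_area(hull)
  solidity <- if (hull_area > 0) area / hull_area else 1
  if (solidity < spider_solidity) return("spider")
  if (solidity < crescent_solidity) return("crescent")
  fer <- compute_feret(m, voxel_size_mm)
  aspect <- if (fer[2] > 0) fer[[1]] / fer[[2]] else Inf
  if (aspect < circular_aspect) "circular" else "ellipse"
}

#' Solidity of a territory
#'
#' Ratio of the voxel area to the convex-hull area of the voxel-corner
#' polygon; 1 for convex shapes.
#'
#' @inheritParams compute_csa
#' @return Solidity in (0, 1].
#' @export
compute_solidity <- function(territory, voxel_size_mm = c(1.5, 1.5)) {
  m <- territory != 0
  if (!any(m)) stop_input("empty territory")
  area <- sum(m) * voxel_size_mm[1] * voxel_size_mm[2]
  hull_area <- polygon_area(convex_hull(voxel_corners(m, voxel_size_mm)))
  if (hull_area > 0) area / hull_area else 1
}

#' Squared co-firing correlation between two voxels
#'
#' Squared Pearson correlation of two voxel time courses over an analysis
#' window. Voxels of one motor unit fire together, so their traces correlate
#' strongly; voxels of different units with different thresholds do not.
#'
#' @param series A [dynamic_series()].
#' @param voxel_a,voxel_b Length-2 `(row, col)` voxel indices (1-based).
#' @param window Integer vector of dynamic indices (1-based) to correlate
#'   over; default all dynamics. At least 3.
#' @return r^2 in `[0, 1]`; `NA` with a warning when either trace has zero
#'   variance.
#' @export
cofire_r2 <- function(series, voxel_a, voxel_b, window = NULL) {
  stopifnot(inherits(series, "dynamic_series"))
  window <- window %||% seq_len(n_dynamics(series))
  if (length(window) < 3L) stop_input("co-firing window needs >= 3 dynamics")
  ta <- series$pixels[voxel_a[1], voxel_a[2], window]
  tb <- series$pixels[voxel_b[1], voxel_b[2], window]
  if (sd(ta) == 0 || sd(tb) == 0) {
    rlang::warn("zero-variance trace: co-firing correlation undefined",
                class = "mumri_undefined_warning")
    return(NA_real_)
  }
  cor(ta, tb)^2
}

#' Full metric set for one territory
#'
#' Convenience wrapper computing CSA, Feret dimensions, shape class,
#' component count and (for split shapes) the component gap.
#'
#' @inheritParams compute_csa
#' @param ... Passed to [classify_shape()].
#' @return A one-row tibble: `csa_mm2`, `feret_max_mm`, `feret_min_mm`,
#'   `shape_class`, `n_components`, `component_gap_mm`, `solidity`.
#' @export
unit_metrics <- function(territory, voxel_size_mm = c(1.5, 1.5), ...) {
  m <- territory != 0
  if (!any(m)) stop_input("empty territory")
  fer <- compute_feret(m, voxel_size_mm)
  lab <- label_components(m, 8L)
  ncomp <- max(lab)
  shape <- classify_shape(m, voxel_size_mm, ...)
  gap <- if (ncomp >= 2L) component_gap(m, voxel_size_mm) else NA_real_
  tibble(csa_mm2 = compute_csa(m, voxel_size_mm),
         feret_max_mm = fer[[1]], feret_min_mm = fer[[2]],
         shape_class = shape, n_components = ncomp,
         component_gap_mm = gap,
         solidity = compute_solidity(m, voxel_size_mm))
}
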