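# Low-level binary-image geometry shared by the simulator and morphometry.

#' Label connected components of a binary map
#'
#' Flood-fill labeling with 8-connectivity by default (diagonally touching
#' voxels belong to one region), matching how alternating regions that share
#' only a corner are read as one territory.
#'
#' @param mask Logical or 0/1 matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of the same shape; 0 background, 1..K components
#'   labelled in scan order.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  m <- mask != 0
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 8L) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 0L, 0L, 1L)
    dc <- c(0L, -1L, 1L, 0L)
  }
  k <- 0L
  for (start in which(m)) {
    if (lab[start] != 0L) next
    k <- k + 1L
    queue <- start
    lab[start] <- k
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r0 <- ((v - 1L) %% nr) + 1L
      c0 <- ((v - 1L) %/% nr) + 1L
      rr <- r0 + dr; cc <- c0 + dc
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      nb <- (cc[ok] - 1L) * nr + rr[ok]
      nb <- nb[m[nb] & lab[nb] == 0L]
      if (length(nb)) {
        lab[nb] <- k
        queue <- c(queue, nb)
      }
    }
  }
  lab
}

#' Dilate a binary map by n voxels
#'
#' Box (Chebyshev) dilation: each pass adds the 8-neighbourhood. Used to
#' model the mechanical-coupling halo around an active territory.
#'
#' @param mask Logical or 0/1 matrix.
#' @param n Number of dilation passes (integer >= 0).
#' @return Logical matrix.
#' @export
dilate_binary <- function(mask, n = 1L) {
  stopifnot(is.matrix(mask), n >= 0L)
  m <- mask != 0
  if (n == 0L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  for (i in seq_len(n)) {
    # separable box dilation: row shifts, then column shifts of the result
    out <- m
    out[-1, ] <- out[-1, ] | m[-nr, ]
    out[-nr, ] <- out[-nr, ] | m[-1, ]
    tmp <- out
    tmp[, -1] <- tmp[, -1] | out[, -nc]
    tmp[, -nc] <- tmp[, -nc] | out[, -1]
    m <- tmp
  }
  m
}

# Physical (x, y) corner points of the union-of-squares polygon of a binary
# map. x runs along columns, y along rows; corners of voxel (r, c) are at
# x in {(c-1), c} * wx and y in {(r-1), r} * wy. Morphometry works on these
# corner points so a single voxel has the physical extent of the voxel, not
# a point.
voxel_corners <- function(mask, voxel_size_mm) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(matrix(numeric(0), 0, 2))
  wy <- voxel_size_mm[1]; wx <- voxel_size_mm[2]
  r <- idx[, 1]; c <- idx[, 2]
  x <- c(c - 1, c, c - 1, c) * wx
  y <- c(r - 1, r - 1, r, r) * wy
  unique(cbind(x, y))
}

# Convex hull of a point set as an ordered polygon matrix (n x 2).
convex_hull <- function(pts) {
  if (nrow(pts) == 1L) return(pts)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  pts[h, , drop = FALSE]
}

# Shoelace area of an ordered polygon.
polygon_area <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Minimum distance between a point and a segment.
point_seg_dist <- function(p, a, b) {
  ab <- b - a
  L2 <- sum(ab^2)
  if (L2 == 0) return(sqrt(sum((p - a)^2)))
  t <- max(0, min(1, sum((p - a) * ab) / L2))
  sqrt(sum((p - a - t * ab)^2))
}

# Minimum distance between two segments (a1-a2, b1-b2).
seg_seg_dist <- function(a1, a2, b1, b2) {
  # segments either intersect (distance 0) or the minimum is endpoint-to-segment
  d1 <- (a2[1] - a1[1]) * (b1[2] - a1[2]) - (a2[2] - a1[2]) * (b1[1] - a1[1])
  d2 <- (a2[1] - a1[1]) * (b2[2] - a1[2]) - (a2[2] - a1[2]) * (b2[1] - a1[1])
  d3 <- (b2[1] - b1[1]) * (a1[2] - b1[2]) - (b2[2] - b1[2]) * (a1[1] - b1[1])
  d4 <- (b2[1] - b1[1]) * (a2[2] - b1[2]) - (b2[2] - b1[2]) * (a2[1] - b1[1])
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
    return(0)
  }
  min(point_seg_dist(b1, a1, a2), point_seg_dist(b2, a1, a2),
      point_seg_dist(a1, b1, b2), point_seg_dist(a2, b1, b2))
}

# Exposed boundary edges of a binary component as physical segments:
# list of 2x2 matrices (rows = endpoints). An edge is exposed when the
# 4-neighbour across it is background.
boundary_segments <- function(mask, voxel_size_mm) {
  idx <- which(mask != 0, arr.ind = TRUE)
  wy <- voxel_size_mm[1]; wx <- voxel_size_mm[2]
  nr <- nrow(mask); nc <- ncol(mask)
  segs <- list()
  inmask <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && mask[r, c] != 0
  for (i in seq_len(nrow(idx))) {
    r <- idx[i, 1]; c <- idx[i, 2]
    x0 <- (c - 1) * wx; x1 <- c * wx
    y0 <- (r - 1) * wy; y1 <- r * wy
    if (!inmask(r - 1, c)) segs[[length(segs) + 1L]] <- rbind(c(x0, y0), c(x1, y0))
    if (!inmask(r + 1, c)) segs[[length(segs) + 1L]] <- rbind(c(x0, y1), c(x1, y1))
    if (!inmask(r, c - 1)) segs[[length(segs) + 1L]] <- rbind(c(x0, y0), c(x0, y1))
    if (!inmask(r, c + 1)) segs[[length(segs) + 1L]] <- rbind(c(x1, y0), c(x1, y1))
  }
  segs
}
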