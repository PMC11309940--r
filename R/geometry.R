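# Planar geometry primitives (projected coordinates in metres).
# Interior tests use the even-odd rule with closed boundaries; distances are
# exact minimum distances between polygon boundaries / cell squares.

ring_area_signed <- function(m) {
  n <- nrow(m)
  if (n < 3) return(0)
  x <- m[, 1]; y <- m[, 2]
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

polys_area <- function(rings) {
  abs(sum(purrr::map_dbl(rings, ring_area_signed)))
}

# even-odd point-in-polygon over a set of rings; boundary points count as
# inside (closed containment). x, y vectorized.
point_in_polys <- function(x, y, rings, tol = 1e-9) {
  inside <- rep(FALSE, length(x))
  on_edge <- rep(FALSE, length(x))
  for (m in rings) {
    n <- nrow(m)
    x1 <- m[, 1]; y1 <- m[, 2]
    x2 <- m[c(2:n, 1), 1]; y2 <- m[c(2:n, 1), 2]
    for (e in seq_len(n)) {
      ax <- x1[e]; ay <- y1[e]; bx <- x2[e]; by <- y2[e]
      # crossing test (half-open in y to avoid double counting at vertices)
      crosses <- ((ay > y) != (by > y))
      if (any(crosses)) {
        xint <- ax + (y[crosses] - ay) / (by - ay) * (bx - ax)
        flip <- which(crosses)[xint > x[crosses]]
        inside[flip] <- !inside[flip]
      }
      # on-segment test
      dx <- bx - ax; dy <- by - ay
      L2 <- dx * dx + dy * dy
      if (L2 > 0) {
        t <- pmin(1, pmax(0, ((x - ax) * dx + (y - ay) * dy) / L2))
        d2 <- (ax + t * dx - x)^2 + (ay + t * dy - y)^2
        on_edge <- on_edge | d2 <= tol^2
      } else {
        on_edge <- on_edge | ((x - ax)^2 + (y - ay)^2 <= tol^2)
      }
    }
  }
  inside | on_edge
}

# min distance from points (px, py) to segment (ax,ay)-(bx,by); vectorized
# over points
point_seg_dist <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  L2 <- dx * dx + dy * dy
  t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) /
                      ifelse(L2 == 0, 1, L2)))
  sqrt((ax + t * dx - px)^2 + (ay + t * dy - py)^2)
}

rings_segments <- function(rings) {
  segs <- purrr::map(rings, function(m) {
    n <- nrow(m)
    cbind(m, m[c(2:n, 1), , drop = FALSE])
  })
  do.call(rbind, segs)  # columns: ax, ay, bx, by
}

segs_cross <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  o <- function(px, py, qx, qy, rx, ry) {
    sign((qx - px) * (ry - py) - (qy - py) * (rx - px))
  }
  o1 <- o(ax, ay, bx, by, cx, cy)
  o2 <- o(ax, ay, bx, by, dx, dy)
  o3 <- o(cx, cy, dx, dy, ax, ay)
  o4 <- o(cx, cy, dx, dy, bx, by)
  (o1 * o2 < 0) & (o3 * o4 < 0)
}

# exact minimum distance between the boundaries/interiors of two polygon
# ring sets; 0 on touch, overlap or containment
polys_min_dist <- function(ringsA, ringsB) {
  va <- do.call(rbind, ringsA)
  vb <- do.call(rbind, ringsB)
  if (any(point_in_polys(va[, 1], va[, 2], ringsB)) ||
      any(point_in_polys(vb[, 1], vb[, 2], ringsA))) {
    return(0)
  }
  sa <- rings_segments(ringsA)
  sb <- rings_segments(ringsB)
  best <- Inf
  for (i in seq_len(nrow(sa))) {
    if (any(segs_cross(sa[i, 1], sa[i, 2], sa[i, 3], sa[i, 4],
                       sb[, 1], sb[, 2], sb[, 3], sb[, 4]))) {
      return(0)
    }
    d1 <- point_seg_dist(sa[i, 1], sa[i, 2], sb[, 1], sb[, 2], sb[, 3], sb[, 4])
    d2 <- point_seg_dist(sa[i, 3], sa[i, 4], sb[, 1], sb[, 2], sb[, 3], sb[, 4])
    d3 <- point_seg_dist(sb[, 1], sb[, 2],
                         sa[i, 1], sa[i, 2], sa[i, 3], sa[i, 4])
    d4 <- point_seg_dist(sb[, 3], sb[, 4],
                         sa[i, 1], sa[i, 2], sa[i, 3], sa[i, 4])
    best <- min(best, min(d1), min(d2), min(d3), min(d4))
  }
  best
}

# boundary cells of a raster patch: cells with a 4-neighbour outside the patch
patch_boundary_cells <- function(cells) {
  key <- paste(cells[, 1], cells[, 2])
  inset <- paste(cells[, 1] - 1L, cells[, 2]) %in% key &
    paste(cells[, 1] + 1L, cells[, 2]) %in% key &
    paste(cells[, 1], cells[, 2] - 1L) %in% key &
    paste(cells[, 1], cells[, 2] + 1L) %in% key
  cells[!inset, , drop = FALSE]
}

# exact min distance between two sets of axis-aligned cell squares given
# their centre coordinates and the cell size
cell_sets_min_dist <- function(xyA, xyB, cell) {
  dx <- abs(outer(xyA[, 1], xyB[, 1], "-")) - cell
  dy <- abs(outer(xyA[, 2], xyB[, 2], "-")) - cell
  dx[dx < 0] <- 0
  dy[dy < 0] <- 0
  sqrt(min(dx * dx + dy * dy))
}

# convex hull polygon (closed ring not repeated) of a point matrix
hull_ring <- function(xy) {
  xy <- unique(xy)
  if (nrow(xy) == 1) {
    return(xy[c(1, 1, 1), , drop = FALSE])
  }
  h <- grDevices::chull(xy[, 1], xy[, 2])
  xy[h, , drop = FALSE]
}

# vertex cloud representing a patch, for hulls and centroids
patch_points <- function(layer, i) {
  if (layer_kind(layer) == "raster") {
    cells <- layer$geometry[[i]]
    ctr <- cell_centre_xy(layer_meta(layer), cells[, 1], cells[, 2])
    h <- attr(layer, "cell") / 2
    rbind(cbind(ctr[, 1] - h, ctr[, 2] - h), cbind(ctr[, 1] + h, ctr[, 2] - h),
          cbind(ctr[, 1] + h, ctr[, 2] + h), cbind(ctr[, 1] - h, ctr[, 2] + h))
  } else {
    do.call(rbind, layer$geometry[[i]])
  }
}

patch_centroid <- function(layer, i) {
  if (layer_kind(layer) == "raster") {
    cells <- layer$geometry[[i]]
    ctr <- cell_centre_xy(layer_meta(layer), cells[, 1], cells[, 2])
    c(mean(ctr[, 1]), mean(ctr[, 2]))
  } else {
    v <- do.call(rbind, layer$geometry[[i]])
    c(mean(v[, 1]), mean(v[, 2]))
  }
}

# an interior point of the patch: a habitat cell centre nearest the centroid
# (raster), or the centroid with a vertex-midpoint fallback (vector)
patch_interior_point <- function(layer, i) {
  if (layer_kind(layer) == "raster") {
    cells <- layer$geometry[[i]]
    ctr <- cell_centre_xy(layer_meta(layer), cells[, 1], cells[, 2])
    cen <- c(mean(ctr[, 1]), mean(ctr[, 2]))
    k <- which.min((ctr[, 1] - cen[1])^2 + (ctr[, 2] - cen[2])^2)
    ctr[k, ]
  } else {
    rings <- layer$geometry[[i]]
    cen <- patch_centroid(layer, i)
    if (point_in_polys(cen[1], cen[2], rings)) return(cen)
    v <- rings[[1]]
    n <- nrow(v)
    for (k in seq_len(n)) {
      mid <- (v[k, ] + v[(k %% n) + 1, ]) / 2
      p <- (mid + cen) / 2
      if (point_in_polys(p[1], p[2], rings)) return(p)
    }
    v[1, ]
  }
}
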