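# helpers to build small in-memory fixtures; everything is generated in code

# mask from a 0/1 matrix given row-wise top-to-bottom, cell size in metres
mk_mask <- function(m, cell = 10, timestep = NA, xmin = 0, ymin = 0) {
  habitat_mask(m, cell = cell, xmin = xmin, ymin = ymin, timestep = timestep)
}

# axis-aligned rectangle ring [x1,x2] x [y1,y2]
rect_ring <- function(x1, x2, y1, y2) {
  cbind(x = c(x1, x2, x2, x1), y = c(y1, y1, y2, y2))
}

# vector patch layer of rectangles; rects = list of c(x1,x2,y1,y2)
rect_layer <- function(rects, ids = NULL, timestep = NA) {
  if (is.null(ids)) ids <- sprintf("P%04d", seq_along(rects))
  patch_layer_from_polygons(
    ids, lapply(rects, function(r) list(rect_ring(r[1], r[2], r[3], r[4]))),
    timestep = timestep
  )
}

# an occurrence matrix directly from a named list of species sets
mk_occmat <- function(sets) {
  sp <- sort(unique(unlist(sets)))
  m <- matrix(0L, length(sets), length(sp),
              dimnames = list(names(sets), sp))
  for (i in seq_along(sets)) m[i, sets[[i]]] <- 1L
  structure(m, n_dropped = 0L, class = "occurrence_matrix")
}

# independent oracle: reachability by boolean matrix closure
closure_components <- function(adj) {
  n <- nrow(adj)
  reach <- adj | diag(TRUE, n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  match(apply(reach, 1, paste, collapse = ""),
        unique(apply(reach, 1, paste, collapse = "")))
}

# compare two integer partitions up to label renaming
same_partition <- function(a, b) {
  identical(match(a, unique(a)), match(b, unique(b)))
}

# small, fast synthetic scenario for structural tests
small_lp <- function(seed = 1) {
  landscape_params(extent = 9000, n_clusters = 2, patches_per_cluster = 8,
                   patch_radius = c(100, 140), gap_range = c(120, 180),
                   inter_cluster_gap = 1100, max_cluster_sep = 5800,
                   cell_size = 25, seed = seed)
}

small_dp <- function(seed = 1) {
  degradation_params(n_steps = 3, removal_prob = 0.05, shrink_fraction = 0.1,
                     timesteps = c(1899, 1955, 2010), seed = seed)
}
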