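#' Synthetic landscape parameters
#'
#' The generator emulates a patchy wetland landscape organised in spatial
#' clusters: each cluster is a chain of disc-shaped patches whose
#' edge-to-edge gaps are drawn from `gap_range`, while clusters are kept at
#' least `inter_cluster_gap` apart edge-to-edge. Chain placement (rather
#' than Gaussian scatter) guarantees two properties at once: every
#' within-cluster gap stays below the smallest dispersal threshold of
#' interest (so the ground-truth components equal the clusters at any tested
#' threshold), and removing an interior patch can split a cluster (so
#' degradation fragments the network, as historical wetland loss did).
#'
#' @param extent Side of the square landscape in metres.
#' @param n_clusters Number of patch clusters (ground-truth metacommunities).
#' @param patches_per_cluster Discs per cluster (single number or range).
#' @param patch_radius Disc radius range in metres.
#' @param gap_range Within-cluster edge-to-edge gap range in metres; keep the
#'   upper end below the smallest dispersal threshold minus a rasterisation
#'   margin of about 1.5 cells.
#' @param inter_cluster_gap Minimum edge-to-edge distance between clusters in
#'   metres; must exceed the largest dispersal threshold to be tested.
#' @param max_cluster_sep Maximum centre separation (m) of a cluster from its
#'   nearest neighbouring cluster. Keeps clusters within beta-diversity
#'   pairing range of each other (the 15 km pairing limit), so that
#'   between-metacommunity patch pairs remain observable.
#' @param cell_size Raster cell size in metres.
#' @param seed Integer seed for the placement stream.
#' @return A `landscape_params` list.
#' @export
landscape_params <- function(extent = 30000, n_clusters = 2,
                             patches_per_cluster = 24,
                             patch_radius = c(140, 180),
                             gap_range = c(140, 200),
                             inter_cluster_gap = 2200,
                             max_cluster_sep = 15500,
                             cell_size = 25, seed = 1) {
  stopifnot(extent > 0, n_clusters >= 1, all(patch_radius > 0),
            all(gap_range > 0), inter_cluster_gap > 0, cell_size > 0,
            max_cluster_sep > inter_cluster_gap)
  structure(list(extent = extent, n_clusters = n_clusters,
                 patches_per_cluster = patches_per_cluster,
                 patch_radius = range(patch_radius),
                 gap_range = range(gap_range),
                 inter_cluster_gap = inter_cluster_gap,
                 max_cluster_sep = max_cluster_sep,
                 cell_size = cell_size, seed = seed),
            class = "landscape_params")
}

#' Habitat degradation parameters
#'
#' Degradation only removes or shrinks patches — habitat is never gained —
#' so the generated series is nested by construction and already satisfies
#' the harmonization invariant.
#'
#' @param n_steps Number of time steps including the initial layer.
#' @param removal_prob Probability that a surviving patch disappears at each
#'   transition; a single value or one per transition (`n_steps - 1`).
#' @param shrink_fraction Per-step fractional radius loss of survivors.
#' @param split_bridges Sever one chain stepping-stone patch per cluster
#'   on a staggered schedule (odd-numbered clusters at the first transition,
#'   even-numbered at the last). This guarantees the progressive component
#'   break-up that a drained wetland landscape shows, independently of where
#'   the random removals happen to fall; background random removal and
#'   shrinkage still apply on top.
#' @param bridge_pos Relative position (0-1) of the severed stepping stone
#'   along the chain. Off-centre values (default 0.25) yield one large and
#'   one small fragment, the typical outcome of piecemeal wetland drainage
#'   starting at a chain's periphery.
#' @param timesteps Ordinal labels, one per step (default three snapshots
#'   spanning roughly a century, mirroring historical map coverage).
#' @param seed Integer seed for the degradation stream.
#' @return A `degradation_params` list.
#' @export
degradation_params <- function(n_steps = 3, removal_prob = 0.03,
                               shrink_fraction = 0.1, split_bridges = TRUE,
                               bridge_pos = 0.25,
                               timesteps = NULL, seed = 1) {
  stopifnot(n_steps >= 1, all(removal_prob >= 0), all(removal_prob <= 1),
            shrink_fraction >= 0, shrink_fraction < 1)
  if (n_steps > 1) {
    stopifnot(length(removal_prob) %in% c(1L, n_steps - 1L))
    removal_prob <- rep_len(removal_prob, n_steps - 1L)
  }
  if (is.null(timesteps)) {
    timesteps <- round(seq(1899, 2010, length.out = n_steps))
  }
  stopifnot(length(timesteps) == n_steps, !is.unsorted(timesteps, strictly = TRUE))
  stopifnot(bridge_pos > 0, bridge_pos < 1)
  structure(list(n_steps = n_steps, removal_prob = removal_prob,
                 shrink_fraction = shrink_fraction,
                 split_bridges = split_bridges, bridge_pos = bridge_pos,
                 timesteps = timesteps, seed = seed),
            class = "degradation_params")
}

#' Community assembly parameters
#'
#' Communities are drawn from per-metacommunity species pools of fixed
#' composition: a share `pool_overlap` of the regional pool is common to all
#' metacommunities, and each metacommunity additionally draws a private
#' sub-pool of `s_pool * (1 - pool_overlap) * private_share` species at
#' random from the remainder. Sampling (rather than partitioning) the
#' private sub-pools means every metacommunity, whatever its patch count,
#' fields a community of comparable richness whose composition has drifted
#' away from its neighbours' — two pools share only the common block plus a
#' small random private overlap. Each member patch then samples its pool
#' with probability `occupancy` (times an optional exponential distance
#' decay from the pool's centroid patch), and every patch-by-species cell
#' flips with probability `noise_rate`. The defaults are calibrated so the
#' median pairwise Jaccard dissimilarity lands near 0.8, the saturation
#' regime typical of sparse pond-insect monitoring data.
#'
#' @param s_pool Regional species pool size.
#' @param pool_overlap Share of the pool common to all metacommunities.
#' @param private_share Fraction of the non-common pool sampled into each
#'   metacommunity's private sub-pool.
#' @param occupancy Baseline per-patch occupancy probability.
#' @param distance_decay Exponential decay rate (1/m) of occupancy with
#'   distance from the pool centroid patch (0 disables the decay).
#' @param noise_rate Per-cell random flip probability.
#' @param seed Integer seed for the community stream.
#' @return A `community_params` list.
#' @export
community_params <- function(s_pool = 60, pool_overlap = 0.3,
                             private_share = 0.3,
                             occupancy = 0.5, distance_decay = 0,
                             noise_rate = 0.05, seed = 1) {
  stopifnot(s_pool >= 1, pool_overlap >= 0, pool_overlap <= 1,
            private_share >= 0, private_share <= 1,
            occupancy >= 0, occupancy <= 1, distance_decay >= 0,
            noise_rate >= 0, noise_rate <= 1)
  structure(list(s_pool = s_pool, pool_overlap = pool_overlap,
                 private_share = private_share,
                 occupancy = occupancy, distance_decay = distance_decay,
                 noise_rate = noise_rate, seed = seed),
            class = "community_params")
}

# chain layout of one cluster relative to its centre; returns disc table
chain_layout <- function(n, p) {
  r <- runif(n, p$patch_radius[1], p$patch_radius[2])
  pos <- matrix(0, n, 2)
  phi <- runif(1, 0, 2 * pi)
  ends <- list(right = 1L, left = 1L)
  # cap on how far jitter may let a chain arm wander from the centre, so the
  # cluster's footprint stays predictable for placement; also bounded so two
  # clusters can always satisfy both separation constraints
  reach_cap <- min(
    1.15 * ceiling(n / 2) * (2 * p$patch_radius[2] + p$gap_range[2]),
    (p$max_cluster_sep - p$inter_cluster_gap) / 2 - 2 * p$cell_size
  )
  for (k in seq_len(n)[-1]) {
    side <- if (k %% 2 == 0) "right" else "left"
    anchor <- ends[[side]]
    placed <- FALSE
    for (try in 1:80) {
      ang <- phi + (if (side == "left") pi else 0) + runif(1, -0.35, 0.35)
      gap <- runif(1, p$gap_range[1], p$gap_range[2])
      step <- r[anchor] + gap + r[k]
      cand <- pos[anchor, ] + step * c(cos(ang), sin(ang))
      others <- setdiff(seq_len(k - 1), anchor)
      gaps <- if (length(others)) {
        sqrt((pos[others, 1] - cand[1])^2 + (pos[others, 2] - cand[2])^2) -
          r[others] - r[k]
      } else numeric()
      if (all(gaps >= p$gap_range[1]) &&
          sqrt(sum(cand^2)) <= reach_cap - r[k]) {
        pos[k, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not lay out cluster chain; widen gap_range or extent")
    ends[[side]] <- k
  }
  # position of each disc along the chain path (the layout alternates ends)
  left <- rev(seq(3, n, by = 2)[seq(3, n, by = 2) <= n])
  right <- seq(2, n, by = 2)[seq(2, n, by = 2) <= n]
  path_seq <- c(if (n >= 3) left, 1L, if (n >= 2) right)
  chain_pos <- integer(n)
  chain_pos[path_seq] <- seq_len(n)
  tibble::tibble(dx = pos[, 1], dy = pos[, 2], r = r, chain_pos = chain_pos)
}

#' Generate a synthetic clustered landscape
#'
#' Places clusters of disc-shaped patches (rejection-sampled so clusters keep
#' their minimum separation), rasterises them to the cell grid and labels
#' patches. Identical seeds give identical landscapes.
#'
#' @param p A [landscape_params()] object.
#' @return List with `mask` ([habitat_mask()]), `layer` ([patch_layer]),
#'   `discs` (disc table with cluster ids) and `truth` (tibble `patch_id`,
#'   `cluster` — the ground-truth metacommunity of every patch).
#' @export
generate_landscape <- function(p) {
  stopifnot(inherits(p, "landscape_params"))
  set.seed(p$seed)
  npc <- if (length(p$patches_per_cluster) == 1) {
    rep(p$patches_per_cluster, p$n_clusters)
  } else {
    sample(seq(p$patches_per_cluster[1], p$patches_per_cluster[2]),
           p$n_clusters, replace = TRUE)
  }
  layouts <- purrr::map(npc, chain_layout, p = p)
  reach <- purrr::map_dbl(layouts, function(l) max(sqrt(l$dx^2 + l$dy^2) + l$r))
  margin <- reach + 2 * p$cell_size
  if (any(p$extent - 2 * margin <= 0)) stop("extent too small for cluster reach")
  # constructive placement: each new cluster is dropped at a sampled
  # distance (within the required separation band) from a previous one, so
  # narrow feasible bands are still hit reliably
  centres <- NULL
  for (attempt in 1:400) {
    centres <- matrix(NA_real_, p$n_clusters, 2)
    centres[1, ] <- runif(2, margin[1], p$extent - margin[1])
    ok <- TRUE
    for (k in seq_len(p$n_clusters)[-1]) {
      prev <- seq_len(k - 1)
      sep_needed <- p$inter_cluster_gap + reach[prev] + reach[k] +
        2 * p$cell_size
      placed <- FALSE
      for (try in 1:500) {
        j <- if (k == 2) 1L else sample(prev, 1)
        d <- runif(1, sep_needed[j], max(p$max_cluster_sep, sep_needed[j]))
        ang <- runif(1, 0, 2 * pi)
        cand <- centres[j, ] + d * c(cos(ang), sin(ang))
        if (any(cand < margin[k]) || any(cand > p$extent - margin[k])) next
        seps <- sqrt((centres[prev, 1] - cand[1])^2 +
                     (centres[prev, 2] - cand[2])^2)
        if (all(seps >= sep_needed)) {
          centres[k, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) break
    centres <- NULL
  }
  if (is.null(centres)) {
    stop("extent too small to place ", p$n_clusters,
         " clusters at the required separation")
  }
  discs <- purrr::map_dfr(seq_len(p$n_clusters), function(k) {
    dplyr::mutate(layouts[[k]], cluster = k,
                  x = centres[k, 1] + .data$dx, y = centres[k, 2] + .data$dy)
  }) |>
    dplyr::mutate(disc_id = dplyr::row_number()) |>
    dplyr::select("disc_id", "cluster", "x", "y", "r", "chain_pos")
  rasterise_discs(discs, p)
}

rasterise_discs <- function(discs, p, timestep = NA) {
  ncell <- ceiling(p$extent / p$cell_size)
  g <- matrix(0L, ncell, ncell)
  meta <- list(grid_dim = c(ncell, ncell), cell = p$cell_size,
               xmin = 0, ymin = 0)
  for (i in seq_len(nrow(discs))) {
    xc <- discs$x[i]; yc <- discs$y[i]; r <- discs$r[i]
    c1 <- max(1, floor((xc - r) / p$cell_size))
    c2 <- min(ncell, ceiling((xc + r) / p$cell_size) + 1)
    r2i <- max(1, ncell - ceiling((yc + r) / p$cell_size))
    r1i <- min(ncell, ncell - floor((yc - r) / p$cell_size) + 1)
    rows <- seq(r2i, r1i); cols <- seq(c1, c2)
    cc <- expand.grid(row = rows, col = cols)
    ctr <- cell_centre_xy(meta, cc$row, cc$col)
    inside <- (ctr[, 1] - xc)^2 + (ctr[, 2] - yc)^2 <= r^2
    g[cbind(cc$row[inside], cc$col[inside])] <- 1L
  }
  mask <- habitat_mask(g, cell = p$cell_size, xmin = 0, ymin = 0,
                       timestep = timestep)
  layer <- label_patches(mask)
  lg <- attr(layer, "label_grid")
  rc <- xy_to_cell(layer_meta(layer), discs$x, discs$y)
  lab <- lg[cbind(rc[, 1], rc[, 2])]
  if (any(lab == 0L)) stop("internal: disc centre not inside its own patch")
  truth <- tibble::tibble(patch_id = layer$patch_id[lab],
                          cluster = discs$cluster) |>
    dplyr::distinct()
  if (anyDuplicated(truth$patch_id)) {
    stop("clusters merged during rasterisation; increase gaps")
  }
  list(mask = mask, layer = layer, discs = discs, truth = truth)
}

#' Degrade a synthetic landscape through time
#'
#' From the seed landscape, each subsequent step removes every surviving
#' patch with `removal_prob` and shrinks survivors' radii by
#' `shrink_fraction`; patches shrunk below one cell vanish. The resulting
#' mask series is nested (habitat only lost), so harmonization leaves it
#' unchanged.
#'
#' @param landscape A [generate_landscape()] result.
#' @param p The [landscape_params()] used to generate it.
#' @param dp A [degradation_params()] object.
#' @return A `landscape_series`: list of per-step lists (`mask`, `layer`,
#'   `discs`, `truth`) ordered by time, with the time labels as attribute
#'   `timesteps`.
#' @export
degrade <- function(landscape, p, dp) {
  stopifnot(inherits(dp, "degradation_params"))
  set.seed(dp$seed)
  steps <- vector("list", dp$n_steps)
  discs <- landscape$discs
  first <- rasterise_discs(discs, p, timestep = dp$timesteps[1])
  steps[[1]] <- first
  n0 <- tapply(landscape$discs$chain_pos, landscape$discs$cluster, max)
  for (t in seq_len(dp$n_steps)[-1]) {
    if (nrow(discs) > 0) {
      keep <- runif(nrow(discs)) >= dp$removal_prob[t - 1]
      discs <- discs[keep, , drop = FALSE]
      if (isTRUE(dp$split_bridges)) {
        tr <- t - 1L
        for (cl in unique(discs$cluster)) {
          # odd clusters fragment progressively (one severed stepping stone
          # per transition); even clusters break up only at the last one
          due <- if (cl %% 2 == 1) tr == 1L else tr == dp$n_steps - 1L
          in_cl <- which(discs$cluster == cl)
          if (due && length(in_cl) >= 4) {
            nc0 <- n0[[as.character(cl)]]
            target <- min(nc0 - 2, max(3, round(nc0 * dp$bridge_pos)))
            bridge <- in_cl[which.min(abs(discs$chain_pos[in_cl] - target))]
            discs <- discs[-bridge, , drop = FALSE]
          }
        }
      }
      discs$r <- discs$r * (1 - dp$shrink_fraction)
      discs <- discs[discs$r >= p$cell_size, , drop = FALSE]
    }
    if (nrow(discs) == 0) {
      warning("all patches lost before the final step; series truncated at t = ",
              dp$timesteps[t - 1])
      steps <- steps[seq_len(t - 1)]
      return(structure(steps, timesteps = dp$timesteps[seq_len(t - 1)],
                       class = "landscape_series"))
    }
    steps[[t]] <- rasterise_discs(discs, p, timestep = dp$timesteps[t])
  }
  structure(steps, timesteps = dp$timesteps, class = "landscape_series")
}

#' Generate species occurrence records with a known grouping signal
#'
#' Seeds one species pool per ground-truth metacommunity (per the supplied
#' grouping of current patches) and emits one occurrence point per realised
#' patch-by-species presence, placed at a random habitat cell of the patch.
#'
#' @param layer Current-time raster [patch_layer].
#' @param grouping Tibble `patch_id`, `group` covering the layer's patches —
#'   the ground truth the communities should reflect (historical clusters
#'   for an extinction-debt regime, current components otherwise).
#' @param cp A [community_params()] object.
#' @return Tibble `x`, `y`, `species` of occurrence points.
#' @export
generate_communities <- function(layer, grouping, cp) {
  stopifnot(inherits(cp, "community_params"),
            all(layer$patch_id %in% grouping$patch_id))
  set.seed(cp$seed)
  groups <- sort(unique(grouping$group))
  k <- length(groups)
  species <- sprintf("sp%03d", seq_len(cp$s_pool))
  n_common <- round(cp$s_pool * cp$pool_overlap)
  common <- species[seq_len(n_common)]
  private_all <- setdiff(species, common)
  n_priv <- round(length(private_all) * cp$private_share)
  if (n_common + n_priv == 0) stop("empty species pools; increase s_pool")
  pools <- if (k * n_priv <= length(private_all)) {
    # enough species for fully differentiated private pools
    shuffled <- sample(private_all)
    purrr::map(seq_len(k), function(g) {
      c(common, shuffled[seq_len(n_priv) + (g - 1) * n_priv])
    })
  } else {
    # crowded regional pool: private pools drift independently and may
    # partially overlap
    purrr::map(seq_len(k), function(g) c(common, sample(private_all, n_priv)))
  }
  centroids <- t(vapply(seq_len(nrow(layer)), function(i) {
    patch_centroid(layer, i)
  }, numeric(2)))
  rownames(centroids) <- layer$patch_id
  presence <- matrix(0L, nrow(layer), cp$s_pool,
                     dimnames = list(layer$patch_id, species))
  for (g in seq_len(k)) {
    members <- grouping$patch_id[grouping$group == groups[g]]
    members <- intersect(members, layer$patch_id)
    if (!length(members)) next
    cen <- colMeans(centroids[members, , drop = FALSE])
    d0 <- sqrt((centroids[members, 1] - cen[1])^2 +
               (centroids[members, 2] - cen[2])^2)
    pool_centroid <- centroids[members[which.min(d0)], ]
    dist_pc <- sqrt((centroids[members, 1] - pool_centroid[1])^2 +
                    (centroids[members, 2] - pool_centroid[2])^2)
    prob <- cp$occupancy * exp(-cp$distance_decay * dist_pc)
    for (i in seq_along(members)) {
      draw <- runif(length(pools[[g]])) < prob[i]
      presence[members[i], pools[[g]]][draw] <- 1L
    }
  }
  if (cp$noise_rate > 0) {
    flips <- matrix(runif(length(presence)) < cp$noise_rate,
                    nrow(presence), ncol(presence))
    presence[flips] <- 1L - presence[flips]
  }
  idx <- which(presence == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("no presences generated; raise occupancy")
  meta <- layer_meta(layer)
  pts <- purrr::map_dfr(seq_len(nrow(idx)), function(j) {
    cells <- layer$geometry[[idx[j, 1]]]
    cell <- cells[sample.int(nrow(cells), 1), , drop = FALSE]
    ctr <- cell_centre_xy(meta, cell[, 1], cell[, 2])
    tibble::tibble(x = ctr[1, 1], y = ctr[1, 2],
                   species = colnames(presence)[idx[j, 2]])
  })
  pts
}

#' Simulate one extinction-debt study and evaluate all time steps
#'
#' The full study conditions in one call: generate a clustered landscape,
#' degrade it through the time steps, seed communities either from the
#' earliest components (`regime = "historical"`: compositional similarity
#' reflects the past configuration — an extinction debt) or from the current
#' components (`regime = "current"`: no debt), then build the per-time-step
#' networks at the reference dispersal threshold, delineate, and score every
#' candidate delineation against beta-diversity.
#'
#' @param seed Master seed; the placement, degradation and community streams
#'   are derived from it so the two regimes share landscapes.
#' @param regime `"historical"` or `"current"`.
#' @param theta Reference dispersal threshold in metres (default 500).
#' @param lp,dp,cp Parameter objects; defaults are the study conditions.
#' @param limit Pairing limit in metres.
#' @return The [evaluate_all()] table, with the simulated scenario attached
#'   as attribute `scenario` (list with the series, layers, matrix,
#'   networks, delineations and truth grouping).
#' @export
debt_experiment <- function(seed, regime = c("historical", "current"),
                            theta = 500,
                            lp = landscape_params(),
                            dp = degradation_params(),
                            cp = community_params(),
                            limit = 15000) {
  regime <- match.arg(regime)
  # one stream per concern, derived from the master seed (kept below 2^31)
  lp$seed <- (seed * 13 + 1) %% 2147483647
  dp$seed <- (seed * 13 + 5) %% 2147483647
  cp$seed <- (seed * 13 + 9) %% 2147483647
  scn <- simulate_scenario(seed, regime, theta, lp, dp, cp)
  ev <- evaluate_all(scn$delineations, scn$matrix, scn$current_layer,
                     limit = limit, d_matrix = scn$dists[[length(scn$dists)]])
  attr(ev, "scenario") <- scn
  ev
}

simulate_scenario <- function(seed, regime, theta, lp, dp, cp) {
  landscape <- generate_landscape(lp)
  series <- degrade(landscape, lp, dp)
  layers <- purrr::map(series, "layer")
  n_t <- length(layers)
  current <- layers[[n_t]]
  dists <- purrr::map(layers, pairwise_edge_distance)
  nets <- purrr::map2(dists, seq_len(n_t), function(d, t) {
    build_network(d, theta, timestep = attr(series, "timesteps")[t])
  })
  parts <- purrr::map(nets, network_components)
  grouping <- if (regime == "historical") {
    # ground truth: each current patch descends from a disc of one cluster
    dplyr::rename(series[[n_t]]$truth, group = "cluster")
  } else {
    dplyr::rename(parts[[n_t]], group = "component")
  }
  occ <- generate_communities(current, grouping, cp)
  m <- build_occurrence_matrix(occ, current)
  dels <- purrr::map(seq_len(n_t), function(t) {
    delineate_from_components(parts[[t]], layers[[t]], current)
  })
  list(series = series, layers = layers, current_layer = current,
       dists = dists, networks = nets, partitions = parts,
       delineations = dels, matrix = m, grouping = grouping, regime = regime)
}
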