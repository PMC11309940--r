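test_that("the generator is deterministic under a fixed seed", {
  lp <- small_lp(5)
  a <- generate_landscape(lp)
  b <- generate_landscape(lp)
  expect_identical(a$mask$grid, b$mask$grid)
  expect_identical(a$discs, b$discs)
  sa <- degrade(a, lp, small_dp(5))
  sb <- degrade(b, lp, small_dp(5))
  expect_identical(lapply(sa, function(s) s$mask$grid),
                   lapply(sb, function(s) s$mask$grid))
  cp <- community_params(s_pool = 40, seed = 5)
  grouping <- dplyr::rename(sa[[3]]$truth, group = "cluster")
  oa <- generate_communities(sa[[3]]$layer, grouping, cp)
  ob <- generate_communities(sb[[3]]$layer, grouping, cp)
  expect_identical(oa, ob)
})

test_that("degraded series are nested without harmonization", {
  for (seed in c(2, 8)) {
    lp <- small_lp(seed)
    series <- degrade(generate_landscape(lp), lp, small_dp(seed))
    for (t in seq_along(series)[-1]) {
      expect_true(all(series[[t - 1]]$mask$grid >= series[[t]]$mask$grid))
    }
    # harmonization is a no-op on the generated masks
    h <- harmonize_time_series(lapply(series, `[[`, "mask"))
    expect_identical(lapply(h, `[[`, "grid"),
                     lapply(series, function(s) s$mask$grid))
  }
})

test_that("identity degradation leaves every step equal to the first", {
  lp <- small_lp(4)
  land <- generate_landscape(lp)
  dp0 <- degradation_params(n_steps = 3, removal_prob = 0,
                            shrink_fraction = 0, split_bridges = FALSE,
                            timesteps = c(1, 2, 3), seed = 4)
  series <- degrade(land, lp, dp0)
  expect_identical(series[[1]]$mask$grid, series[[3]]$mask$grid)
  # total removal truncates the series with a warning
  dp1 <- degradation_params(n_steps = 3, removal_prob = 1,
                            shrink_fraction = 0, split_bridges = FALSE,
                            timesteps = c(1, 2, 3), seed = 4)
  expect_warning(short <- degrade(land, lp, dp1), "truncated")
  expect_length(short, 1)
})

test_that("network components at the reference threshold recover the true clusters", {
  for (seed in c(1, 7, 23)) {
    scn <- generate_landscape(small_lp(seed))
    part <- network_components(build_network(
      pairwise_edge_distance(scn$layer), 500))
    truth <- scn$truth$cluster[match(part$patch_id, scn$truth$patch_id)]
    expect_true(same_partition(part$component, truth))
  }
})

test_that("a single cluster forms one component at any tested threshold", {
  lp <- landscape_params(extent = 6000, n_clusters = 1,
                         patches_per_cluster = 6,
                         patch_radius = c(100, 140), gap_range = c(120, 180),
                         inter_cluster_gap = 1100, max_cluster_sep = 5000,
                         cell_size = 25, seed = 2)
  scn <- generate_landscape(lp)
  for (theta in c(250, 500, 2000)) {
    part <- network_components(build_network(
      pairwise_edge_distance(scn$layer), theta))
    expect_equal(max(part$component), 1)
  }
})

test_that("extreme community parameters give perfect separation", {
  lp <- small_lp(11)
  scn <- generate_landscape(lp)
  grouping <- dplyr::rename(scn$truth, group = "cluster")
  cp <- community_params(s_pool = 40, pool_overlap = 0, private_share = 0.4,
                         occupancy = 1, distance_decay = 0, noise_rate = 0,
                         seed = 11)
  occ <- generate_communities(scn$layer, grouping, cp)
  m <- build_occurrence_matrix(occ, scn$layer)
  b <- beta_matrix(m)
  same <- outer(grouping$group[match(rownames(m), grouping$patch_id)],
                grouping$group[match(rownames(m), grouping$patch_id)], "==")
  expect_true(all(b[same & upper.tri(b)] == 0))
  expect_true(all(b[!same & upper.tri(b)] == 1))
  # full overlap: all communities identical, beta saturates at 0
  cp1 <- community_params(s_pool = 40, pool_overlap = 1, occupancy = 1,
                          noise_rate = 0, seed = 11)
  occ1 <- generate_communities(scn$layer, grouping, cp1)
  b1 <- beta_matrix(build_occurrence_matrix(occ1, scn$layer))
  expect_true(all(b1 == 0))
})

test_that("default parameters put the median Jaccard dissimilarity near 0.8", {
  meds <- vapply(c(1, 2, 3), function(s) {
    ev <- suppressWarnings(suppressMessages(debt_experiment(s, "historical")))
    attr(ev, "threshold")
  }, numeric(1))
  expect_true(all(meds > 0.7 & meds < 0.9))
})

test_that("the debt signal orders delineation scores by regime", {
  # under an extinction debt the historical grouping separates beta classes
  # better; without one the current grouping does
  evh <- suppressWarnings(suppressMessages(debt_experiment(2, "historical")))
  th <- tibble::as_tibble(evh)
  expect_equal(th$timestep[th$best], 1899)
  expect_gt(th$kappa[th$timestep == 1899], th$kappa[th$timestep == 2010])
  evc <- suppressWarnings(suppressMessages(debt_experiment(2, "current")))
  tc <- tibble::as_tibble(evc)
  expect_equal(tc$timestep[tc$best], 2010)
})
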