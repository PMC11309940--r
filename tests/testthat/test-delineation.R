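# two historical patches (left, right) that each shrink into smaller current
# patches on a shared 10 m grid
two_step_layers <- function() {
  g1 <- matrix(0L, 6, 12)
  g1[2:5, 2:5] <- 1L          # H1
  g1[2:5, 8:11] <- 1L         # H2
  g2 <- matrix(0L, 6, 12)
  g2[3:4, 3:4] <- 1L          # C1 inside H1
  g2[3:4, 9:10] <- 1L         # C2 inside H2
  list(hist = label_patches(mk_mask(g1, cell = 10, timestep = 1899)),
       cur = label_patches(mk_mask(g2, cell = 10, timestep = 2010)))
}

test_that("current patches are assigned to the overlapping component", {
  ly <- two_step_layers()
  d <- pairwise_edge_distance(ly$hist)
  part <- network_components(build_network(d, 10, timestep = 1899))
  expect_equal(max(part$component), 2)       # patches 20 m apart, theta 10
  del <- delineate_from_components(part, ly$hist, ly$cur)
  expect_equal(nrow(del$membership), 2)
  expect_equal(dplyr::n_distinct(del$membership$mc_id), 2)
  expect_length(del$unassigned, 0)
  # every current patch appears exactly once
  expect_false(anyDuplicated(del$membership$patch_id) > 0)
  # stepping within theta=100: one component, both current patches together
  part1 <- network_components(build_network(d, 100, timestep = 1899))
  del1 <- delineate_from_components(part1, ly$hist, ly$cur)
  expect_equal(dplyr::n_distinct(del1$membership$mc_id), 1)
  expect_true(all(!del1$metacommunities$singleton))
})

test_that("max-overlap rule picks the dominant component", {
  g1 <- matrix(0L, 4, 12)
  g1[1:4, 1:5] <- 1L           # H1 (left)
  g1[1:4, 9:12] <- 1L          # H2 (right)
  hist <- label_patches(mk_mask(g1, cell = 10, timestep = 1899))
  # current patch spans cols 2..7: 4 cols over H1, 2 cols outside either --
  # only overlapping cells count, so it goes with H1's component
  g2 <- matrix(0L, 4, 12)
  g2[2:3, 2:7] <- 1L
  cur <- label_patches(mk_mask(g2, cell = 10, timestep = 2010))
  part <- network_components(build_network(pairwise_edge_distance(hist), 10))
  del <- delineate_from_components(part, hist, cur)
  h1_comp <- part$component[part$patch_id == hist$patch_id[1]]
  expect_equal(del$membership$mc_id,
               del$metacommunities$mc_id[h1_comp])
})

test_that("zero-overlap current patches are unassigned with a warning", {
  g1 <- matrix(0L, 4, 8); g1[1:2, 1:2] <- 1L
  g2 <- matrix(0L, 4, 8); g2[4, 7:8] <- 1L     # no ancestor habitat
  hist <- label_patches(mk_mask(g1, cell = 10, timestep = 1899))
  cur <- label_patches(mk_mask(g2, cell = 10, timestep = 2010))
  part <- network_components(build_network(pairwise_edge_distance(hist), 100))
  expect_warning(del <- delineate_from_components(part, hist, cur),
                 "unharmonized")
  expect_equal(del$unassigned, cur$patch_id)
  expect_equal(nrow(del$membership), 0)
})

test_that("the current-time delineation is the identity on current components", {
  scn <- generate_landscape(small_lp(4))
  part <- network_components(build_network(
    pairwise_edge_distance(scn$layer), 500, timestep = 2010))
  del <- delineate_from_components(part, scn$layer, scn$layer)
  memb <- dplyr::left_join(del$membership, part, by = "patch_id")
  # mc assignment refines to exactly the component partition
  expect_true(all(tapply(memb$component, memb$mc_id,
                         function(v) length(unique(v))) == 1))
  expect_equal(dplyr::n_distinct(memb$mc_id), max(part$component))
})

test_that("harmonized ancestry keeps current patches in their cluster's component", {
  lp <- small_lp(6)
  scn <- generate_landscape(lp)
  series <- degrade(scn, lp, small_dp(6))
  hist_layer <- series[[1]]$layer
  cur_layer <- series[[3]]$layer
  part <- network_components(build_network(
    pairwise_edge_distance(hist_layer), 500, timestep = 1899))
  del <- delineate_from_components(part, hist_layer, cur_layer)
  # ground truth: cluster of each current patch must match the cluster of
  # its assigned component's source patches
  truth_hist <- series[[1]]$truth
  truth_cur <- series[[3]]$truth
  for (i in seq_len(nrow(del$membership))) {
    mc <- del$membership$mc_id[i]
    src <- del$metacommunities$source_members[[
      match(mc, del$metacommunities$mc_id)]]
    src_clusters <- unique(truth_hist$cluster[truth_hist$patch_id %in% src])
    cur_cluster <- truth_cur$cluster[truth_cur$patch_id ==
                                       del$membership$patch_id[i]]
    expect_true(cur_cluster %in% src_clusters)
  }
})

test_that("polygon partitions assign patches by interior point", {
  l <- rect_layer(list(c(0, 10, 0, 10), c(20, 30, 0, 10), c(60, 70, 0, 10)))
  polys <- tibble::tibble(
    name = c("WS_A", "WS_B"),
    rings = list(list(rect_ring(0, 40, -5, 15)),
                 list(rect_ring(40, 80, -5, 15)))
  )
  del <- delineate_from_polygons(polys, l)
  expect_equal(del$membership$mc_id, c("WS_A", "WS_A", "WS_B"))
  # patch straddling the boundary follows its interior point
  l2 <- rect_layer(list(c(35, 55, 0, 10)))   # centroid at x=45 -> WS_B
  del2 <- delineate_from_polygons(polys, l2)
  expect_equal(del2$membership$mc_id, "WS_B")
  # patch outside both polygons is unassigned
  l3 <- rect_layer(list(c(100, 110, 0, 10)))
  del3 <- delineate_from_polygons(polys, l3)
  expect_length(del3$unassigned, 1)
  expect_equal(nrow(del3$membership), 0)
})

test_that("delineations export extents and membership", {
  ly <- two_step_layers()
  part <- network_components(build_network(pairwise_edge_distance(ly$hist), 10))
  del <- delineate_from_components(part, ly$hist, ly$cur)
  fg <- withr::local_tempfile(fileext = ".geojson")
  fc <- withr::local_tempfile(fileext = ".csv")
  write_delineation(del, fg, fc)
  gj <- jsonlite::read_json(fg)
  expect_equal(length(gj$features), 2)
  memb <- readr::read_csv(fc, show_col_types = FALSE)
  expect_equal(nrow(memb), 2)
})
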