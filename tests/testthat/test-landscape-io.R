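test_that("ASCII grid masks round-trip with georeferencing intact", {
  g <- matrix(rbinom(48, 1, 0.4), 6, 8)
  m <- mk_mask(g, cell = 25, timestep = 1899, xmin = 100, ymin = 200)
  f <- withr::local_tempfile(fileext = ".asc")
  write_mask_asc(m, f)
  m2 <- read_mask_asc(f, timestep = 1899)
  expect_identical(m2$grid, m$grid)
  expect_equal(m2$cell, 25)
  expect_equal(c(m2$xmin, m2$ymin), c(100, 200))
})

test_that("non-binary rasters need an explicit threshold, mismatched grids error", {
  f <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 10", "NODATA_value -9999", "0 255", "255 0"), f)
  expect_error(read_mask_asc(f), "0/1")
  m <- read_mask_asc(f, binarize_at = 128)
  expect_identical(as.vector(m$grid), c(0L, 1L, 1L, 0L))

  f1 <- withr::local_tempfile(fileext = ".asc")
  f2 <- withr::local_tempfile(fileext = ".asc")
  write_mask_asc(mk_mask(matrix(1L, 2, 2), cell = 10), f1)
  write_mask_asc(mk_mask(matrix(1L, 2, 2), cell = 20), f2)
  expect_error(read_mask_series(c(f1, f2), c(1899, 2010)), "grid mismatch")
  masks <- read_mask_series(c(f1, f1), c(1899, 2010))
  expect_length(masks, 2)
  expect_equal(masks[[1]]$timestep, 1899)
})

test_that("harmonization backward-propagates habitat and is idempotent", {
  s <- list(mk_mask(matrix(c(1, 0, 0), 1), timestep = 1),
            mk_mask(matrix(c(0, 1, 0), 1), timestep = 2),
            mk_mask(matrix(c(0, 0, 1), 1), timestep = 3))
  h <- harmonize_time_series(s)
  expect_identical(as.vector(h[[1]]$grid), c(1L, 1L, 1L))
  expect_identical(as.vector(h[[2]]$grid), c(0L, 1L, 1L))
  expect_identical(as.vector(h[[3]]$grid), c(0L, 0L, 1L))
  # already-nested series unchanged; double application is a no-op
  nested <- list(mk_mask(matrix(c(1, 1, 1), 1), timestep = 1),
                 mk_mask(matrix(c(1, 1, 0), 1), timestep = 2),
                 mk_mask(matrix(c(1, 0, 0), 1), timestep = 3))
  h2 <- harmonize_time_series(nested)
  expect_identical(lapply(h2, `[[`, "grid"), lapply(nested, `[[`, "grid"))
  hh <- harmonize_time_series(h)
  expect_identical(lapply(hh, `[[`, "grid"), lapply(h, `[[`, "grid"))
  expect_error(harmonize_time_series(rev(s)), "strictly increasing")
})

test_that("harmonization yields nested series on random inputs", {
  set.seed(7)
  for (rep in 1:25) {
    s <- lapply(1:4, function(t) mk_mask(matrix(rbinom(36, 1, 0.4), 6),
                                         timestep = t))
    h <- harmonize_time_series(s)
    for (t in 1:3) {
      expect_true(all(h[[t]]$grid >= h[[t + 1]]$grid))
    }
    expect_true(all(h[[4]]$grid == s[[4]]$grid))
  }
})

test_that("patch labeling follows the connectivity rule and partitions habitat", {
  # two 1-cell islands
  g <- matrix(0L, 3, 5); g[2, 1] <- 1L; g[2, 4] <- 1L
  expect_equal(nrow(label_patches(mk_mask(g), connectivity = 8)), 2)
  # diagonal-touching cells: one patch at 8-connectivity, two at 4
  g <- matrix(0L, 3, 3); g[1, 1] <- 1L; g[2, 2] <- 1L
  expect_equal(nrow(label_patches(mk_mask(g), connectivity = 8)), 1)
  expect_equal(nrow(label_patches(mk_mask(g), connectivity = 4)), 2)
  # 3x3 block of 10 m cells: one patch of 900 m^2
  l <- label_patches(mk_mask(matrix(1L, 3, 3), cell = 10))
  expect_equal(l$area, 900)
  expect_warning(label_patches(mk_mask(matrix(0L, 2, 2))), "empty")
  # partition property on random masks
  set.seed(11)
  for (rep in 1:10) {
    g <- matrix(rbinom(100, 1, 0.45), 10)
    l <- label_patches(mk_mask(g))
    cells <- do.call(rbind, l$geometry)
    expect_equal(nrow(cells), sum(g))           # covers all habitat
    expect_false(anyDuplicated(cells) > 0)      # disjoint
    expect_equal(sum(l$n_cells), sum(g))
  }
})

test_that("patch ids are deterministic and min_patch_area filters", {
  g <- matrix(0L, 4, 4); g[1, 1] <- 1L; g[3:4, 3:4] <- 1L
  l <- label_patches(mk_mask(g, cell = 10))
  expect_identical(l$patch_id, c("P0001", "P0002"))
  l2 <- label_patches(mk_mask(g, cell = 10), min_patch_area = 200)
  expect_equal(nrow(l2), 1)
  expect_equal(l2$area, 400)
})

test_that("occurrence CSVs are validated row by row", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,species", "1,2,a", "3,4,b", "bad,6,c", "7,8,"), f)
  expect_warning(rec <- read_occurrences(f), "malformed")
  expect_equal(nrow(rec), 2)
  writeLines("x,y,species", f)
  expect_warning(read_occurrences(f), "no valid")
  writeLines(c("x,y", "1,2"), f)
  expect_error(read_occurrences(f), "species")
})

test_that("patch layers round-trip through GeoJSON", {
  g <- matrix(0L, 5, 5); g[1:2, 1:2] <- 1L; g[4:5, 4] <- 1L
  l <- label_patches(mk_mask(g, cell = 10))
  f <- withr::local_tempfile(fileext = ".geojson")
  write_patch_geojson(l, f)
  l2 <- read_patch_geojson(f)
  expect_equal(nrow(l2), nrow(l))
  expect_identical(l2$patch_id, l$patch_id)
  expect_equal(l2$area, l$area, tolerance = 1e-6)
})
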