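#' Patch layers
#'
#' A `patch_layer` is a timestamped tibble of habitat patches with stable ids:
#' one row per patch with columns `patch_id`, `area` (m^2), `n_cells` and a
#' `geometry` list-column. Raster-derived layers keep each patch as its set of
#' grid cells (two-column matrix of row, col) plus a label grid for fast
#' point lookup; vector layers keep polygon rings (list of two-column xy
#' matrices, even-odd interior rule, so holes are supported).
#'
#' @name patch_layer
NULL

new_patch_layer <- function(tbl, kind, timestep, cell = NA_real_,
                            xmin = NA_real_, ymin = NA_real_, dim = NULL,
                            label_grid = NULL, crs = NA_character_) {
  structure(
    tbl,
    kind = kind, timestep = timestep, cell = cell, xmin = xmin, ymin = ymin,
    grid_dim = dim, label_grid = label_grid, crs = crs,
    class = c("patch_layer", class(tibble::tibble()))
  )
}

layer_kind <- function(layer) attr(layer, "kind")
layer_timestep <- function(layer) attr(layer, "timestep")

#' @export
print.patch_layer <- function(x, ...) {
  cat(sprintf("<patch_layer> %d patches, t = %s, %s\n", nrow(x),
              format(attr(x, "timestep")), attr(x, "kind")))
  NextMethod()
}

# map coordinates of cell centres; r, c vectors
cell_centre_xy <- function(meta, r, c) {
  nr <- meta$grid_dim[1]
  cbind(x = meta$xmin + (c - 0.5) * meta$cell,
        y = meta$ymin + (nr - r + 0.5) * meta$cell)
}

# row/col of the cell containing a point; closed on the outer border
xy_to_cell <- function(meta, x, y) {
  nr <- meta$grid_dim[1]; nc <- meta$grid_dim[2]
  cc <- floor((x - meta$xmin) / meta$cell) + 1
  rr <- nr - floor((y - meta$ymin) / meta$cell)
  cc[x == meta$xmin + nc * meta$cell] <- nc
  rr[y == meta$ymin + nr * meta$cell] <- 1
  ok <- cc >= 1 & cc <= nc & rr >= 1 & rr <= nr
  cbind(row = ifelse(ok, rr, NA_integer_), col = ifelse(ok, cc, NA_integer_))
}

layer_meta <- function(layer) {
  list(grid_dim = attr(layer, "grid_dim"), cell = attr(layer, "cell"),
       xmin = attr(layer, "xmin"), ymin = attr(layer, "ymin"))
}

#' Label habitat patches in a binary mask
#'
#' Maximal connected groups of habitat cells become patches. Patch ids are
#' deterministic: patches are numbered in row-major order of each patch's
#' first (top-left-most) cell, so the same mask always yields the same ids.
#'
#' @param mask A [habitat_mask()].
#' @param connectivity 8 (default; diagonally adjacent cells are one patch)
#'   or 4.
#' @param min_patch_area Optional minimum-mapping-unit filter in m^2; patches
#'   below it are dropped (default 0, keep everything).
#' @return A [patch_layer] at the mask's time step.
#' @export
label_patches <- function(mask, connectivity = 8, min_patch_area = 0) {
  stopifnot(inherits(mask, "habitat_mask"), connectivity %in% c(4, 8))
  g <- mask$grid
  nr <- nrow(g); nc <- ncol(g)
  hab <- which(g == 1L)
  meta <- list(grid_dim = c(nr, nc), cell = mask$cell,
               xmin = mask$xmin, ymin = mask$ymin)
  if (length(hab) == 0) {
    warning("empty mask: no habitat cells at t = ", format(mask$timestep))
    tbl <- tibble::tibble(patch_id = character(), area = numeric(),
                          n_cells = integer(), geometry = list())
    return(new_patch_layer(tbl, "raster", mask$timestep, mask$cell,
                           mask$xmin, mask$ymin, c(nr, nc),
                           matrix(0L, nr, nc), mask$crs))
  }
  idx <- matrix(0L, nr, nc)
  idx[hab] <- seq_along(hab)
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  edges <- list()
  rhab <- ((hab - 1L) %% nr) + 1L
  chab <- ((hab - 1L) %/% nr) + 1L
  for (o in offs) {
    r2 <- rhab + o[1]; c2 <- chab + o[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    j <- rep(0L, length(hab))
    j[ok] <- idx[cbind(r2[ok], c2[ok])]
    keep <- j > 0L
    if (any(keep)) edges[[length(edges) + 1]] <- cbind(idx[hab][keep], j[keep])
  }
  el <- if (length(edges)) do.call(rbind, edges) else matrix(0L, 0, 2)
  gr <- igraph::graph_from_edgelist(el, directed = FALSE)
  gr <- igraph::add_vertices(gr, max(0, length(hab) - igraph::vcount(gr)))
  comp <- igraph::components(gr)$membership
  # deterministic ordering by row-major (row, col) of each patch's first cell
  lin_rm <- (rhab - 1L) * nc + chab
  first_cell <- tapply(lin_rm, comp, min)
  rank <- match(comp, as.integer(names(sort(first_cell))))
  np <- max(rank)
  width <- max(4, nchar(np))
  ids <- sprintf(paste0("P%0", width, "d"), seq_len(np))
  label_grid <- matrix(0L, nr, nc)
  label_grid[hab] <- rank
  cells <- unname(split.data.frame(cbind(row = rhab, col = chab), rank))
  tbl <- tibble::tibble(
    patch_id = ids,
    area = purrr::map_dbl(cells, nrow) * mask$cell^2,
    n_cells = purrr::map_int(cells, nrow),
    geometry = purrr::map(cells, function(m) {
      m <- m[order((m[, 1] - 1L) * nc + m[, 2]), , drop = FALSE]
      storage.mode(m) <- "integer"
      m
    })
  )
  if (min_patch_area > 0) {
    drop <- tbl$area < min_patch_area
    if (any(drop)) {
      label_grid[label_grid %in% which(drop)] <- 0L
      keep_rank <- which(!drop)
      label_grid <- matrix(match(label_grid, keep_rank, nomatch = 0L), nr, nc)
      tbl <- tbl[!drop, ]
      width <- max(4, nchar(nrow(tbl)))
      tbl$patch_id <- sprintf(paste0("P%0", width, "d"), seq_len(nrow(tbl)))
    }
  }
  new_patch_layer(tbl, "raster", mask$timestep, mask$cell, mask$xmin,
                  mask$ymin, c(nr, nc), label_grid, mask$crs)
}

#' Build a patch layer directly from polygon features
#'
#' @param patch_id Character vector of unique ids.
#' @param rings List (one element per patch) of lists of two-column xy
#'   matrices; interior by the even-odd rule (GeoJSON hole convention).
#' @param timestep Time label.
#' @param crs Optional CRS identifier.
#' @return A vector-kind [patch_layer].
#' @export
patch_layer_from_polygons <- function(patch_id, rings, timestep = NA,
                                      crs = NA_character_) {
  stopifnot(length(patch_id) == length(rings), !anyDuplicated(patch_id))
  areas <- purrr::map_dbl(rings, polys_area)
  if (any(!is.finite(areas)) || any(areas <= 0)) {
    stop("invalid or empty geometry for patch ",
         patch_id[which(!is.finite(areas) | areas <= 0)[1]])
  }
  tbl <- tibble::tibble(patch_id = as.character(patch_id), area = areas,
                        n_cells = NA_integer_, geometry = rings)
  new_patch_layer(tbl, "vector", timestep, crs = crs)
}

#' Read a patch layer from GeoJSON
#'
#' Expects a FeatureCollection of Polygon/MultiPolygon features carrying a
#' `patch_id` property.
#'
#' @param path GeoJSON file.
#' @param timestep Time label to attach.
#' @return A vector-kind [patch_layer].
#' @export
read_patch_geojson <- function(path, timestep = NA) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  if (is.null(feats)) stop("not a FeatureCollection: ", path)
  ids <- purrr::map_chr(feats, function(f) {
    id <- f$properties$patch_id
    if (is.null(id)) stop("feature without patch_id in ", path)
    as.character(id)
  })
  rings <- purrr::map(feats, function(f) geojson_rings(f$geometry))
  patch_layer_from_polygons(ids, rings, timestep = timestep)
}

geojson_rings <- function(geom) {
  coord_mat <- function(ring) {
    m <- do.call(rbind, purrr::map(ring, function(p) c(p[[1]], p[[2]])))
    colnames(m) <- c("x", "y")
    # drop the closing vertex; rings are treated as implicitly closed
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    m
  }
  if (geom$type == "Polygon") {
    purrr::map(geom$coordinates, coord_mat)
  } else if (geom$type == "MultiPolygon") {
    purrr::flatten(purrr::map(geom$coordinates, function(poly) {
      purrr::map(poly, coord_mat)
    }))
  } else {
    stop("unsupported geometry type: ", geom$type)
  }
}

#' Write a patch layer to GeoJSON
#'
#' Raster patches are written as MultiPolygons of their cell squares, which
#' preserves ids and areas exactly on a round trip; vector patches are written
#' with their original rings.
#'
#' @param layer A [patch_layer].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_patch_geojson <- function(layer, path) {
  stopifnot(inherits(layer, "patch_layer"))
  meta <- layer_meta(layer)
  feats <- purrr::map(seq_len(nrow(layer)), function(i) {
    geom <- if (layer_kind(layer) == "raster") {
      cells <- layer$geometry[[i]]
      ctr <- cell_centre_xy(meta, cells[, 1], cells[, 2])
      h <- meta$cell / 2
      coords <- purrr::map(seq_len(nrow(ctr)), function(k) {
        x <- ctr[k, 1]; y <- ctr[k, 2]
        list(list(
          list(x - h, y - h), list(x + h, y - h), list(x + h, y + h),
          list(x - h, y + h), list(x - h, y - h)
        ))
      })
      list(type = "MultiPolygon", coordinates = coords)
    } else {
      rings <- purrr::map(layer$geometry[[i]], function(m) {
        m <- rbind(m, m[1, ])
        purrr::map(seq_len(nrow(m)), function(k) list(m[k, 1], m[k, 2]))
      })
      list(type = "Polygon", coordinates = rings)
    }
    list(type = "Feature",
         properties = list(patch_id = layer$patch_id[i],
                           area = layer$area[i]),
         geometry = geom)
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rasterize a vector patch layer onto a grid
#'
#' Lets vector inputs join the raster pipeline (harmonization, component
#' delineation). A cell belongs to a patch when its centre is interior to the
#' patch polygon (even-odd rule).
#'
#' @param layer Vector-kind [patch_layer].
#' @param cell Cell size (m).
#' @param xmin,ymin Grid origin.
#' @param dim `c(nrow, ncol)` of the target grid.
#' @return A [habitat_mask()] at the layer's time step.
#' @export
rasterize_patches <- function(layer, cell, xmin, ymin, dim) {
  stopifnot(inherits(layer, "patch_layer"), layer_kind(layer) == "vector")
  nr <- dim[1]; nc <- dim[2]
  g <- matrix(0L, nr, nc)
  cc <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  meta <- list(grid_dim = c(nr, nc), cell = cell, xmin = xmin, ymin = ymin)
  ctr <- cell_centre_xy(meta, cc$row, cc$col)
  for (i in seq_len(nrow(layer))) {
    inside <- point_in_polys(ctr[, 1], ctr[, 2], layer$geometry[[i]])
    g[cbind(cc$row[inside], cc$col[inside])] <- 1L
  }
  habitat_mask(g, cell = cell, xmin = xmin, ymin = ymin,
               timestep = layer_timestep(layer))
}
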