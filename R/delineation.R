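#' Metacommunity delineations
#'
#' A `delineation` partitions the current-time patches into candidate
#' metacommunities, either from the connected components of a (historical or
#' current) habitat network or from abiotic polygons such as watersheds. The
#' extent polygons (convex hulls of member geometries) are for reporting
#' only: all scoring uses membership, because metacommunity boundaries are
#' fuzzy and the hull geometry itself carries no information.
#'
#' @name delineation
NULL

new_delineation <- function(membership, metacommunities, unassigned, source) {
  structure(list(membership = membership, metacommunities = metacommunities,
                 unassigned = unassigned, source = source),
            class = "delineation")
}

#' @export
print.delineation <- function(x, ...) {
  src <- x$source
  lab <- if (src$type == "network") {
    sprintf("network(t = %s, theta = %g)", format(src$timestep), src$theta)
  } else {
    sprintf("polygons(%s)", src$name)
  }
  cat(sprintf("<delineation> %s: %d metacommunities (%d singleton), %d assigned, %d unassigned\n",
              lab, nrow(x$metacommunities), sum(x$metacommunities$singleton),
              nrow(x$membership), length(x$unassigned)))
  invisible(x)
}

delineation_label <- function(d) {
  src <- d$source
  if (src$type == "network") {
    sprintf("network_%s_theta%g", format(src$timestep), src$theta)
  } else {
    sprintf("polygons_%s", src$name)
  }
}

#' Delineate metacommunities from network components
#'
#' Each component of the source network becomes one metacommunity. Every
#' current patch is assigned to the metacommunity whose member patches (at
#' the source time step) maximally overlap it, measured in shared habitat
#' cells; after harmonization every current habitat cell is habitat at all
#' earlier steps, so each current patch is wholly covered and the assignment
#' is effectively by ancestry. Overlap ties are broken by distance to the
#' nearest member patch, then lexicographically by metacommunity id. Current
#' patches overlapping no component (possible only on unharmonized input) go
#' to `unassigned` with a warning.
#'
#' @param partition A [network_components()] result for the source network.
#' @param source_layer The [patch_layer] the source network was built from.
#' @param current_layer The current-time [patch_layer] (same grid).
#' @return A [delineation].
#' @export
delineate_from_components <- function(partition, source_layer, current_layer) {
  stopifnot(inherits(partition, "component_partition"),
            inherits(source_layer, "patch_layer"),
            inherits(current_layer, "patch_layer"))
  if (nrow(partition) == 0) stop("empty component partition")
  if (layer_kind(source_layer) != "raster" ||
      layer_kind(current_layer) != "raster") {
    stop("component delineation requires raster-derived layers on one grid")
  }
  if (!isTRUE(all.equal(layer_meta(source_layer), layer_meta(current_layer)))) {
    stop("source and current layers are not on the same grid")
  }
  ncomp <- max(partition$component)
  width <- max(3, nchar(ncomp))
  mc_ids <- sprintf(paste0("MC%0", width, "d"), seq_len(ncomp))
  comp_of_source <- partition$component[match(source_layer$patch_id,
                                              partition$patch_id)]
  src_lab <- attr(source_layer, "label_grid")
  assign_mc <- purrr::map_chr(seq_len(nrow(current_layer)), function(i) {
    cells <- current_layer$geometry[[i]]
    labs <- src_lab[cells]
    labs <- labs[labs > 0L]
    if (!length(labs)) return(NA_character_)
    comp_counts <- table(comp_of_source[labs])
    best <- as.integer(names(comp_counts)[comp_counts == max(comp_counts)])
    if (length(best) > 1) {
      # nearest member patch boundary, then lexicographic mc_id
      dd <- purrr::map_dbl(best, function(cp) {
        mem <- which(comp_of_source == cp)
        min(purrr::map_dbl(mem, function(s) {
          cell_sets_min_dist(
            cell_centre_xy(layer_meta(current_layer), cells[, 1], cells[, 2]),
            cell_centre_xy(layer_meta(source_layer),
                           source_layer$geometry[[s]][, 1],
                           source_layer$geometry[[s]][, 2]),
            attr(current_layer, "cell"))
        }))
      })
      best <- best[order(dd, best)][1]
    }
    mc_ids[best]
  })
  if (any(is.na(assign_mc))) {
    warning(sum(is.na(assign_mc)),
            " current patch(es) overlap no component (unharmonized input?)")
  }
  membership <- tibble::tibble(patch_id = current_layer$patch_id,
                               mc_id = assign_mc) |>
    dplyr::filter(!is.na(.data$mc_id))
  meta_tbl <- tibble::tibble(mc_id = mc_ids) |>
    dplyr::mutate(
      source_members = purrr::map(seq_len(ncomp), function(k) {
        partition$patch_id[partition$component == k]
      }),
      n_source_patches = purrr::map_int(.data$source_members, length),
      total_source_area = purrr::map_dbl(.data$source_members, function(ids) {
        sum(source_layer$area[match(ids, source_layer$patch_id)])
      }),
      members = purrr::map(.data$mc_id, function(id) {
        membership$patch_id[membership$mc_id == id]
      }),
      n_members = purrr::map_int(.data$members, length),
      singleton = .data$n_members < 2,
      extent = purrr::map(seq_len(ncomp), function(k) {
        idx <- match(.data$source_members[[k]], source_layer$patch_id)
        hull_ring(do.call(rbind, purrr::map(idx, function(s) {
          patch_points(source_layer, s)
        })))
      })
    )
  new_delineation(
    membership, meta_tbl, current_layer$patch_id[is.na(assign_mc)],
    list(type = "network", timestep = attr(partition, "timestep"),
         theta = attr(partition, "theta"), name = NA_character_)
  )
}

#' Read named partition polygons (e.g. watersheds) from GeoJSON
#'
#' Features need a `name` (or `patch_id`) property.
#'
#' @param path GeoJSON FeatureCollection of Polygon/MultiPolygon features.
#' @return Tibble with `name` and a `rings` list-column.
#' @export
read_polygons_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  if (is.null(feats)) stop("not a FeatureCollection: ", path)
  tibble::tibble(
    name = purrr::map_chr(feats, function(f) {
      nm <- f$properties$name %||% f$properties$patch_id
      if (is.null(nm)) stop("feature without name in ", path)
      as.character(nm)
    }),
    rings = purrr::map(feats, function(f) geojson_rings(f$geometry))
  )
}

#' Delineate metacommunities from an abiotic polygon partition
#'
#' Each polygon (e.g. a watershed defined from contour lines) becomes one
#' metacommunity; a current patch joins the polygon containing its
#' representative interior point (default) or, with `method = "overlap"`,
#' the polygon covering most of its cells. Patches outside every polygon are
#' unassigned.
#'
#' @param polygons Tibble from [read_polygons_geojson()] (`name`, `rings`).
#' @param current_layer The current-time [patch_layer].
#' @param method `"point"` (interior point, default) or `"overlap"`
#'   (majority cell cover, raster layers only).
#' @return A [delineation].
#' @export
delineate_from_polygons <- function(polygons, current_layer,
                                    method = c("point", "overlap")) {
  method <- match.arg(method)
  stopifnot(inherits(current_layer, "patch_layer"), nrow(polygons) > 0)
  np <- nrow(polygons)
  assign_mc <- rep(NA_character_, nrow(current_layer))
  if (method == "point") {
    pts <- t(vapply(seq_len(nrow(current_layer)), function(i) {
      patch_interior_point(current_layer, i)
    }, numeric(2)))
    for (k in seq_len(np)) {
      free <- which(is.na(assign_mc))
      if (!length(free)) break
      inside <- point_in_polys(pts[free, 1], pts[free, 2],
                               polygons$rings[[k]])
      assign_mc[free[inside]] <- polygons$name[k]
    }
  } else {
    if (layer_kind(current_layer) != "raster") {
      stop("overlap assignment requires a raster layer")
    }
    meta <- layer_meta(current_layer)
    for (i in seq_len(nrow(current_layer))) {
      cells <- current_layer$geometry[[i]]
      ctr <- cell_centre_xy(meta, cells[, 1], cells[, 2])
      cover <- vapply(seq_len(np), function(k) {
        sum(point_in_polys(ctr[, 1], ctr[, 2], polygons$rings[[k]]))
      }, numeric(1))
      if (any(cover > 0)) assign_mc[i] <- polygons$name[which.max(cover)]
    }
  }
  membership <- tibble::tibble(patch_id = current_layer$patch_id,
                               mc_id = assign_mc) |>
    dplyr::filter(!is.na(.data$mc_id))
  meta_tbl <- tibble::tibble(mc_id = polygons$name) |>
    dplyr::mutate(
      source_members = purrr::map(.data$mc_id, function(...) character()),
      n_source_patches = NA_integer_,
      total_source_area = purrr::map_dbl(polygons$rings, polys_area),
      members = purrr::map(.data$mc_id, function(id) {
        membership$patch_id[membership$mc_id == id]
      }),
      n_members = purrr::map_int(.data$members, length),
      singleton = .data$n_members < 2,
      extent = purrr::map(polygons$rings, function(r) hull_ring(do.call(rbind, r)))
    )
  new_delineation(
    membership, meta_tbl, current_layer$patch_id[is.na(assign_mc)],
    list(type = "polygons", timestep = NA, theta = NA_real_,
         name = paste(substr(polygons$name[1], 1, 2), "partition"))
  )
}

#' Export a delineation as GeoJSON extents plus a membership CSV
#'
#' @param d A [delineation].
#' @param geojson_path,csv_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_delineation <- function(d, geojson_path, csv_path) {
  feats <- purrr::map(seq_len(nrow(d$metacommunities)), function(k) {
    ring <- d$metacommunities$extent[[k]]
    ring <- rbind(ring, ring[1, ])
    list(type = "Feature",
         properties = list(mc_id = d$metacommunities$mc_id[k],
                           singleton = d$metacommunities$singleton[k],
                           n_members = d$metacommunities$n_members[k]),
         geometry = list(type = "Polygon", coordinates = list(
           purrr::map(seq_len(nrow(ring)), function(i) {
             list(ring[i, 1], ring[i, 2])
           }))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       geojson_path, auto_unbox = TRUE, digits = NA)
  src <- d$source
  readr::write_csv(
    dplyr::mutate(d$membership, source = src$type,
                  timestep = format(src$timestep), theta = src$theta),
    csv_path)
  invisible(c(geojson_path, csv_path))
}
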