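#' Read species occurrence records
#'
#' Expects a CSV with at least the columns `x`, `y`, `species` (planar metres
#' and a non-empty species name). Malformed rows (non-numeric coordinates,
#' blank species) are skipped with a warning naming their line numbers; an
#' optional `site_id` column is ignored.
#'
#' @param path CSV file.
#' @return A tibble `x`, `y`, `species`.
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("x", "y", "species")
  if (!all(need %in% names(raw))) {
    stop("occurrence file must have columns x, y, species; missing: ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  }
  x <- suppressWarnings(as.numeric(raw$x))
  y <- suppressWarnings(as.numeric(raw$y))
  sp <- as.character(raw$species)
  bad <- !is.finite(x) | !is.finite(y) | is.na(sp) | !nzchar(sp)
  if (any(bad)) {
    warning(sum(bad), " malformed occurrence row(s) skipped (lines ",
            paste(utils::head(which(bad) + 1L, 10), collapse = ", "),
            if (sum(bad) > 10) ", ..." else "", ")")
  }
  out <- tibble::tibble(x = x[!bad], y = y[!bad], species = sp[!bad])
  if (nrow(out) == 0) warning("no valid occurrence records in ", path)
  out
}

#' Build the patch-by-species presence/absence matrix
#'
#' Each record contributes a presence of its species to the patch containing
#' its point (closed containment: boundary points belong to the patch).
#' Repeat observations collapse to a single presence — monitoring revisits
#' carry no abundance information here. Points outside all patches are
#' dropped and counted; patches without any record are omitted, so every
#' retained patch has at least one species.
#'
#' @param records Tibble from [read_occurrences()] (columns `x`, `y`,
#'   `species`).
#' @param layer The current-time [patch_layer].
#' @return Binary matrix (patches x species, dimnames set) of class
#'   `occurrence_matrix`; attribute `n_dropped` counts unassigned points.
#' @export
build_occurrence_matrix <- function(records, layer) {
  stopifnot(inherits(layer, "patch_layer"), nrow(layer) > 0)
  n <- nrow(records)
  pid <- rep(NA_character_, n)
  if (n > 0) {
    if (layer_kind(layer) == "raster") {
      meta <- layer_meta(layer)
      rc <- xy_to_cell(meta, records$x, records$y)
      lg <- attr(layer, "label_grid")
      ok <- !is.na(rc[, 1])
      lab <- rep(0L, n)
      lab[ok] <- lg[cbind(rc[ok, 1], rc[ok, 2])]
      pid[lab > 0L] <- layer$patch_id[lab[lab > 0L]]
    } else {
      left <- seq_len(n)
      for (i in seq_len(nrow(layer))) {
        if (!length(left)) break
        inside <- point_in_polys(records$x[left], records$y[left],
                                 layer$geometry[[i]])
        pid[left[inside]] <- layer$patch_id[i]
        left <- left[!inside]
      }
    }
  }
  dropped <- sum(is.na(pid))
  if (dropped > 0) {
    message(dropped, " occurrence point(s) fell outside all patches and were dropped")
  }
  keep <- !is.na(pid)
  if (!any(keep)) {
    warning("no occurrence point falls inside a patch; empty matrix")
    m <- matrix(0L, 0, 0)
    return(structure(m, n_dropped = dropped, class = "occurrence_matrix"))
  }
  tab <- unique(tibble::tibble(patch_id = pid[keep],
                               species = records$species[keep]))
  patches <- layer$patch_id[layer$patch_id %in% tab$patch_id]
  species <- sort(unique(tab$species))
  m <- matrix(0L, length(patches), length(species),
              dimnames = list(patches, species))
  m[cbind(match(tab$patch_id, patches), match(tab$species, species))] <- 1L
  structure(m, n_dropped = dropped, class = "occurrence_matrix")
}

#' Jaccard dissimilarity between two patches
#'
#' `beta = 1 - |shared| / |union|` over the two patches' species sets: 0 for
#' identical composition, 1 for disjoint. The presence/absence form is used
#' throughout (no abundance data).
#'
#' @param m An [build_occurrence_matrix()] result.
#' @param i,j Patch ids (rownames of `m`).
#' @return Dissimilarity in `[0, 1]`; `NA` with a warning when a patch has an
#'   empty species set.
#' @export
jaccard_beta <- function(m, i, j) {
  si <- m[i, ] > 0; sj <- m[j, ] > 0
  if (!any(si) || !any(sj)) {
    warning("patch with empty species set: beta undefined")
    return(NA_real_)
  }
  1 - sum(si & sj) / sum(si | sj)
}

#' All pairwise Jaccard dissimilarities
#'
#' @param m An [build_occurrence_matrix()] result.
#' @return Symmetric matrix of dissimilarities with zero diagonal and the
#'   patch ids as dimnames.
#' @export
beta_matrix <- function(m) {
  if (nrow(m) < 2) stop("need at least two patches with species data")
  b <- as.matrix(vegan::vegdist(unclass(m), method = "jaccard",
                                binary = TRUE))
  dimnames(b) <- list(rownames(m), rownames(m))
  b
}

#' Gamma diversity of a patch set
#'
#' Total species richness (size of the union of species sets) over the member
#' patches of a delineated metacommunity. Members absent from the matrix
#' (no species data) are ignored.
#'
#' @param m An [build_occurrence_matrix()] result.
#' @param members Patch ids.
#' @return Integer species count; `NA` when no member has data.
#' @export
gamma_richness <- function(m, members) {
  rows <- intersect(members, rownames(m))
  if (!length(rows)) return(NA_integer_)
  sum(colSums(m[rows, , drop = FALSE]) > 0)
}

#' Export a wide binary or dissimilarity matrix as CSV
#'
#' @param m Matrix with dimnames.
#' @param path Output CSV (id column first).
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  tbl <- tibble::as_tibble(as.data.frame(unclass(m)), rownames = "id")
  num <- vapply(tbl, is.double, logical(1))
  tbl[num] <- lapply(tbl[num], num12)
  readr::write_csv(tbl, path)
  invisible(path)
}
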