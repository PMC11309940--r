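#' Habitat mask
#'
#' A binary raster snapshot of habitat at one time step. The grid is stored as
#' an integer matrix with row 1 at the *top* (north); the affine placement is
#' axis-aligned: cell centre of `grid[r, c]` sits at
#' `x = xmin + (c - 0.5) * cell`, `y = ymin + (nrow - r + 0.5) * cell`.
#' All coordinates are planar metres (a projected CRS is assumed throughout;
#' no geodesic computation is performed).
#'
#' @param grid Integer/numeric matrix of 0/1 values (1 = habitat).
#' @param cell Cell size in metres (single positive number; square cells).
#' @param xmin,ymin Map coordinates of the lower-left corner of the grid.
#' @param timestep Ordinal time label (e.g. a year).
#' @param crs Optional CRS identifier carried through unchanged.
#'
#' @return An object of class `habitat_mask`.
#' @export
habitat_mask <- function(grid, cell, xmin = 0, ymin = 0, timestep = NA,
                         crs = NA_character_) {
  stopifnot(is.matrix(grid), is.numeric(cell), length(cell) == 1, cell > 0)
  vals <- unique(as.vector(grid))
  if (!all(vals %in% c(0L, 1L))) {
    stop("habitat mask values must be 0/1; configure `binarize_at` when reading")
  }
  storage.mode(grid) <- "integer"
  structure(
    list(grid = grid, cell = as.numeric(cell), xmin = as.numeric(xmin),
         ymin = as.numeric(ymin), timestep = timestep, crs = crs),
    class = "habitat_mask"
  )
}

#' @export
print.habitat_mask <- function(x, ...) {
  cat(sprintf("<habitat_mask> %d x %d cells, cell %g m, t = %s, %d habitat cells\n",
              nrow(x$grid), ncol(x$grid), x$cell, format(x$timestep),
              sum(x$grid)))
  invisible(x)
}

#' Read a raster mask from an ESRI ASCII grid file
#'
#' Plain-text `.asc` rasters carry their georeferencing in a six-line header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`)
#' followed by rows of cell values, north row first.
#'
#' @param path Path to the `.asc` file.
#' @param timestep Time label to attach.
#' @param binarize_at Optional numeric threshold: values `>= binarize_at`
#'   become 1, others 0. Without it, non-0/1 values are an error (silent
#'   coercion is forbidden).
#' @param crs Optional CRS identifier.
#' @return A [habitat_mask()].
#' @export
read_mask_asc <- function(path, timestep = NA, binarize_at = NULL,
                          crs = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("malformed ASCII grid header in ", path)
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc) {
    stop("grid body of ", path, " has ", length(vals), " values, expected ",
         nr * nc)
  }
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- 0
  grid <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(binarize_at)) {
    grid <- (grid >= binarize_at) + 0L
  }
  habitat_mask(grid, cell = hdr$cellsize, xmin = hdr$xllcorner,
               ymin = hdr$yllcorner, timestep = timestep, crs = crs)
}

#' Write a habitat mask as an ESRI ASCII grid
#'
#' @param mask A [habitat_mask()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_asc <- function(mask, path) {
  stopifnot(inherits(mask, "habitat_mask"))
  hdr <- c(
    sprintf("ncols %d", ncol(mask$grid)),
    sprintf("nrows %d", nrow(mask$grid)),
    sprintf("xllcorner %.6f", mask$xmin),
    sprintf("yllcorner %.6f", mask$ymin),
    sprintf("cellsize %.6f", mask$cell),
    "NODATA_value -9999"
  )
  body <- apply(mask$grid, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a time-ordered series of raster masks
#'
#' All files must share grid shape, cell size and origin; a mismatch is a hard
#' error naming the offending file.
#'
#' @param paths Character vector of `.asc` paths, one per time step.
#' @param labels Strictly increasing ordinal time labels, same length.
#' @inheritParams read_mask_asc
#' @return A list of [habitat_mask()] objects ordered by `labels`.
#' @export
read_mask_series <- function(paths, labels, binarize_at = NULL,
                             crs = NA_character_) {
  stopifnot(length(paths) == length(labels))
  ord <- order(labels)
  paths <- paths[ord]; labels <- labels[ord]
  masks <- purrr::map2(paths, labels, function(p, l) {
    read_mask_asc(p, timestep = l, binarize_at = binarize_at, crs = crs)
  })
  ref <- masks[[1]]
  for (k in seq_along(masks)[-1]) {
    m <- masks[[k]]
    if (!identical(dim(m$grid), dim(ref$grid)) ||
        !isTRUE(all.equal(c(m$cell, m$xmin, m$ymin),
                          c(ref$cell, ref$xmin, ref$ymin)))) {
      stop("grid mismatch: ", paths[k], " does not align with ", paths[1])
    }
    if (!identical(is.na(m$crs), is.na(ref$crs)) ||
        (!is.na(m$crs) && m$crs != ref$crs)) {
      stop("CRS mismatch: ", paths[k])
    }
  }
  masks
}

#' Harmonize a habitat time series (backward propagation)
#'
#' Habitat is assumed only ever to be lost, never gained. Any cell that is
#' habitat at some time step is therefore forced to be habitat at every
#' earlier step: the output at time *t* is the cell-wise union of the inputs
#' at all times >= *t*. The latest mask is unchanged and the operation is
#' idempotent. This corrects digitisation misalignment between map series of
#' different vintages.
#'
#' @param masks Time-ordered list of [habitat_mask()] with strictly
#'   increasing `timestep` labels and identical grids.
#' @return List of harmonized masks, same order.
#' @export
harmonize_time_series <- function(masks) {
  stopifnot(length(masks) >= 2)
  labs <- purrr::map_dbl(masks, function(m) as.numeric(m$timestep))
  if (any(is.na(labs)) || any(diff(labs) <= 0)) {
    stop("timestep labels must be strictly increasing")
  }
  for (m in masks[-1]) {
    if (!identical(dim(m$grid), dim(masks[[1]]$grid))) {
      stop("grid mismatch within mask series")
    }
  }
  acc <- masks[[length(masks)]]$grid
  out <- masks
  for (k in rev(seq_along(masks))) {
    acc <- pmax(acc, masks[[k]]$grid)
    out[[k]]$grid <- acc
    storage.mode(out[[k]]$grid) <- "integer"
  }
  out
}
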