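#' Vegetation grids
#'
#' A `veg_grid` is the habitat map of the model: a matrix of per-cell entry
#' probabilities on a square lattice of (by default) 10 m cells. Entry
#' probabilities take one of three legal values describing vegetation
#' quality: 1.0 ("good"), 0.1 ("poor") and 0 ("no-go"). The probability
#' governs the crossing rule between adjacent cells during diffusion (see
#' [diffuse_step()]).
#'
#' @param entry numeric matrix of entry probabilities.
#' @param cell_size cell edge length in metres (default 10).
#' @param layout a short tag describing how the grid was built
#'   (`"block"`, `"band"`, `"checkerboard"`, `"serpentine"`, `"custom"`).
#' @param band_path optional integer vector of linear cell indices tracing
#'   the medial axis of a band in path order; used for even placement of
#'   baits along bands.
#' @param band_width band width in cells, or `NA`.
#' @param strict if `TRUE` (default), entry probabilities must be one of
#'   1.0, 0.1, 0.
#'
#' @return An object of class `veg_grid`: a list with elements `entry`,
#'   `cell_size`, `layout`, `band_path`, `band_width`.
#' @seealso [make_block()], [make_band()], [make_checkerboard()]
#' @export
veg_grid <- function(entry, cell_size = 10, layout = "custom",
                     band_path = NULL, band_width = NA_real_,
                     strict = TRUE) {
  if (!is.matrix(entry) || !is.numeric(entry))
    stop("`entry` must be a numeric matrix")
  if (nrow(entry) < 1L || ncol(entry) < 1L)
    stop("grid must be at least 1x1")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  if (anyNA(entry) || any(entry < 0) || any(entry > 1))
    stop("entry probabilities must lie in [0, 1]")
  if (strict && !all(entry %in% c(1, 0.1, 0)))
    stop("entry probabilities must be 1.0 (good), 0.1 (poor) or 0 (no-go); ",
         "use strict = FALSE to allow other values")
  structure(
    list(entry = entry, cell_size = cell_size, layout = layout,
         band_path = band_path, band_width = band_width),
    class = "veg_grid")
}

#' @export
print.veg_grid <- function(x, ...) {
  s <- geometry_summary(x)
  cat(sprintf("<veg_grid> %d x %d cells of %g m (%s layout)\n",
              nrow(x$entry), ncol(x$entry), x$cell_size, x$layout))
  cat(sprintf("  good %.4f km^2 | poor %.4f km^2 | no-go %.4f km^2\n",
              s$good_area_km2, s$poor_area_km2, s$nogo_area_km2))
  invisible(x)
}

#' @export
dim.veg_grid <- function(x) dim(x$entry)

is_veg_grid <- function(x) inherits(x, "veg_grid")

stopifnot_grid <- function(grid) {
  if (!is_veg_grid(grid)) stop("expected a `veg_grid` object")
  invisible(grid)
}

#' Linear indices of good cells (entry probability 1)
#' @param grid a [veg_grid()].
#' @return integer vector of linear (column-major) indices.
#' @export
good_cells <- function(grid) {
  stopifnot_grid(grid)
  which(grid$entry == 1)
}

#' Geometry summary of a vegetation grid
#'
#' Areas of each vegetation class in km^2, the band width if known, and the
#' layout tag. The good area normalises catches "per square kilometre of
#' good habitat" in the experiment drivers.
#'
#' @param grid a [veg_grid()].
#' @return a list with `good_area_km2`, `poor_area_km2`, `nogo_area_km2`,
#'   `band_width_m`, `layout`, `n_cells`.
#' @export
geometry_summary <- function(grid) {
  stopifnot_grid(grid)
  a_cell <- (grid$cell_size / 1000)^2     # km^2 per cell
  e <- grid$entry
  list(good_area_km2 = sum(e == 1) * a_cell,
       poor_area_km2 = sum(e == 0.1) * a_cell,
       nogo_area_km2 = sum(e == 0) * a_cell,
       band_width_m = if (is.na(grid$band_width)) NA_real_ else
         grid$band_width * grid$cell_size,
       layout = grid$layout,
       n_cells = length(e))
}

#' Connected components of the good habitat
#'
#' Good cells are connected through their four orthogonal neighbours. Grids
#' whose good habitat splits into several components are legal (flies are
#' seeded per component by [stationary_field()]) but most experiments expect
#' a single component.
#'
#' @param grid a [veg_grid()].
#' @return integer vector, one component label per good cell, with the good
#'   cell linear indices as names; `attr(, "n_components")` gives the count.
#' @export
good_components <- function(grid) {
  stopifnot_grid(grid)
  gc <- good_cells(grid)
  if (length(gc) == 0L) {
    out <- integer(0)
    attr(out, "n_components") <- 0L
    return(out)
  }
  nr <- nrow(grid$entry)
  pos <- match(gc, gc)
  # orthogonal neighbour pairs among good cells
  r <- (gc - 1L) %% nr + 1L
  co <- (gc - 1L) %/% nr + 1L
  edges <- NULL
  # right neighbour
  nb <- gc + nr
  ok <- co < ncol(grid$entry) & !is.na(match(nb, gc))
  e1 <- cbind(pos[ok], match(nb[ok], gc))
  # down neighbour
  nb <- gc + 1L
  ok <- r < nr & !is.na(match(nb, gc))
  e2 <- cbind(pos[ok], match(nb[ok], gc))
  edges <- rbind(e1, e2)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(gc) - igraph::vcount(g)))
  comp <- igraph::components(g)
  out <- comp$membership[seq_along(gc)]
  names(out) <- gc
  attr(out, "n_components") <- comp$no
  out
}

# ---- plain-text raster I/O ---------------------------------------------

#' Read / write vegetation grids as ESRI-ASCII-style rasters
#'
#' The format is the plain-text ARC/INFO ASCII grid: a six-line header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`)
#' followed by one row of cell values per line, northernmost row first.
#' Values are the entry probabilities.
#'
#' @param grid a [veg_grid()].
#' @param path file path.
#' @param strict passed to [veg_grid()] on read.
#' @return `read_grid_asc()` returns a [veg_grid()]; `write_grid_asc()`
#'   returns `path` invisibly.
#' @export
write_grid_asc <- function(grid, path) {
  stopifnot_grid(grid)
  e <- grid$entry
  hdr <- c(sprintf("ncols %d", ncol(e)),
           sprintf("nrows %d", nrow(e)),
           "xllcorner 0",
           "yllcorner 0",
           sprintf("cellsize %g", grid$cell_size),
           "NODATA_value -9999")
  rows <- apply(e, 1L, function(v) paste(format(v, trim = TRUE), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_grid_asc
#' @export
read_grid_asc <- function(path, strict = TRUE) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  for (k in c("ncols", "nrows", "cellsize"))
    if (!k %in% keys) stop("malformed ASCII grid header: missing ", k)
  nc <- as.integer(vals[["ncols"]]); nr <- as.integer(vals[["nrows"]])
  body <- lines[-(1:6)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != nr) stop("expected ", nr, " data rows, found ", length(body))
  e <- do.call(rbind, lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  if (ncol(e) != nc) stop("row length does not match ncols")
  veg_grid(e, cell_size = vals[["cellsize"]], layout = "custom", strict = strict)
}

#' Read / write vegetation grids as CSV
#'
#' A headerless CSV of entry probabilities, one grid row per line.
#'
#' @inheritParams write_grid_asc
#' @param cell_size cell size in m used when reading (default 10).
#' @export
write_grid_csv <- function(grid, path) {
  stopifnot_grid(grid)
  utils::write.table(grid$entry, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path, cell_size = 10, strict = TRUE) {
  e <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(e) <- NULL
  veg_grid(e, cell_size = cell_size, strict = strict)
}
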