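#' Habitat layouts
#'
#' Builders for the standard habitat geometries of the model, all on a
#' (default) 200 x 200 grid of 10 m cells representing a 2 x 2 km map:
#' square blocks of good vegetation, bands flanked by poorer vegetation,
#' checkerboards of good and poor blocks, and serpentine bands that fold a
#' long band into the map by right-angle bends.
#'
#' @name landscapes
NULL

.veg_value <- function(x) {
  switch(match.arg(x, c("good", "poor", "nogo", "no-go")),
         good = 1, poor = 0.1, nogo = 0, `no-go` = 0)
}

#' Square block of good habitat
#'
#' A `width_cells` x `width_cells` block of good cells centred on the map,
#' surrounded by poor or no-go vegetation. `width_cells` equal to the map
#' width gives the homogeneous "large block" reference habitat.
#'
#' @param width_cells block edge length in cells (1 to the map width).
#' @param outside vegetation outside the block: `"poor"` or `"nogo"`.
#' @param n_rows,n_cols map dimensions in cells.
#' @param cell_size cell edge length in m.
#' @return a [veg_grid()].
#' @export
make_block <- function(width_cells, outside = c("poor", "nogo"),
                       n_rows = 200, n_cols = 200, cell_size = 10) {
  outside <- match.arg(outside)
  w <- as.integer(width_cells)
  if (w < 1L || w > min(n_rows, n_cols))
    stop("block width must be between 1 and the map width (", min(n_rows, n_cols), ")")
  e <- matrix(.veg_value(outside), n_rows, n_cols)
  r0 <- (n_rows - w) %/% 2L
  c0 <- (n_cols - w) %/% 2L
  e[(r0 + 1L):(r0 + w), (c0 + 1L):(c0 + w)] <- 1
  veg_grid(e, cell_size = cell_size, layout = "block")
}

#' Band of good habitat
#'
#' A straight band of the requested width crossing the whole map, flanked
#' by no-go (or poor) vegetation. With `serpentine = TRUE` the band is
#' folded into the map by right-angle bends at intervals of nearly 2 km,
#' giving an effectively much longer band: parallel straight runs separated
#' by `gap` flanking rows, connected alternately at the right and left map
#' edge. The medial axis of the band is recorded in `band_path` in walking
#' order, so baits can be spaced evenly *along* the band.
#'
#' @param width_cells band width in cells (must be less than the map width).
#' @param orientation `"horizontal"` (band runs along columns) or
#'   `"vertical"`.
#' @param flank vegetation flanking the band: `"nogo"` (default) or
#'   `"poor"`.
#' @param serpentine fold the band through the map (see Details).
#' @param gap flanking rows between serpentine runs (default 1).
#' @inheritParams make_block
#' @return a [veg_grid()] with `band_path` set.
#' @export
make_band <- function(width_cells, orientation = c("horizontal", "vertical"),
                      flank = c("nogo", "poor"), serpentine = FALSE,
                      gap = 1L, n_rows = 200, n_cols = 200, cell_size = 10) {
  orientation <- match.arg(orientation)
  flank <- match.arg(flank)
  w <- as.integer(width_cells)
  if (w < 1L) stop("band width must be at least 1 cell")
  if (w >= min(n_rows, n_cols))
    stop("band width must be less than the map width; use make_block() for full-map habitat")
  if (orientation == "vertical") {
    g <- make_band(w, "horizontal", flank, serpentine, gap,
                   n_rows = n_cols, n_cols = n_rows, cell_size = cell_size)
    path_rc <- arrayInd(g$band_path, dim(g$entry))
    e <- t(g$entry)
    path <- (path_rc[, 1L] - 1L) * nrow(e) + path_rc[, 2L]
    return(veg_grid(e, cell_size, layout = g$layout, band_path = path,
                    band_width = w))
  }
  fl <- .veg_value(flank)
  e <- matrix(fl, n_rows, n_cols)
  if (!serpentine) {
    r0 <- (n_rows - w) %/% 2L
    e[(r0 + 1L):(r0 + w), ] <- 1
    axis_row <- r0 + 1L + (w - 1L) %/% 2L
    path <- (seq_len(n_cols) - 1L) * n_rows + axis_row
    return(veg_grid(e, cell_size, layout = "band", band_path = path,
                    band_width = w))
  }
  # serpentine: horizontal runs of width w at rows 1, 1+w+gap, ... connected
  # alternately at the right and left edges by vertical links of width w
  gap <- as.integer(gap)
  if (gap < 1L) stop("`gap` must be at least 1 row")
  starts <- seq.int(1L, n_rows - w + 1L, by = w + gap)
  nrun <- length(starts)
  path <- integer(0)
  axis_off <- (w - 1L) %/% 2L
  for (k in seq_len(nrun)) {
    rows <- starts[k]:(starts[k] + w - 1L)
    e[rows, ] <- 1
    axis_row <- starts[k] + axis_off
    cols <- if (k %% 2L == 1L) seq_len(n_cols) else rev(seq_len(n_cols))
    path <- c(path, (cols - 1L) * n_rows + axis_row)
    if (k < nrun) {
      # vertical connector through the gap at the end the walk has reached
      ccols <- if (k %% 2L == 1L) (n_cols - w + 1L):n_cols else 1L:w
      crows <- (starts[k] + w):(starts[k + 1L] - 1L)
      e[crows, ccols] <- 1
      axis_col <- ccols[1L] + axis_off
      path <- c(path, (axis_col - 1L) * n_rows + crows)
    }
  }
  veg_grid(e, cell_size, layout = "serpentine", band_path = path,
           band_width = w)
}

#' Checkerboard of good and poor blocks
#'
#' Square blocks of good vegetation alternating with poor vegetation in a
#' checkerboard, tiling the whole map. Flies can diffuse between good
#' blocks through the poor ones, albeit slowly.
#'
#' @param block_width_cells block edge length in cells.
#' @inheritParams make_block
#' @return a [veg_grid()].
#' @export
make_checkerboard <- function(block_width_cells, n_rows = 200, n_cols = 200,
                              cell_size = 10) {
  w <- as.integer(block_width_cells)
  if (w < 1L) stop("block width must be at least 1 cell")
  i <- (row(matrix(0, n_rows, n_cols)) - 1L) %/% w
  j <- (col(matrix(0, n_rows, n_cols)) - 1L) %/% w
  e <- ifelse((i + j) %% 2L == 0L, 1, 0.1)
  veg_grid(e, cell_size = cell_size, layout = "checkerboard")
}

#' Add impenetrable bushes to a habitat
#'
#' Sets the listed good cells to no-go, simulating dense bushes inside the
#' habitat. The remaining good habitat is checked for connectivity with a
#' four-neighbour flood fill: disconnecting all habitat is an error,
#' multiple surviving components produce a warning.
#'
#' @param grid a [veg_grid()].
#' @param cells two-column matrix (or data frame) of (row, col) positions,
#'   1-based; all must currently be good cells.
#' @return the modified [veg_grid()].
#' @seealso [bush_pattern()] for built-in bush arrangements.
#' @export
add_bushes <- function(grid, cells) {
  stopifnot_grid(grid)
  cells <- as.matrix(cells)
  if (length(cells) == 0L) return(grid)
  if (ncol(cells) != 2L) stop("`cells` must have two columns (row, col)")
  nr <- nrow(grid$entry)
  idx <- (cells[, 2L] - 1L) * nr + cells[, 1L]
  if (any(cells[, 1L] < 1L | cells[, 1L] > nr |
          cells[, 2L] < 1L | cells[, 2L] > ncol(grid$entry)))
    stop("bush cells must lie on the map")
  if (any(grid$entry[idx] != 1))
    stop("bush cells must lie inside good habitat")
  grid$entry[idx] <- 0
  if (sum(grid$entry > 0) == 0L)
    stop("bush pattern removes all habitable cells")
  comp <- good_components(grid)
  if (length(comp) == 0L)
    stop("bush pattern removes all good habitat")
  if (attr(comp, "n_components") > 1L)
    warning("good habitat is split into ", attr(comp, "n_components"),
            " disconnected components")
  grid
}

#' Built-in bush arrangements for a band
#'
#' Parameterised generators of periodic bush patterns inside a band of good
#' habitat, graded from mildly to severely obstructive:
#'
#' * `"spaced"`: isolated single bushes on the band axis every `period`
#'   columns;
#' * `"staggered"`: bushes alternating between the two outer band rows,
#'   forcing a zig-zag flight path;
#' * `"comb"`: bush walls across all but one band row, teeth alternating
#'   between the two band edges, creating tortuous paths;
#' * `"maze"`: comb walls plus interleaved dead-end stubs, so that much
#'   flight is spent retracing steps.
#'
#' @param grid a band [veg_grid()] made by [make_band()] (width >= 3 for
#'   patterns other than `"spaced"`).
#' @param kind pattern kind.
#' @param period column period of the pattern (default 6).
#' @return two-column matrix of (row, col) bush positions, suitable for
#'   [add_bushes()].
#' @export
bush_pattern <- function(grid, kind = c("spaced", "staggered", "comb", "maze"),
                         period = 6L) {
  stopifnot_grid(grid)
  kind <- match.arg(kind)
  if (is.na(grid$band_width) || grid$layout != "band")
    stop("bush patterns are defined for straight bands")
  w <- grid$band_width
  nr <- nrow(grid$entry); nc <- ncol(grid$entry)
  r0 <- (nr - w) %/% 2L + 1L           # first band row
  axis <- r0 + (w - 1L) %/% 2L
  period <- as.integer(period)
  if (period < 2L) stop("`period` must be at least 2")
  if (kind != "spaced" && w < 3L)
    stop("pattern '", kind, "' needs a band at least 3 cells wide")
  cols <- seq.int(2L, nc - 1L, by = period)
  cells <- switch(kind,
    spaced = cbind(axis, cols),
    staggered = {
      top <- cols[seq_along(cols) %% 2L == 1L]
      bot <- cols[seq_along(cols) %% 2L == 0L]
      rbind(cbind(r0, top), cbind(r0 + w - 1L, bot))
    },
    comb = {
      # walls leaving a single-cell passage, alternating edges
      out <- NULL
      for (i in seq_along(cols)) {
        rows <- if (i %% 2L == 1L) r0:(r0 + w - 2L) else (r0 + 1L):(r0 + w - 1L)
        out <- rbind(out, cbind(rows, cols[i]))
      }
      out
    },
    maze = {
      out <- NULL
      for (i in seq_along(cols)) {
        rows <- if (i %% 2L == 1L) r0:(r0 + w - 2L) else (r0 + 1L):(r0 + w - 1L)
        out <- rbind(out, cbind(rows, cols[i]))
        # dead-end stub halfway between walls
        stub <- cols[i] + period %/% 2L
        if (stub < nc) {
          rows_s <- if (i %% 2L == 1L) (r0 + 1L):(r0 + w - 1L) else r0:(r0 + w - 2L)
          out <- rbind(out, cbind(rows_s, stub))
        }
      }
      out
    })
  colnames(cells) <- c("row", "col")
  cells
}
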