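#' Bait range-scaling parameters
#'
#' Detection ranges scale with bait body mass from two empirical anchors:
#' a 50 kg mammal-shaped model is visually effective to about 6 m, and a
#' 470 kg ox produces an odor plume attractive from about 90 m. Visual
#' range is proportional to the bait's linear dimension (cube root of
#' mass); plume length grows as the square root of mass, a compromise
#' between Kleiber's 3/4-power metabolic scaling of odor dose and the
#' sub-linear growth of plume length with dose. The plume is a downwind
#' triangle whose edges deviate 26 degrees from the axis. Large targets
#' deployed with artificial ox odor use a fixed 60 m olfactory range.
#'
#' @param visual_ref_mass,visual_ref_range visual anchor (kg, m).
#' @param olfactory_ref_mass,olfactory_ref_range olfactory anchor (kg, m).
#' @param plume_half_angle plume edge-to-axis angle in degrees.
#' @param large_target_odor_range olfactory range of an odor-baited large
#'   target, m.
#' @return an object of class `bait_scaling`.
#' @export
bait_scaling <- function(visual_ref_mass = 50, visual_ref_range = 6,
                         olfactory_ref_mass = 470, olfactory_ref_range = 90,
                         plume_half_angle = 26,
                         large_target_odor_range = 60) {
  stopifnot(visual_ref_mass > 0, visual_ref_range > 0,
            olfactory_ref_mass > 0, olfactory_ref_range > 0,
            plume_half_angle > 0, plume_half_angle < 90,
            large_target_odor_range > 0)
  structure(list(visual_ref_mass = visual_ref_mass,
                 visual_ref_range = visual_ref_range,
                 olfactory_ref_mass = olfactory_ref_mass,
                 olfactory_ref_range = olfactory_ref_range,
                 plume_half_angle = plume_half_angle,
                 large_target_odor_range = large_target_odor_range),
            class = "bait_scaling")
}

#' Standard host body masses (kg)
#'
#' The four simulated host sizes. Masses were chosen so that the disc of
#' visual perception matches a whole number of 10 m cells (1, 4 and 25 for
#' warthog, kudu and elephant).
#'
#' @format named numeric vector.
#' @export
host_masses <- c(lizard = 2, warthog = 42, kudu = 333, elephant = 5196)

#' Visual and olfactory detection ranges
#'
#' `visual_range()` returns `r_ref * (mass / m_ref)^(1/3)` (6 m at 50 kg);
#' `olfactory_range()` returns `R_ref * sqrt(mass / M_ref)` (90 m at
#' 470 kg).
#'
#' @param mass body mass in kg.
#' @param scaling a [bait_scaling()].
#' @return range in metres.
#' @export
visual_range <- function(mass, scaling = bait_scaling()) {
  if (!is.numeric(mass) || any(mass <= 0)) stop("`mass` must be positive")
  scaling$visual_ref_range * (mass / scaling$visual_ref_mass)^(1 / 3)
}

#' @rdname visual_range
#' @export
olfactory_range <- function(mass, scaling = bait_scaling()) {
  if (!is.numeric(mass) || any(mass <= 0)) stop("`mass` must be positive")
  scaling$olfactory_ref_range * sqrt(mass / scaling$olfactory_ref_mass)
}

.bait_kinds <- c("lizard", "warthog", "kudu", "elephant",
                 "large_target", "tiny_target", "custom_host")

#' Specify a bait
#'
#' A bait is either a natural host (lizard, warthog, kudu, elephant, or a
#' custom mass) or an insecticide-treated target. Targets have the visual
#' effectiveness of a proxy host -- a kudu for the large target, a lizard
#' for the tiny target -- adjusted for their flat, two-sided shape; the
#' tiny target is always odorless.
#'
#' @param kind one of `"lizard"`, `"warthog"`, `"kudu"`, `"elephant"`,
#'   `"large_target"`, `"tiny_target"`, `"custom_host"`.
#' @param position integer `(row, col)` cell of the bait.
#' @param has_odor does the bait emit (or is it baited with) odor?
#' @param wind downwind direction of the plume: `"N"`, `"E"`, `"S"`, `"W"`
#'   (grid-axis wind, fixed for a whole experiment).
#' @param mass body mass in kg; defaults to the standard mass for named
#'   hosts and to the proxy host's mass for targets.
#' @param response `"fixed"` (capture at an electric pen, f = 0.6) or
#'   `"day"` (probing responsiveness rising 0.1 to 0.6 over the hunger
#'   cycle).
#' @param f_fixed the fixed effective-response probability.
#' @param active_window `"all"`: the bait operates through every step
#'   block of the day; `"second_half"`: only during the second half of the
#'   day's blocks (the afternoon-catch convention of simulated field
#'   experiments).
#' @param active_days integer vector of cycle days on which the bait is
#'   deployed (`NULL` = every day); crossover designs use this to swap
#'   baits between sites daily.
#' @return an object of class `bait_spec`.
#' @export
bait_spec <- function(kind, position, has_odor = FALSE, wind = "E",
                      mass = NULL, response = c("fixed", "day"),
                      f_fixed = 0.6, active_window = c("all", "second_half"),
                      active_days = NULL) {
  kind <- match.arg(kind, .bait_kinds)
  response <- match.arg(response)
  wind <- match.arg(wind, c("N", "E", "S", "W"))
  position <- as.integer(position)
  if (length(position) != 2L) stop("`position` must be (row, col)")
  if (kind == "tiny_target" && has_odor)
    stop("the tiny target is always used without odor")
  if (is.null(mass)) {
    mass <- switch(kind,
                   large_target = host_masses[["kudu"]],
                   tiny_target = host_masses[["lizard"]],
                   custom_host = stop("`mass` is required for custom_host"),
                   host_masses[[kind]])
  }
  if (!is.numeric(mass) || mass <= 0) stop("`mass` must be positive")
  if (f_fixed < 0 || f_fixed > 1) stop("`f_fixed` must be a probability")
  active_window <- match.arg(active_window)
  structure(list(kind = kind, mass = mass, position = position,
                 has_odor = has_odor, wind = wind, response = response,
                 f_fixed = f_fixed, active_window = active_window,
                 active_days = active_days),
            class = "bait_spec")
}

# mass-matched square block side in cells: disc of visual perception has
# the same area as the block
.visual_block_side <- function(r_m, cell_size) {
  max(1L, as.integer(round(sqrt(pi) * r_m / cell_size)))
}

# cells of a side x side block; odd sides centred on the bait, even sides
# anchored with the bait at the upper-left-of-centre cell
.block_cells <- function(row, col, side) {
  lo <- -((side - 1L) %/% 2L)
  hi <- side %/% 2L
  off <- lo:hi
  cbind(rep(row + off, times = side), rep(col + off, each = side))
}

.clip_cells <- function(cells, nr, nc, what = "footprint") {
  ok <- cells[, 1L] >= 1L & cells[, 1L] <= nr &
        cells[, 2L] >= 1L & cells[, 2L] <= nc
  if (!all(ok))
    warning(what, " extends off the map and was clipped (", sum(!ok),
            " cells); mirror boundaries make the clipping conservative")
  cells[ok, , drop = FALSE]
}

.footprint <- function(rows, cols, fraction, zone) {
  data.frame(row = as.integer(rows), col = as.integer(cols),
             fraction = fraction, zone = zone)
}

#' Visual stimulus footprint of a bait
#'
#' Hosts of warthog size and above stimulate every fly in a square block of
#' cells whose area matches the disc of visual perception (1x1, 2x2 and
#' 5x5 cells for warthog, kudu and elephant). The lizard's stimuli cover
#' less than one cell: 50\% of the flies in its cell are stimulated with
#' visual cues alone, 80\% when odor is added (the odor contribution is
#' folded into the same cell because the lizard plume barely leaves it).
#' The tiny target, perceptible from only two directions, stimulates 25\%.
#' The large target uses the kudu block restricted to the two cells facing
#' the target plane (a 1x2 block), reflecting its two-sided visibility.
#'
#' @param spec a [bait_spec()].
#' @param grid a [veg_grid()].
#' @param scaling a [bait_scaling()].
#' @return a data frame with columns `row`, `col`, `fraction`, `zone`.
#' @export
visual_footprint <- function(spec, grid, scaling = bait_scaling()) {
  stopifnot_grid(grid)
  nr <- nrow(grid$entry); nc <- ncol(grid$entry)
  r <- spec$position[1L]; co <- spec$position[2L]
  if (r < 1L || r > nr || co < 1L || co > nc)
    stop("bait position must lie on the map")
  cs <- grid$cell_size
  out <- switch(spec$kind,
    lizard = .footprint(r, co, if (spec$has_odor) 0.8 else 0.5, "visual"),
    tiny_target = .footprint(r, co, 0.25, "visual"),
    large_target = {
      cells <- cbind(c(r, r), c(co, co + 1L))   # two faces of the plane
      .footprint(cells[, 1L], cells[, 2L], 1, "visual")
    },
    { # warthog, kudu, elephant, custom_host
      side <- .visual_block_side(visual_range(spec$mass, scaling), cs)
      cells <- .block_cells(r, co, side)
      .footprint(cells[, 1L], cells[, 2L], 1, "visual")
    })
  cells <- .clip_cells(as.matrix(out[, c("row", "col")]), nr, nc,
                       "visual footprint")
  keep <- paste(out$row, out$col) %in% paste(cells[, 1L], cells[, 2L])
  out[keep, , drop = FALSE]
}

#' Odor-plume footprint of a bait
#'
#' The plume extends downwind from the bait cell centre as an isoceles
#' triangle of length equal to the olfactory range, its edges deviating
#' 26 degrees from the axis. Cells belong to the plume when their centres
#' lie inside the triangle (the apex cell itself carries the visual
#' stimulus and is not duplicated here). All flies in a plume cell are
#' stimulated. Odorless baits, and the lizard (whose short plume is folded
#' into its visual cell), have an empty plume footprint.
#'
#' @inheritParams visual_footprint
#' @return a data frame with columns `row`, `col`, `fraction`, `zone`.
#' @export
plume_footprint <- function(spec, grid, scaling = bait_scaling()) {
  stopifnot_grid(grid)
  empty <- .footprint(integer(0), integer(0), numeric(0), character(0))
  if (!spec$has_odor) return(empty)
  if (spec$kind == "lizard") return(empty)
  range_m <- if (spec$kind == "large_target")
    scaling$large_target_odor_range else olfactory_range(spec$mass, scaling)
  if (range_m <= 0) return(empty)
  cs <- grid$cell_size
  nr <- nrow(grid$entry); nc <- ncol(grid$entry)
  r0 <- spec$position[1L]; c0 <- spec$position[2L]
  # axial/lateral cell offsets relative to the bait, by wind direction
  ext <- ceiling(range_m / cs) + 1L
  dr <- rep(-ext:ext, times = 2L * ext + 1L)
  dc <- rep(-ext:ext, each = 2L * ext + 1L)
  ax <- switch(spec$wind, N = -dr, S = dr, E = dc, W = -dc)   # downwind
  lat <- switch(spec$wind, N = dc, S = dc, E = dr, W = dr)
  x <- ax * cs; y <- lat * cs
  tanh_ <- tan(scaling$plume_half_angle * pi / 180)
  inside <- x > 0 & x <= range_m & abs(y) < x * tanh_
  rows <- r0 + dr[inside]; cols <- c0 + dc[inside]
  cells <- .clip_cells(cbind(rows, cols), nr, nc, "odor plume")
  if (nrow(cells) == 0L) return(empty)
  .footprint(cells[, 1L], cells[, 2L], 1, "olfactory")
}

#' Combined stimulus footprint of a bait
#'
#' Union of the visual and plume footprints; where a cell appears in both,
#' the larger stimulation fraction wins.
#'
#' @inheritParams visual_footprint
#' @return a data frame with columns `row`, `col`, `fraction`, `zone`.
#' @export
bait_footprint <- function(spec, grid, scaling = bait_scaling()) {
  v <- visual_footprint(spec, grid, scaling)
  p <- plume_footprint(spec, grid, scaling)
  all <- rbind(v, p)
  if (nrow(all) == 0L) return(all)
  key <- paste(all$row, all$col)
  all <- all[order(key, -all$fraction), , drop = FALSE]
  all[!duplicated(paste(all$row, all$col)), , drop = FALSE]
}

#' Read / write bait rosters
#'
#' A roster is a CSV with columns `kind`, `mass_kg`, `row`, `col`,
#' `has_odor`, `wind`, `response` (empty `mass_kg` uses the standard mass).
#'
#' @param baits a list of [bait_spec()]s.
#' @param path file path.
#' @export
write_bait_roster <- function(baits, path) {
  df <- do.call(rbind, lapply(baits, function(b)
    data.frame(kind = b$kind, mass_kg = b$mass, row = b$position[1L],
               col = b$position[2L], has_odor = b$has_odor, wind = b$wind,
               response = b$response)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bait_roster
#' @export
read_bait_roster <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    bait_spec(df$kind[i], c(df$row[i], df$col[i]),
              has_odor = isTRUE(as.logical(df$has_odor[i])),
              wind = df$wind[i], mass = df$mass_kg[i],
              response = df$response[i]))
}
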