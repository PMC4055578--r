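#' Place baits singly and evenly (or in groups) over the habitat
#'
#' At an overall density of `density` baits per km^2 of good habitat,
#' baits are spaced evenly: along the band axis (equal arc spacing of the
#' recorded band path) when the grid is a band, or on a square lattice
#' inside the good-habitat bounding box for blocks. With `grouped = TRUE`
#' the same overall density is arranged in evenly spaced groups of
#' `group_size` baits occupying consecutive cells along the band axis (or
#' a row, in blocks).
#'
#' @param grid a [veg_grid()].
#' @param kind bait kind (see [bait_spec()]).
#' @param density baits per km^2 of good habitat.
#' @param grouped place baits in groups rather than singly.
#' @param group_size baits per group.
#' @param has_odor,wind,response,f_fixed,active_window passed to
#'   [bait_spec()].
#' @return list of [bait_spec()]s.
#' @export
place_baits_evenly <- function(grid, kind, density, grouped = FALSE,
                               group_size = 4L, has_odor = FALSE,
                               wind = "E", response = "day", f_fixed = 0.6,
                               active_window = "all") {
  stopifnot_grid(grid)
  if (density <= 0) stop("`density` must be positive")
  area <- geometry_summary(grid)$good_area_km2
  if (area <= 0) stop("grid has no good habitat")
  n_baits <- max(1L, as.integer(round(density * area)))
  mk <- function(row, col) bait_spec(kind, c(row, col), has_odor = has_odor,
                                     wind = wind, response = response,
                                     f_fixed = f_fixed,
                                     active_window = active_window)
  nr <- nrow(grid$entry)
  if (!is.null(grid$band_path)) {
    path <- grid$band_path
    L <- length(path)
    n_units <- if (grouped) max(1L, as.integer(round(n_baits / group_size)))
               else n_baits
    centres <- pmin(L, pmax(1L, round((seq_len(n_units) - 0.5) * L / n_units)))
    if (grouped) {
      off <- -((group_size - 1L) %/% 2L):(group_size %/% 2L)
      at <- pmin(L, pmax(1L, rep(centres, each = group_size) +
                           rep(off, times = n_units)))
    } else at <- centres
    idx <- path[at]
    rows <- (idx - 1L) %% nr + 1L
    cols <- (idx - 1L) %/% nr + 1L
    return(mapply(mk, rows, cols, SIMPLIFY = FALSE))
  }
  # block habitat: square lattice inside the good bounding box
  gc <- good_cells(grid)
  r <- (gc - 1L) %% nr + 1L
  co <- (gc - 1L) %/% nr + 1L
  r1 <- min(r); r2 <- max(r); c1 <- min(co); c2 <- max(co)
  n_units <- if (grouped) max(1L, as.integer(round(n_baits / group_size)))
             else n_baits
  side <- max(1L, as.integer(round(sqrt(n_units))))
  if (side * side != n_units)
    warning("density gives ", n_units, " placement units; using a ",
            side, "x", side, " lattice")
  rows <- round(r1 - 0.5 + (seq_len(side) - 0.5) * (r2 - r1 + 1L) / side)
  cols <- round(c1 - 0.5 + (seq_len(side) - 0.5) * (c2 - c1 + 1L) / side)
  specs <- list()
  for (rr in rows) for (cc in cols) {
    if (grouped) {
      off <- -((group_size - 1L) %/% 2L):(group_size %/% 2L)
      for (o in off) specs[[length(specs) + 1L]] <-
          mk(rr, min(c2, max(c1, cc + o)))
    } else specs[[length(specs) + 1L]] <- mk(rr, cc)
  }
  specs
}

#' Crossover design for simulated field catches
#'
#' Two baits are compared over six days at two sites far enough apart that
#' their stimulus footprints cannot compete; the baits swap sites daily
#' and are present for the second half of each day's 25-step blocks (field
#' catches are typically made in the afternoon).
#'
#' @param sites 2 x 2 integer matrix of (row, col) site positions, or
#'   `NULL` to place sites automatically at the quarter points of the
#'   habitat (the band path for bands, the medial axis for blocks).
#' @param n_days days of operation.
#' @param active_window step blocks during which the baits operate.
#' @return an object of class `crossover_design`.
#' @export
crossover_design <- function(sites = NULL, n_days = 6L,
                             active_window = "second_half") {
  structure(list(sites = sites, n_days = as.integer(n_days),
                 active_window = active_window),
            class = "crossover_design")
}

.default_sites <- function(grid) {
  nr <- nrow(grid$entry)
  nc <- ncol(grid$entry)
  if (!is.null(grid$band_path)) {
    L <- length(grid$band_path)
    # quarter points of the band path, snapped (along the path) to cells
    # far enough from the map boundary that stimulus footprints fit
    pr <- (grid$band_path - 1L) %% nr + 1L
    pc <- (grid$band_path - 1L) %/% nr + 1L
    margin <- min(35L, (min(nr, nc) - 1L) %/% 2L)
    ok <- which(pmin(pr - 1L, nr - pr, pc - 1L, nc - pc) >= margin)
    if (length(ok) < 2L) ok <- seq_len(L)
    pick <- function(target) ok[which.min(abs(ok - target))]
    at <- c(pick(round(L / 4)), pick(round(3 * L / 4)))
    idx <- grid$band_path[at]
    return(cbind((idx - 1L) %% nr + 1L, (idx - 1L) %/% nr + 1L))
  }
  gc <- good_cells(grid)
  if (length(gc) == 0L) gc <- which(grid$entry > 0)
  r <- (gc - 1L) %% nr + 1L
  co <- (gc - 1L) %/% nr + 1L
  if (length(gc) <= 2L) {     # degenerate habitats: use the cells themselves
    ord <- order(co, r)
    return(cbind(r, co)[c(ord[1L], ord[length(ord)]), , drop = FALSE])
  }
  rmid <- round((min(r) + max(r)) / 2)
  cq <- round(min(co) - 0.5 + c(0.25, 0.75) * (max(co) - min(co) + 1L))
  cbind(c(rmid, rmid), cq)
}

.footprint_cells <- function(spec, grid, scaling) {
  fp <- bait_footprint(spec, grid, scaling)
  (fp$col - 1L) * nrow(grid$entry) + fp$row
}

#' Simulated crossover catch comparison
#'
#' Runs the six-day crossover protocol: `bait_a` and `bait_b` operate
#' simultaneously at two distant sites, swapping sites daily, present for
#' half of each day's step blocks, with capture response `f = 0.6` (an
#' electric pen) unless the specs say otherwise. Wild hosts compete
#' throughout at the calibrated background rate. Catches are expressed as
#' a percent of the initial abundance of tsetse per km^2 of good habitat.
#'
#' @param grid a [veg_grid()].
#' @param bait_a,bait_b [bait_spec()]s (their positions are overridden by
#'   the design's sites).
#' @param design a [crossover_design()].
#' @param schedule,response,params,dispersal,scaling see [run_cycle()].
#' @return a list with `catch_percent` (named, one entry per bait),
#'   `caught` (absolute), `initial_per_km2`, and the full `cycle_result`.
#' @export
crossover_catch <- function(grid, bait_a, bait_b,
                            design = crossover_design(),
                            schedule = step_schedule(),
                            response = response_schedule(),
                            params = cohort_params(),
                            dispersal = dispersal_params(),
                            scaling = bait_scaling()) {
  stopifnot_grid(grid)
  sites <- design$sites
  if (is.null(sites)) sites <- .default_sites(grid)
  sites <- as.matrix(sites)
  if (!all(dim(sites) == c(2L, 2L))) stop("`sites` must be a 2x2 matrix")
  days <- seq_len(design$n_days)
  odd <- days[days %% 2L == 1L]; even <- days[days %% 2L == 0L]
  at <- function(spec, site, active_days) {
    spec$position <- as.integer(sites[site, ])
    spec$active_days <- active_days
    spec$active_window <- design$active_window
    spec
  }
  specs <- list(a1 = at(bait_a, 1L, odd), a2 = at(bait_a, 2L, even),
                b1 = at(bait_b, 2L, odd), b2 = at(bait_b, 1L, even))
  # sites must not compete: footprints at the two sites must be disjoint
  s1 <- unique(c(.footprint_cells(specs$a1, grid, scaling),
                 .footprint_cells(specs$b2, grid, scaling)))
  s2 <- unique(c(.footprint_cells(specs$a2, grid, scaling),
                 .footprint_cells(specs$b1, grid, scaling)))
  if (length(intersect(s1, s2)) > 0L)
    stop("site footprints overlap; move the sites further apart")
  res <- run_cycle(grid, specs, schedule, response, params, dispersal,
                   scaling, end_day = 6L)
  caught <- c(a = res$caught[1L] + res$caught[2L],
              b = res$caught[3L] + res$caught[4L])
  area <- res$good_area_km2
  init_per_km2 <- res$initial_total / area
  list(catch_percent = 100 * caught / init_per_km2,
       caught = caught, initial_per_km2 = init_per_km2, result = res)
}

#' Relative efficacy of odor in a crossover experiment
#'
#' Compares a host (visual stimuli plus odor) with an odorless model of
#' the same size in the crossover design, and reports the percent by which
#' odor increases the catch: `100 (catch_vo - catch_v) / catch_v`.
#'
#' @inheritParams crossover_catch
#' @param kind host kind (see [bait_spec()]).
#' @param wind downwind plume direction.
#' @return a list with `catch_v`, `catch_vo` (percent per km^2 of good
#'   habitat) and `efficacy_percent`.
#' @export
odor_efficacy_experiment <- function(grid, kind, wind = "E",
                                     design = crossover_design(),
                                     schedule = step_schedule(),
                                     response = response_schedule(),
                                     params = cohort_params(),
                                     dispersal = dispersal_params(),
                                     scaling = bait_scaling()) {
  vo <- bait_spec(kind, c(1L, 1L), has_odor = TRUE, wind = wind,
                  response = "fixed")
  v <- bait_spec(kind, c(1L, 1L), has_odor = FALSE, wind = wind,
                 response = "fixed")
  out <- crossover_catch(grid, vo, v, design, schedule, response, params,
                         dispersal, scaling)
  cv <- unname(out$catch_percent["b"])
  cvo <- unname(out$catch_percent["a"])
  list(catch_v = cv, catch_vo = cvo,
       efficacy_percent = 100 * (cvo - cv) / cv)
}

#' Kill rate of insecticide-treated targets
#'
#' Targets are placed singly and evenly at `density` per km^2 of good
#' habitat and operated continuously through the cycle with the
#' day-schedule response; wild hosts compete at the background rate.
#' Returns the percent of the initial population killed per hunger cycle.
#'
#' @inheritParams place_baits_evenly
#' @param target_kind `"large_target"` or `"tiny_target"`.
#' @param schedule,response,params,dispersal,scaling see [run_cycle()].
#' @return a list with `kill_percent_per_cycle`, `n_targets`, `result`.
#' @export
target_efficacy <- function(grid, target_kind = c("large_target", "tiny_target"),
                            density, has_odor = FALSE, wind = "E",
                            schedule = step_schedule(),
                            response = response_schedule(),
                            params = cohort_params(),
                            dispersal = dispersal_params(),
                            scaling = bait_scaling()) {
  target_kind <- match.arg(target_kind)
  if (density == 0)
    return(list(kill_percent_per_cycle = 0, n_targets = 0L, result = NULL))
  specs <- place_baits_evenly(grid, target_kind, density,
                              has_odor = has_odor, wind = wind,
                              response = "day")
  res <- run_cycle(grid, specs, schedule, response, params, dispersal,
                   scaling)
  list(kill_percent_per_cycle = 100 * sum(res$caught) / res$initial_total,
       n_targets = length(specs), result = res)
}

#' Cumulative feeding success on mapped hosts
#'
#' Hosts of one kind are placed at an overall density per km^2 of good
#' habitat (singly, or in groups along the band/row axis), and the cohort
#' feeds only on them: the wild-host probability is forced to zero.
#' Feeding follows the day-schedule probing response; background mortality
#' stays at 3\%/day. Returns the cumulative percent of the initial cohort
#' fed by the end of `horizon_days` (4 = the normal cycle length, 6 = the
#' brink of starvation).
#'
#' @inheritParams place_baits_evenly
#' @param horizon_days scoring horizon (4 or 6).
#' @param schedule,response,params,dispersal,scaling see [run_cycle()].
#' @return a list with `fed_percent`, `n_hosts`, `result`.
#' @export
feeding_success <- function(grid, kind, density, grouped = FALSE,
                            group_size = 4L, horizon_days = 4L,
                            has_odor = FALSE, wind = "E",
                            schedule = step_schedule(),
                            response = response_schedule(),
                            params = cohort_params(),
                            dispersal = dispersal_params(),
                            scaling = bait_scaling()) {
  params$p_wild <- 0
  specs <- place_baits_evenly(grid, kind, density, grouped = grouped,
                              group_size = group_size, has_odor = has_odor,
                              wind = wind, response = "day")
  res <- run_cycle(grid, specs, schedule, response, params, dispersal,
                   scaling, end_day = as.integer(horizon_days))
  list(fed_percent = 100 * sum(res$caught) / res$initial_total,
       n_hosts = length(specs), result = res)
}

#' Starvation-probability table
#'
#' For each host population, habitat, number of completed host-searching
#' days and mobility multiplier, the percent probability that flies still
#' unfed at that point die of starvation by the end of the cycle
#' ([starvation_probability()]); flies feed only on the mapped hosts.
#'
#' @param hosts named list; each element a list with `kind` and `density`
#'   (per km^2 of good habitat).
#' @param grids named list of [veg_grid()]s.
#' @param days numbers of completed days to evaluate.
#' @param multipliers mobility multipliers applied to the step schedule.
#' @param response,params,dispersal,scaling see [run_cycle()].
#' @return a data frame with columns `host`, `habitat`, `days_completed`,
#'   `steps_per_cycle`, `starvation_percent`.
#' @export
starvation_table <- function(hosts, grids, days = c(2L, 5L),
                             multipliers = c(1 / 3, 1, 3),
                             response = response_schedule(),
                             params = cohort_params(),
                             dispersal = dispersal_params(),
                             scaling = bait_scaling()) {
  params$p_wild <- 0
  rows <- list()
  for (hn in names(hosts)) for (gn in names(grids)) {
    grid <- grids[[gn]]
    specs <- place_baits_evenly(grid, hosts[[hn]]$kind, hosts[[hn]]$density,
                                response = "day")
    for (m in multipliers) {
      sched <- step_schedule(multiplier = m)
      for (d in days) {
        p <- starvation_probability(grid, specs, day_completed = d,
                                    schedule = sched, response = response,
                                    params = params, dispersal = dispersal,
                                    scaling = scaling)
        rows[[length(rows) + 1L]] <- data.frame(
          host = hn, habitat = gn, days_completed = d,
          steps_per_cycle = sum(sched$daily_steps),
          starvation_percent = 100 * p)
      }
    }
  }
  do.call(rbind, rows)
}

#' Mean distance from flies to the nearest bait
#'
#' Baits are placed singly and evenly at `density` per km^2 of good
#' habitat; the mean over the stationary fly distribution of the distance
#' to the nearest bait summarises how habitat attenuation separates flies
#' from baits. Distance is measured through the habitat the flies can
#' traverse: along the band axis when the grid records a band path (a
#' serpentine's adjacent runs are close in the plane but far apart for a
#' fly that cannot cross the no-go gap), and centre-to-centre Euclidean
#' distance otherwise.
#'
#' @inheritParams place_baits_evenly
#' @param baits optional list of [bait_spec()]s overriding the automatic
#'   placement.
#' @return mean distance in metres.
#' @export
nearest_bait_distance <- function(grid, density = NULL, baits = NULL,
                                  kind = "large_target") {
  stopifnot_grid(grid)
  if (is.null(baits)) {
    if (is.null(density) || density <= 0) stop("`density` must be positive")
    baits <- place_baits_evenly(grid, kind, density)
  }
  w <- stationary_field(grid)
  nr <- nrow(grid$entry)
  bidx <- vapply(baits, function(b)
    (b$position[2L] - 1L) * nr + b$position[1L], integer(1))
  if (!is.null(grid$band_path) && all(bidx %in% grid$band_path)) {
    # along-band distance: positions are arc lengths on the recorded path
    s <- seq_along(grid$band_path)
    sb <- match(bidx, grid$band_path)
    dmin <- rep(Inf, length(s))
    for (p in sb) dmin <- pmin(dmin, abs(s - p))
    ww <- w[grid$band_path]
    return(sum(ww * dmin) / sum(ww) * grid$cell_size)
  }
  ok <- which(w > 0)
  r <- (ok - 1L) %% nr + 1L
  co <- (ok - 1L) %/% nr + 1L
  dmin <- rep(Inf, length(ok))
  for (b in baits) {
    d2 <- (r - b$position[1L])^2 + (co - b$position[2L])^2
    dmin <- pmin(dmin, d2)
  }
  sum(w[ok] * sqrt(dmin)) / sum(w[ok]) * grid$cell_size
}
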