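#' Daily step schedule of the hunger cycle
#'
#' Spontaneous activity rises through the hunger cycle: the defaults give
#' 150 steps on day 1, doubling each day to 2400 on day 5, then 1350 on
#' day 6 when flies are close to starvation (6000 steps per cycle). Each
#' day is partitioned into alternating 25-step host-searching and general
#' blocks, starting with a host-searching block. A mobility multiplier
#' scales every day's count (rounded to a multiple of 50 so the 25/25
#' alternation is preserved): 1/3 and 3 give the 2000- and 18000-step
#' cycles used to represent less and more mobile flies.
#'
#' @param daily_steps steps per cycle day.
#' @param block_size steps per host-searching or general block.
#' @param multiplier mobility multiplier.
#' @return an object of class `step_schedule`.
#' @export
step_schedule <- function(daily_steps = c(150, 300, 600, 1200, 2400, 1350),
                          block_size = 25L, multiplier = 1) {
  if (any(daily_steps <= 0)) stop("daily step counts must be positive")
  if (multiplier <= 0) stop("`multiplier` must be positive")
  block_size <- as.integer(block_size)
  unit <- 2L * block_size
  scaled <- pmax(unit, as.integer(round(daily_steps * multiplier / unit) * unit))
  structure(list(daily_steps = scaled, block_size = block_size,
                 multiplier = multiplier),
            class = "step_schedule")
}

#' Effective-response schedules
#'
#' The fraction `f` of flies arriving in a bait's vicinity that respond
#' effectively (feed, or are caught or killed) before the end of the step
#' period. For capture at an electric pen, `f` is fixed at 0.6 (the
#' capture efficiency of the netting). For feeding and for target kills,
#' `f` follows the probing responsiveness, rising linearly from 0.1 on
#' day 1 of the cycle to 0.6 on day 6. Wild-host encounters always use the
#' day schedule.
#'
#' @param f_by_day probing response per cycle day.
#' @param f_fixed fixed capture probability.
#' @return an object of class `response_schedule`.
#' @export
response_schedule <- function(f_by_day = seq(0.1, 0.6, by = 0.1),
                              f_fixed = 0.6) {
  if (any(f_by_day < 0 | f_by_day > 1) || f_fixed < 0 || f_fixed > 1)
    stop("all response probabilities must lie in [0, 1]")
  structure(list(f_by_day = f_by_day, f_fixed = f_fixed),
            class = "response_schedule")
}

#' Cohort-level parameters
#'
#' @param p_wild per-step probability of finding an (unmapped) wild host;
#'   the default 0.00125 is calibrated so that, with no introduced baits,
#'   the cycle ends in starvation for 2.7\% of the cohort (see
#'   [goal_seek_wild_prob()]).
#' @param daily_mortality mortality per day from all causes other than
#'   starvation, spread geometrically over the day's steps.
#' @param starvation_day starvation occurs at the end of this cycle day.
#' @return an object of class `cohort_params`.
#' @export
cohort_params <- function(p_wild = 0.00125, daily_mortality = 0.03,
                          starvation_day = 6L) {
  if (p_wild < 0 || p_wild > 1 || daily_mortality < 0 || daily_mortality > 1)
    stop("probabilities must lie in [0, 1]")
  structure(list(p_wild = p_wild, daily_mortality = daily_mortality,
                 starvation_day = as.integer(starvation_day)),
            class = "cohort_params")
}

# ---- bait compilation ---------------------------------------------------

# Turn bait specs into flat index/fraction vectors, batched so that no two
# baits in a batch share a cell (recruitment within a batch is then a
# single vectorised operation; batches are processed in roster order).
.compile_baits <- function(baits, grid, scaling) {
  nr <- nrow(grid$entry)
  n <- length(baits)
  info <- vector("list", n)
  for (b in seq_len(n)) {
    sp <- baits[[b]]
    fp <- bait_footprint(sp, grid, scaling)
    idx <- (fp$col - 1L) * nr + fp$row
    vis <- fp$zone == "visual"
    rel <- idx[vis & grid$entry[idx] == 1]
    if (length(rel) == 0L) rel <- idx[vis & grid$entry[idx] > 0]
    if (length(rel) == 0L)
      stop("bait ", b, " (", sp$kind,
           "): visual footprint contains no habitable cell")
    info[[b]] <- list(
      idx = idx, frac = fp$fraction, release_idx = rel,
      response = sp$response, f_fixed = sp$f_fixed,
      window = if (is.null(sp$active_window)) "all" else sp$active_window,
      days = sp$active_days)   # NULL = every day
  }
  # greedy batching on cell-collision
  batches <- list()
  taken <- list()
  for (b in seq_len(n)) {
    placed <- FALSE
    for (j in seq_along(batches)) {
      if (!any(info[[b]]$idx %in% taken[[j]])) {
        batches[[j]]$idx <- c(batches[[j]]$idx, info[[b]]$idx)
        batches[[j]]$frac <- c(batches[[j]]$frac, info[[b]]$frac)
        batches[[j]]$bait <- c(batches[[j]]$bait,
                               rep(b, length(info[[b]]$idx)))
        taken[[j]] <- c(taken[[j]], info[[b]]$idx)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      batches[[length(batches) + 1L]] <-
        list(idx = info[[b]]$idx, frac = info[[b]]$frac,
             bait = rep(b, length(info[[b]]$idx)))
      taken[[length(batches)]] <- info[[b]]$idx
    }
  }
  list(n = n, info = info, batches = batches,
       release_idx = lapply(info, `[[`, "release_idx"))
}

.bait_f_day <- function(cb, day, response) {
  vapply(cb$info, function(i) {
    if (i$response == "fixed") i$f_fixed else response$f_by_day[day]
  }, numeric(1))
}

.bait_active <- function(cb, day, block, n_blocks) {
  vapply(cb$info, function(i) {
    (is.null(i$days) || day %in% i$days) &&
      (i$window == "all" || block > n_blocks / 2)
  }, logical(1))
}

# recruit `frac` of `source[idx]` (removed from F) for each bait in the
# batch set; returns updated F and per-bait recruited totals. Batches are
# drawn sequentially from the still-unrecruited part of `source`, so
# baits with overlapping footprints (which land in different batches)
# cannot jointly remove more than is present.
.recruit <- function(F, source, cb, active, rec) {
  avail <- source
  for (ba in cb$batches) {
    sel <- active[ba$bait]
    if (!any(sel)) next
    idx <- ba$idx[sel]
    r <- avail[idx] * ba$frac[sel]
    avail[idx] <- avail[idx] - r
    F[idx] <- F[idx] - r
    rs <- rowsum(r, ba$bait[sel])
    ids <- as.integer(rownames(rs))
    rec[ids] <- rec[ids] + rs[, 1L]
  }
  list(F = F, rec = rec)
}

# end-of-host-searching-block release of inactive pools into the good
# cells of each bait's visual footprint, in equal shares
.release_pools <- function(F, pools, cb) {
  nz <- which(pools > 0)
  if (length(nz) == 0L) return(list(F = F, pools = pools))
  lens <- lengths(cb$release_idx[nz])
  idx <- unlist(cb$release_idx[nz], use.names = FALSE)
  share <- rep(pools[nz] / lens, lens)
  ag <- rowsum(share, idx)
  ii <- as.integer(rownames(ag))
  F[ii] <- F[ii] + ag[, 1L]
  pools[nz] <- 0
  list(F = F, pools = pools)
}

# the seven-stage update for a single step period
.one_step <- function(F, pools, tal, kernel, cb, active, is_hs,
                      s_step, wild_rem) {
  # stage 2: natural losses at the start of the period
  tot <- sum(F)
  tal$dead <- tal$dead + tot * (1 - s_step)
  F <- F * s_step
  if (wild_rem > 0) {
    fw <- sum(F) * wild_rem
    tal$fed_wild <- tal$fed_wild + fw
    F <- F * (1 - wild_rem)
  }
  any_active <- is_hs && cb$n > 0L && any(active)
  rec <- numeric(cb$n)
  # stage 3: recruitment of flies already in stimulus cells
  if (any_active) {
    out <- .recruit(F, F, cb, active, rec)
    F <- out$F; rec <- out$rec
  }
  # stage 4: orthogonal dispersal
  d <- .diffuse(F, kernel)
  F <- d$field
  # stage 5: recruitment of flies that just stepped into stimulus cells
  if (any_active) {
    out <- .recruit(F, d$inflow, cb, active, rec)
    F <- out$F; rec <- out$rec
  }
  # stage 6: effective response f -> removed and tallied; 1 - f -> inactive
  if (any_active) {
    caught <- tal$f_day * rec
    tal$caught <- tal$caught + caught
    pools <- pools + (1 - tal$f_day) * rec
  }
  list(F = F, pools = pools, tal = tal)
}

# ---- cohort state & public steppers ------------------------------------

#' Initialise a cohort simulation state
#'
#' Bundles the habitat, baits and parameters with the diffusing fly field
#' and all tallies, positioned at the start of `start_day`. [run_step()]
#' advances such a state one step period at a time; [run_cycle()] is the
#' whole-cycle driver.
#'
#' @param grid a [veg_grid()].
#' @param baits list of [bait_spec()]s.
#' @param schedule a [step_schedule()].
#' @param response a [response_schedule()].
#' @param params a [cohort_params()].
#' @param dispersal a [dispersal_params()].
#' @param scaling a [bait_scaling()].
#' @param initial starting density matrix; defaults to the stationary
#'   pattern [stationary_field()] scaled to `initial_total`.
#' @param initial_total cohort size when `initial` is `NULL`.
#' @param start_day first cycle day to simulate.
#' @param check_tol relative tolerance for the bookkeeping identity
#'   (active + inactive + all tallies = initial), checked at block ends.
#' @return an object of class `cohort_state`.
#' @export
cohort_state <- function(grid, baits = list(), schedule = step_schedule(),
                         response = response_schedule(),
                         params = cohort_params(),
                         dispersal = dispersal_params(),
                         scaling = bait_scaling(),
                         initial = NULL, initial_total = 1,
                         start_day = 1L, check_tol = 1e-9) {
  stopifnot_grid(grid)
  if (is.null(initial)) initial <- stationary_field(grid, initial_total)
  if (!all(dim(initial) == dim(grid$entry)))
    stop("`initial` must be congruent with the grid")
  if (any(initial < 0)) stop("initial densities must be non-negative")
  if (any(initial[grid$entry == 0] > 0))
    stop("initial field places flies in no-go cells")
  if (sum(initial) <= 0) stop("initial cohort is empty")
  cb <- .compile_baits(baits, grid, scaling)
  structure(list(
    grid = grid, kernel = .make_kernel(grid, dispersal), cb = cb,
    schedule = schedule, response = response, params = params,
    field = initial, pools = numeric(cb$n),
    tallies = list(caught = numeric(cb$n), fed_wild = 0, dead = 0,
                   starved = 0),
    initial_total = sum(initial),
    day = as.integer(start_day), block = 1L, step_in_block = 0L,
    check_tol = check_tol), class = "cohort_state")
}

#' Advance a cohort state by one step period
#'
#' Applies, in order: background mortality and wild-host feeding;
#' recruitment of flies in stimulus cells (host-searching steps only);
#' orthogonal dispersal; recruitment of flies that just entered stimulus
#' cells; the effective-response partition (`f` removed and tallied,
#' `1 - f` to the bait's inactive pool); and the clock advance, releasing
#' inactive pools evenly over the good cells of each bait's visual
#' footprint at the end of every 25-step host-searching block.
#'
#' @param state a [cohort_state()].
#' @return the advanced `cohort_state`.
#' @export
run_step <- function(state) {
  if (!inherits(state, "cohort_state")) stop("expected a `cohort_state`")
  day <- state$day
  steps_day <- state$schedule$daily_steps[day]
  bs <- state$schedule$block_size
  n_blocks <- steps_day %/% bs
  if (state$step_in_block >= bs) {       # roll into next block/day
    state$step_in_block <- 0L
    state$block <- state$block + 1L
    if (state$block > n_blocks) {
      state$block <- 1L
      state$day <- day <- day + 1L
      steps_day <- state$schedule$daily_steps[day]
      n_blocks <- steps_day %/% bs
    }
  }
  is_hs <- state$block %% 2L == 1L
  s_step <- (1 - state$params$daily_mortality)^(1 / steps_day)
  wild_rem <- state$params$p_wild * state$response$f_by_day[day]
  active <- .bait_active(state$cb, day, state$block, n_blocks)
  tal <- state$tallies
  tal$f_day <- .bait_f_day(state$cb, day, state$response)
  out <- .one_step(state$field, state$pools, tal, state$kernel, state$cb,
                   active, is_hs, s_step, wild_rem)
  state$field <- out$F
  state$pools <- out$pools
  out$tal$f_day <- NULL
  state$tallies <- out$tal
  state$step_in_block <- state$step_in_block + 1L
  if (state$step_in_block == bs && is_hs) {
    rel <- .release_pools(state$field, state$pools, state$cb)
    state$field <- rel$F
    state$pools <- rel$pools
    .check_books(state)
  }
  state
}

.check_books <- function(st) {
  tot <- sum(st$field) + sum(st$pools) + st$tallies$fed_wild +
    st$tallies$dead + st$tallies$starved + sum(st$tallies$caught)
  if (abs(tot - st$initial_total) > st$check_tol * max(1, st$initial_total))
    stop("bookkeeping identity violated: total ", format(tot),
         " vs initial ", format(st$initial_total))
  if (min(st$field) < -st$check_tol)
    stop("negative fly density encountered")
  invisible(TRUE)
}

#' Run a cohort through (part of) its hunger cycle
#'
#' Simulates days `start_day` to `end_day` of the six-day cycle. If the
#' run reaches the end of the starvation day (day 6), all remaining
#' active flies are tallied as starved. Returns per-day cumulative
#' tallies and the final state.
#'
#' @inheritParams cohort_state
#' @param end_day last cycle day to simulate (at most 6).
#' @return an object of class `cycle_result`: a list with `caught`
#'   (per-bait totals), `fed_wild`, `dead`, `starved`, `field` (final
#'   active densities), `daily` (data frame of cumulative tallies per
#'   day), `initial_total`, `good_area_km2`.
#' @export
run_cycle <- function(grid, baits = list(), schedule = step_schedule(),
                      response = response_schedule(),
                      params = cohort_params(),
                      dispersal = dispersal_params(),
                      scaling = bait_scaling(),
                      initial = NULL, initial_total = 1,
                      start_day = 1L, end_day = 6L, check_tol = 1e-9) {
  start_day <- as.integer(start_day); end_day <- as.integer(end_day)
  n_days <- length(schedule$daily_steps)
  if (start_day < 1L || end_day > n_days || start_day > end_day)
    stop("days must satisfy 1 <= start_day <= end_day <= ", n_days)
  st <- cohort_state(grid, baits, schedule, response, params, dispersal,
                     scaling, initial, initial_total, start_day, check_tol)
  bs <- schedule$block_size
  daily <- vector("list", end_day - start_day + 1L)
  for (day in start_day:end_day) {
    steps_day <- schedule$daily_steps[day]
    n_blocks <- steps_day %/% bs
    s_step <- (1 - params$daily_mortality)^(1 / steps_day)
    wild_rem <- params$p_wild * response$f_by_day[day]
    f_day <- .bait_f_day(st$cb, day, response)
    F <- st$field; pools <- st$pools; tal <- st$tallies
    tal$f_day <- f_day
    for (block in seq_len(n_blocks)) {
      is_hs <- block %% 2L == 1L
      active <- .bait_active(st$cb, day, block, n_blocks)
      for (s in seq_len(bs)) {
        out <- .one_step(F, pools, tal, st$kernel, st$cb, active, is_hs,
                         s_step, wild_rem)
        F <- out$F; pools <- out$pools; tal <- out$tal
      }
      if (is_hs) {
        rel <- .release_pools(F, pools, st$cb)
        F <- rel$F; pools <- rel$pools
      }
    }
    tal$f_day <- NULL
    st$field <- F; st$pools <- pools; st$tallies <- tal
    st$day <- day
    .check_books(st)
    if (day == params$starvation_day) {
      left <- sum(st$field) + sum(st$pools)
      st$tallies$starved <- st$tallies$starved + left
      st$field[] <- 0
      st$pools[] <- 0
    }
    daily[[day - start_day + 1L]] <- data.frame(
      day = day, steps = steps_day,
      fed_wild = st$tallies$fed_wild,
      caught = sum(st$tallies$caught),
      dead = st$tallies$dead,
      starved = st$tallies$starved,
      active_remaining = sum(st$field))
  }
  structure(list(
    caught = st$tallies$caught, fed_wild = st$tallies$fed_wild,
    dead = st$tallies$dead, starved = st$tallies$starved,
    field = st$field, daily = do.call(rbind, daily),
    initial_total = st$initial_total,
    good_area_km2 = geometry_summary(grid)$good_area_km2),
    class = "cycle_result")
}

#' @export
print.cycle_result <- function(x, ...) {
  cat("<cycle_result>\n")
  cat(sprintf("  initial %.6g | caught %.6g | fed wild %.6g | dead %.6g | starved %.6g | active %.6g\n",
              x$initial_total, sum(x$caught), x$fed_wild, x$dead,
              x$starved, sum(x$field)))
  invisible(x)
}

#' Starvation probability of flies still unfed after day d
#'
#' Among flies alive and unfed at the end of cycle day `d`, the
#' probability that the feeding question is eventually resolved by
#' starvation rather than by a meal: the model is run to day `d`, the
#' unfed field is renormalised, the run continues to the end of the
#' cycle, and the starved total is divided by the starved-plus-fed total.
#' Deaths from causes other than starvation remove flies before their
#' feeding fate is decided, so they appear in neither the numerator nor
#' the denominator. (They cannot be part of the reported probability: on
#' the slowest schedules it exceeds `1 - daily_mortality`, which is the
#' ceiling any definition charging those deaths to the denominator would
#' impose.)
#'
#' @inheritParams run_cycle
#' @param day_completed `d`, between 1 and 5.
#' @return starvation probability (0--1).
#' @export
starvation_probability <- function(grid, baits = list(),
                                   day_completed,
                                   schedule = step_schedule(),
                                   response = response_schedule(),
                                   params = cohort_params(),
                                   dispersal = dispersal_params(),
                                   scaling = bait_scaling(),
                                   initial = NULL, initial_total = 1) {
  d <- as.integer(day_completed)
  if (d < 1L || d > 5L) stop("`day_completed` must be between 1 and 5")
  r1 <- run_cycle(grid, baits, schedule, response, params, dispersal,
                  scaling, initial, initial_total, start_day = 1L,
                  end_day = d)
  unfed <- sum(r1$field)
  if (unfed <= 0) stop("no flies remain unfed at the end of day ", d)
  r2 <- run_cycle(grid, baits, schedule, response, params, dispersal,
                  scaling, initial = r1$field / unfed,
                  start_day = d + 1L, end_day = 6L)
  fed <- sum(r2$caught) + r2$fed_wild
  r2$starved / (r2$starved + fed)
}

#' Per-cycle starvation under wild hosts only (closed form)
#'
#' With no introduced baits the model is spatially uniform and the starved
#' fraction per cycle has the closed form
#' \deqn{\prod_d (1 - m)\,(1 - p\,f_d)^{s_d}}
#' with daily mortality `m`, wild-host step probability `p`, probing
#' response `f_d` and step count `s_d` on day `d`. Agrees exactly with
#' [run_cycle()] on a homogeneous grid with no baits.
#'
#' @param p_wild wild-host step probability.
#' @inheritParams run_cycle
#' @return starved fraction of the initial cohort (0--1).
#' @export
starved_fraction_wild_only <- function(p_wild = 0.00125,
                                       schedule = step_schedule(),
                                       response = response_schedule(),
                                       params = cohort_params()) {
  m <- params$daily_mortality
  f <- response$f_by_day[seq_along(schedule$daily_steps)]
  prod((1 - m) * (1 - p_wild * f)^schedule$daily_steps)
}

#' Calibrate the wild-host encounter probability
#'
#' Finds, by bisection, the per-step wild-host probability at which a
#' criterion of the cycle reaches a target value. The default criterion is
#' the per-cycle starvation fraction with no introduced baits
#' ([starved_fraction_wild_only()]); the default target of 2.7\% recovers
#' the standard 0.00125.
#'
#' @param target target criterion value.
#' @param bracket interval of probabilities bracketing the solution.
#' @param criterion function of the probability returning the criterion
#'   value; must be monotone over the bracket.
#' @param tol relative tolerance of the bisection.
#' @param ... passed to the default criterion
#'   ([starved_fraction_wild_only()]).
#' @return the calibrated probability.
#' @export
goal_seek_wild_prob <- function(target = 0.027, bracket = c(1e-4, 1e-2),
                                criterion = NULL, tol = 1e-6, ...) {
  if (is.null(criterion))
    criterion <- function(p) starved_fraction_wild_only(p, ...)
  g <- function(p) criterion(p) - target
  lo <- g(bracket[1L]); hi <- g(bracket[2L])
  if (sign(lo) == sign(hi))
    stop("criterion does not straddle the target over the bracket")
  stats::uniroot(g, bracket, tol = tol * mean(bracket))$root
}
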