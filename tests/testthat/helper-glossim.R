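# Shared fixtures and the Monte-Carlo walker oracle.

# A small mixed-vegetation grid: mostly good, a poor column, one no-go cell.
mixed_grid <- function(n = 13) {
  e <- matrix(1, n, n)
  e[, n - 2L] <- 0.1
  e[2L, 2L] <- 0
  veg_grid(e, cell_size = 10)
}

# Independent stochastic oracle for the orthogonal movement model: each of
# `n_walkers` walkers attempts, per step, one orthogonal move with
# probability h/4 per direction (staying put otherwise); a move into a
# worse cell succeeds with probability p_dest/p_src and otherwise returns
# to the source cell; a move off the map returns too (mirror boundary).
# Returns the mean straight-line displacement and its standard error.
walker_displacement <- function(grid, n_steps, n_walkers, seed,
                                params = dispersal_params()) {
  set.seed(seed)
  p <- grid$entry
  nr <- nrow(p); nc <- ncol(p)
  start <- central_good_cell(grid)
  r <- rep(start[1L], n_walkers)
  co <- rep(start[2L], n_walkers)
  h <- params$h
  for (s in seq_len(n_steps)) {
    u <- stats::runif(n_walkers)
    dir <- findInterval(u, cumsum(c(h / 4, h / 4, h / 4, h / 4)))
    # dir: 0 = up, 1 = down, 2 = left, 3 = right, 4 = stay
    mv <- dir < 4L
    dr <- integer(n_walkers); dc <- integer(n_walkers)
    dr[dir == 0L] <- -1L; dr[dir == 1L] <- 1L
    dc[dir == 2L] <- -1L; dc[dir == 3L] <- 1L
    r2 <- r + dr; c2 <- co + dc
    on_map <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    ok <- mv & on_map
    ratio <- numeric(n_walkers)
    ratio[ok] <- pmin(1, p[cbind(r2[ok], c2[ok])] / p[cbind(r[ok], co[ok])])
    cross <- ok & stats::runif(n_walkers) < ratio
    r[cross] <- r2[cross]
    co[cross] <- c2[cross]
  }
  d <- grid$cell_size * sqrt((r - start[1L])^2 + (co - start[2L])^2)
  list(mean = mean(d), se = stats::sd(d) / sqrt(n_walkers))
}

# A cheap step schedule for unit tests of the cohort machinery (50 steps a
# day = one host-searching and one general block).
cheap_schedule <- function() step_schedule(daily_steps = rep(50, 6))
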