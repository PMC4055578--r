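#' Dispersal parameters
#'
#' Movement is a series of orthogonal steps on the cell lattice: at each
#' step a fly moves from the centre of its cell to the centre of one of the
#' four orthogonally adjacent cells with probability `h`, and stays put with
#' probability `1 - h`. The default `h = 0.7858` calibrates the orthogonal
#' walk against the classical random walk with 10 m steps (see [match_h()]).
#'
#' @param h step probability in \[0, 1\].
#' @param step_length step (cell) length in metres.
#' @return an object of class `dispersal_params`.
#' @export
dispersal_params <- function(h = 0.7858, step_length = 10) {
  if (!is.numeric(h) || length(h) != 1L || h < 0 || h > 1)
    stop("`h` must be a single probability in [0, 1]")
  if (!is.numeric(step_length) || length(step_length) != 1L || step_length <= 0)
    stop("`step_length` must be positive")
  structure(list(h = h, step_length = step_length),
            class = "dispersal_params")
}

#' Mean displacement of the classical random walk
#'
#' For the classical two-dimensional random walk -- each step of length `x`
#' in a direction drawn uniformly on 0--360 degrees -- the mean straight-line
#' distance from the origin after `n` steps is the Rayleigh mean
#' \deqn{D = x \sqrt{\pi n} / 2.}
#'
#' @param x step length in metres.
#' @param n number of steps.
#' @return mean displacement in metres.
#' @seealso [orthogonal_mean_displacement()], [match_h()]
#' @export
classical_mean_displacement <- function(x, n) {
  if (!is.numeric(x) || any(x <= 0)) stop("`x` must be positive")
  if (!is.numeric(n) || any(n < 0)) stop("`n` must be non-negative")
  x * sqrt(pi * n) / 2
}

#' Exact mean displacement of the orthogonal lattice walk
#'
#' Computes, by deterministic convolution of the step kernel, the exact mean
#' straight-line displacement of a walker that at each of `n` steps moves to
#' one of the four orthogonal neighbours (each with probability `h/4`) or
#' stays put (probability `1 - h`), on an unbounded homogeneous lattice of
#' `x`-metre cells. For `x = 10`, `n = 196`, `h = 1` this gives 124.10 m,
#' slightly above the large-`n` classical value
#' [classical_mean_displacement()] because of the finite-`n` lattice
#' correction.
#'
#' @inheritParams classical_mean_displacement
#' @param h step probability.
#' @return mean displacement in metres.
#' @export
orthogonal_mean_displacement <- function(x, n, h = 1) {
  if (!is.numeric(x) || x <= 0) stop("`x` must be positive")
  n <- as.integer(n)
  if (n < 0) stop("`n` must be non-negative")
  if (n == 0L) return(0)
  sz <- 2L * n + 3L
  f <- matrix(0, sz, sz)
  ctr <- n + 2L
  f[ctr, ctr] <- 1
  q <- h / 4
  for (s in seq_len(n)) {
    up    <- rbind(f[-1L, , drop = FALSE], 0)
    down  <- rbind(0, f[-sz, , drop = FALSE])
    left  <- cbind(f[, -1L, drop = FALSE], 0)
    right <- cbind(0, f[, -sz, drop = FALSE])
    f <- (1 - h) * f + q * (up + down + left + right)
  }
  ii <- row(f) - ctr
  jj <- col(f) - ctr
  sum(f * sqrt(ii^2 + jj^2)) * x
}

#' Match the orthogonal walk to the classical walk
#'
#' The orthogonal lattice walk displaces less per step than the classical
#' walk. The two are matched through a step probability `h`: the classical
#' walk with reduced step length `x h` displaces `x h sqrt(n)` (its
#' root-mean-square), while the orthogonal walk's mean displacement scales
#' as the square root of `h`, `d(h) = d(1) sqrt(h)`. Equating,
#' \deqn{x\,h\,\sqrt{n} = d(1)\,\sqrt{h} \quad\Rightarrow\quad
#'   h = \left(\frac{d(1)}{x\sqrt{n}}\right)^2,}
#' which is independent of the arbitrary choice of `x` and `n` up to the
#' finite-`n` lattice correction in `d(1)`. With `x = 10` m and `n = 196`,
#' `d(1) = 124.1` m and `h = 0.7858`, the value used throughout the model;
#' the large-`n` limit is `pi/4`.
#'
#' @inheritParams classical_mean_displacement
#' @param d_orthogonal mean displacement of the orthogonal walk at `h = 1`;
#'   computed exactly by [orthogonal_mean_displacement()] when `NULL`.
#' @return the matching step probability.
#' @export
match_h <- function(x, n, d_orthogonal = NULL) {
  if (!is.numeric(x) || x <= 0) stop("`x` must be positive")
  if (!is.numeric(n) || n < 1) stop("`n` must be at least 1")
  if (is.null(d_orthogonal))
    d_orthogonal <- orthogonal_mean_displacement(x, n, h = 1)
  (d_orthogonal / (x * sqrt(n)))^2
}

# ---- diffusion kernel ---------------------------------------------------

# Precompute the per-direction crossing-success matrices for a grid.
# Movement from cell s to orthogonal neighbour t succeeds fully when
# entry(t) >= entry(s), else with fraction entry(t)/entry(s); failed
# attempts return to s. Map edges adjoin mirror-image maps, so the flux
# leaving at an edge re-enters the same cell.
.make_kernel <- function(grid, params) {
  p <- grid$entry
  nr <- nrow(p); nc <- ncol(p)
  ratio <- function(dest, src) {
    s <- dest / src
    s[src == 0] <- 0           # no flies can be in no-go cells
    pmin(s, 1)
  }
  up <- down <- left <- right <- matrix(1, nr, nc)
  if (nr > 1L) {
    up[-1L, ]   <- ratio(p[-nr, , drop = FALSE], p[-1L, , drop = FALSE])
    down[-nr, ] <- ratio(p[-1L, , drop = FALSE], p[-nr, , drop = FALSE])
  }
  if (nc > 1L) {
    left[, -1L]   <- ratio(p[, -nc, drop = FALSE], p[, -1L, drop = FALSE])
    right[, -nc]  <- ratio(p[, -1L, drop = FALSE], p[, -nc, drop = FALSE])
  }
  # edge rows/cols keep success 1: the mirror neighbour is identical, and
  # its inflow exactly mirrors the outflow
  list(up = up, down = down, left = left, right = right,
       q = params$h / 4, nr = nr, nc = nc)
}

# One diffusion step. Returns the new field and the inflow (flies that
# changed cell this step, including mirror-boundary returns), which stage 5
# of the cohort update needs.
.diffuse <- function(f, k) {
  q <- k$q
  fu <- q * f * k$up
  fd <- q * f * k$down
  fl <- q * f * k$left
  fr <- q * f * k$right
  nr <- k$nr; nc <- k$nc
  zr <- numeric(nc); zc <- numeric(nr)
  infl <- rbind(fu[-1L, , drop = FALSE], zr) +      # up-movers land one row up
          rbind(zr, fd[-nr, , drop = FALSE]) +
          cbind(fl[, -1L, drop = FALSE], zc) +
          cbind(zc, fr[, -nc, drop = FALSE])
  # mirror boundaries: edge outflux re-enters the same edge cell
  infl[1L, ]  <- infl[1L, ]  + fu[1L, ]
  infl[nr, ]  <- infl[nr, ]  + fd[nr, ]
  infl[, 1L]  <- infl[, 1L]  + fl[, 1L]
  infl[, nc]  <- infl[, nc]  + fr[, nc]
  dimnames(infl) <- NULL                 # rbind/cbind pad rows add names
  list(field = f - (fu + fd + fl + fr) + infl, inflow = infl)
}

#' One orthogonal dispersal step of a fly-density field
#'
#' A fraction `h/4` of each cell's flies attempts to move to each of the
#' four orthogonal neighbours. Attempts succeed fully when the destination
#' entry probability is at least that of the source; otherwise the fraction
#' succeeding equals destination/source. Failed attempts return to the
#' source cell. The map adjoins mirror-image maps on all four sides, so
#' flux leaving an edge re-enters at the same cell. Total flies are
#' conserved exactly.
#'
#' @param field numeric matrix of fly densities, congruent with the grid.
#' @param grid a [veg_grid()].
#' @param params a [dispersal_params()].
#' @param return_inflow also return the matrix of flies that changed cell
#'   during the step.
#' @return the new density matrix, or (if `return_inflow`) a list with
#'   elements `field` and `inflow`.
#' @export
diffuse_step <- function(field, grid, params = dispersal_params(),
                         return_inflow = FALSE) {
  stopifnot_grid(grid)
  if (!is.matrix(field) || !all(dim(field) == dim(grid$entry)))
    stop("`field` must be a matrix with the same dimensions as the grid")
  if (any(field < 0)) stop("fly densities must be non-negative")
  k <- .make_kernel(grid, params)
  out <- .diffuse(field, k)
  if (return_inflow) out else out$field
}

#' Mean displacement of a cohort after n steps
#'
#' Seeds a unit point mass of flies in `seed_cell`, iterates the
#' deterministic diffusion for `n_steps`, and returns the density-weighted
#' mean centre-to-centre distance from the seed cell. When a reference
#' displacement is supplied (typically the same number of steps in a large
#' homogeneous block) the displacement is also expressed as a percentage of
#' it.
#'
#' @param grid a [veg_grid()].
#' @param n_steps number of steps.
#' @param params a [dispersal_params()].
#' @param seed_cell `(row, col)` of the seeded cell; defaults to the good
#'   cell nearest the map centre.
#' @param reference_mean optional reference displacement in metres.
#' @return a list with `mean_displacement_m`, `n_steps`,
#'   `relative_percent` (`NA` when no reference is given).
#' @export
displacement_after <- function(grid, n_steps, params = dispersal_params(),
                               seed_cell = NULL, reference_mean = NULL) {
  stopifnot_grid(grid)
  n_steps <- as.integer(n_steps)
  if (n_steps < 0) stop("`n_steps` must be non-negative")
  if (is.null(seed_cell)) seed_cell <- central_good_cell(grid)
  sr <- seed_cell[1L]; sc <- seed_cell[2L]
  if (grid$entry[sr, sc] <= 0)
    stop("seed cell must have entry probability > 0")
  f <- matrix(0, nrow(grid$entry), ncol(grid$entry))
  f[sr, sc] <- 1
  k <- .make_kernel(grid, params)
  for (s in seq_len(n_steps)) f <- .diffuse(f, k)$field
  dmat <- grid$cell_size *
    sqrt((row(f) - sr)^2 + (col(f) - sc)^2)
  d <- sum(f * dmat) / sum(f)
  list(mean_displacement_m = d, n_steps = n_steps,
       relative_percent = if (is.null(reference_mean)) NA_real_ else
         100 * d / reference_mean)
}

#' Good cell nearest the map centre
#' @param grid a [veg_grid()].
#' @return integer `(row, col)`.
#' @export
central_good_cell <- function(grid) {
  stopifnot_grid(grid)
  ok <- which(grid$entry > 0)
  if (length(ok) == 0L) stop("grid has no habitable cells")
  nr <- nrow(grid$entry)
  r <- (ok - 1L) %% nr + 1L
  co <- (ok - 1L) %/% nr + 1L
  ctr_r <- (nr + 1) / 2; ctr_c <- (ncol(grid$entry) + 1) / 2
  i <- which.min((r - ctr_r)^2 + (co - ctr_c)^2)
  c(r[i], co[i])
}

#' Stationary fly distribution on a grid
#'
#' The crossing rule satisfies detailed balance with a stationary density
#' proportional to the cell entry probability: the flux from a better to a
#' poorer neighbour, throttled by the crossing ratio, then exactly equals
#' the reverse flux. `stationary_field()` returns this fixed point directly
#' (normalised to `total`); [stabilize()] reaches it by iterating
#' [diffuse_step()] and is the general route for arbitrary starting fields.
#'
#' @param grid a [veg_grid()].
#' @param total total number of flies to distribute.
#' @return density matrix summing to `total`.
#' @export
stationary_field <- function(grid, total = 1) {
  stopifnot_grid(grid)
  p <- grid$entry
  if (sum(p) == 0) stop("grid has no habitable cells")
  p / sum(p) * total
}

#' Iterate diffusion to the stabilized pattern
#'
#' Repeats [diffuse_step()] until the largest per-cell change falls below
#' `tol`. The start of every cohort simulation distributes flies according
#' to this stabilized pattern arising from the vegetation arrangement
#' alone.
#'
#' @param field starting density matrix; defaults to uniform over
#'   habitable cells.
#' @param grid a [veg_grid()].
#' @param params a [dispersal_params()].
#' @param tol convergence tolerance on the max per-cell change.
#' @param max_iter iteration cap.
#' @param total normalise the result to this total.
#' @return the stationary density matrix, with the iteration count in
#'   `attr(, "iterations")`.
#' @export
stabilize <- function(field = NULL, grid, params = dispersal_params(),
                      tol = 1e-10, max_iter = 1e6, total = 1) {
  stopifnot_grid(grid)
  if (tol <= 0) stop("`tol` must be positive")
  if (is.null(field)) {
    ok <- grid$entry > 0
    if (!any(ok)) stop("grid has no habitable cells")
    field <- matrix(0, nrow(grid$entry), ncol(grid$entry))
    field[ok] <- 1 / sum(ok)
  }
  field <- field / sum(field) * total
  k <- .make_kernel(grid, params)
  for (it in seq_len(max_iter)) {
    new <- .diffuse(field, k)$field
    if (max(abs(new - field)) < tol) {
      attr(new, "iterations") <- it
      return(new)
    }
    field <- new
  }
  stop("stabilize() did not converge within ", max_iter,
       " iterations (last max change ", format(max(abs(new - field))), ")")
}
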