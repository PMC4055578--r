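test_that("the step-probability calibration reproduces the movement anchors", {
  # exact lattice displacement at h = 1 after 196 steps of 10 m
  expect_equal(orthogonal_mean_displacement(10, 196), 124.1, tolerance = 0.001)
  # classical closed form x * sqrt(pi n) / 2
  expect_equal(classical_mean_displacement(10, 196), 10 * sqrt(pi * 196) / 2)
  # matching h, and its independence of the step length
  h <- match_h(10, 196)
  expect_equal(h, 0.7858, tolerance = 7e-4)
  expect_equal(match_h(25, 196), h)
})

test_that("diffusion conserves flies and obeys the crossing rule", {
  g <- mixed_grid()
  f <- stationary_field(g, 1000)
  tot <- sum(f)
  for (i in 1:50) f <- diffuse_step(f, g)
  expect_lt(abs(sum(f) - tot), 50 * 1e-12 * tot)
  expect_true(all(f >= 0))

  # h = 1 moves a point mass entirely to its four neighbours
  g5 <- make_block(5, n_rows = 5, n_cols = 5)
  p <- matrix(0, 5, 5); p[3, 3] <- 1
  p1 <- diffuse_step(p, g5, dispersal_params(h = 1))
  expect_equal(p1[3, 3], 0)
  expect_equal(unname(p1[cbind(c(2, 4, 3, 3), c(3, 3, 2, 4))]), rep(0.25, 4))

  # good -> poor crossing: h/4 attempt, fraction 0.1 crosses, rest returns
  e <- matrix(0, 3, 3); e[2, 2] <- 1; e[2, 3] <- 0.1
  gc <- veg_grid(e)
  f0 <- matrix(0, 3, 3); f0[2, 2] <- 1
  h <- dispersal_params()$h
  f1 <- diffuse_step(f0, gc)
  expect_equal(f1[2, 3], (h / 4) * 0.1)
  expect_equal(f1[2, 2], 1 - (h / 4) * 0.1)

  # mirror boundary: a 1x1 habitable map loses nothing
  g1 <- veg_grid(matrix(1, 1, 1))
  expect_equal(diffuse_step(matrix(1, 1, 1), g1), matrix(1, 1, 1))
})

test_that("stationary density is proportional to entry probability", {
  ck <- make_checkerboard(5, n_rows = 20, n_cols = 20)
  st <- stationary_field(ck, 1)
  good <- st[ck$entry == 1]
  poor <- st[ck$entry == 0.1]
  expect_equal(mean(good) / mean(poor), 10)
  # one diffusion step leaves the stationary field unchanged
  expect_equal(diffuse_step(st, ck), st, tolerance = 1e-12)
  # stabilize() reaches the same fixed point from a uniform start
  sb <- stabilize(grid = ck, tol = 1e-12)
  expect_equal(sb, st, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("displacement scales with the square root of time", {
  g <- make_block(101, n_rows = 101, n_cols = 101)
  d1 <- displacement_after(g, 100)$mean_displacement_m
  d4 <- displacement_after(g, 400)$mean_displacement_m
  expect_equal(d4 / d1, 2, tolerance = 0.02)
})

test_that("deterministic diffusion matches the Monte-Carlo walker oracle", {
  g <- mixed_grid()
  n_steps <- 30
  det <- displacement_after(g, n_steps)$mean_displacement_m
  mc <- walker_displacement(g, n_steps, n_walkers = 150000, seed = 421)
  expect_lt(abs(det - mc$mean), 3 * mc$se)
})

test_that("habitat geometry orders displacement as expected", {
  n <- 1000
  band5 <- displacement_after(make_band(5), n)$mean_displacement_m
  block5 <- displacement_after(make_block(5, outside = "nogo"),
                               n)$mean_displacement_m
  band1 <- displacement_after(make_band(1), n)$mean_displacement_m
  block20 <- displacement_after(make_block(20, outside = "nogo"),
                                n)$mean_displacement_m
  # band > block at equal width; displacement increases with width
  expect_gt(band5, block5)
  expect_gt(band5, band1)
  expect_gt(block20, block5)

  # a dead-end bush pattern slows displacement below the open band
  b <- make_band(5)
  maze <- add_bushes(b, bush_pattern(b, "maze"))
  expect_lt(displacement_after(maze, n)$mean_displacement_m, band5)
})
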