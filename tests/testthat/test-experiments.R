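test_that("even placement respects density, spacing and grouping", {
  # serpentine band, one bait per km of band axis
  g <- make_band(1, serpentine = TRUE)
  L <- length(g$band_path)
  area <- geometry_summary(g)$good_area_km2
  baits <- place_baits_evenly(g, "lizard", density = 100)
  expect_equal(length(baits), round(100 * area))
  nr <- nrow(g$entry)
  at <- match(vapply(baits, function(b)
    (b$position[2L] - 1L) * nr + b$position[1L], integer(1)), g$band_path)
  expect_false(anyNA(at))                      # all on the band path
  expect_true(all(abs(diff(at) - L / length(baits)) <= 2))

  # grouped placement: same overall density, consecutive path cells
  gb <- place_baits_evenly(g, "lizard", density = 100, grouped = TRUE,
                           group_size = 4L)
  expect_equal(length(gb), 4 * round(round(100 * area) / 4))
  atg <- match(vapply(gb, function(b)
    (b$position[2L] - 1L) * nr + b$position[1L], integer(1)), g$band_path)
  expect_true(all(diff(atg)[seq_along(atg) %% 4 != 0] == 1))

  # block habitat: a square lattice inside the good area
  blk <- make_block(200)
  bb <- place_baits_evenly(blk, "large_target", density = 100)
  expect_equal(length(bb), 400)
  pos <- t(vapply(bb, `[[`, integer(2), "position"))
  expect_equal(length(unique(pos[, 1])), 20)
  expect_equal(length(unique(pos[, 2])), 20)
  expect_true(all(blk$entry[pos] == 1))
})

test_that("nearest-bait distance matches a hand-computed oracle", {
  # straight 1-cell band of 41 cells, one bait at the centre: the
  # stationary field is uniform on the band, so the mean along-path
  # distance is mean(|i - 21|) cells
  g <- make_band(1, n_rows = 5, n_cols = 41)
  b <- list(bait_spec("large_target", c(3L, 21L)))
  expect_equal(nearest_bait_distance(g, baits = b),
               mean(abs(seq_len(41) - 21)) * 10)
  # two baits: distance to the nearer one
  b2 <- c(b, list(bait_spec("large_target", c(3L, 1L))))
  d2 <- pmin(abs(seq_len(41) - 21), abs(seq_len(41) - 1))
  expect_equal(nearest_bait_distance(g, baits = b2), mean(d2) * 10)
  # Euclidean metric on a block
  blk <- veg_grid(matrix(1, 9, 9))
  bb <- list(bait_spec("large_target", c(5L, 5L)))
  r <- rep(1:9, 9); co <- rep(1:9, each = 9)
  expect_equal(nearest_bait_distance(blk, baits = bb),
               mean(sqrt((r - 5)^2 + (co - 5)^2)) * 10)
})

test_that("crossover designs reject competing sites", {
  g <- veg_grid(matrix(1, 40, 50))
  a <- bait_spec("elephant", c(1L, 1L), has_odor = TRUE, wind = "E",
                 response = "fixed")
  b <- bait_spec("elephant", c(1L, 1L), response = "fixed")
  near <- crossover_design(sites = rbind(c(20L, 10L), c(20L, 14L)))
  expect_error(crossover_catch(g, a, b, near), "overlap")
})

test_that("a crossover catch splits between the two baits sensibly", {
  g <- make_band(3, n_rows = 9, n_cols = 120)
  # four blocks a day, so the second-half window holds a searching block
  sched <- step_schedule(daily_steps = rep(100, 6))
  a <- bait_spec("warthog", c(1L, 1L), has_odor = TRUE, wind = "E",
                 response = "fixed")
  b <- bait_spec("warthog", c(1L, 1L), response = "fixed")
  out <- crossover_catch(g, a, b, schedule = sched)
  expect_true(all(out$catch_percent > 0))
  # odour-baited catch exceeds the odourless catch
  expect_gt(out$catch_percent["a"], out$catch_percent["b"])
  # and the efficacy wrapper reports the same comparison
  eff <- odor_efficacy_experiment(g, "warthog", schedule = sched)
  expect_equal(unname(out$catch_percent["a"]), eff$catch_vo)
  expect_equal(unname(out$catch_percent["b"]), eff$catch_v)
  expect_gt(eff$efficacy_percent, 0)
})

test_that("feeding success shuts off wild hosts and penalises grouping", {
  g <- make_band(1, serpentine = TRUE, n_rows = 40, n_cols = 40)
  sched <- cheap_schedule()
  # a density giving exactly four hosts, so one group of four holds the
  # same total as the singly-placed comparison
  dens <- 4 / geometry_summary(g)$good_area_km2
  singly <- feeding_success(g, "kudu", density = dens, schedule = sched)
  grouped <- feeding_success(g, "kudu", density = dens, grouped = TRUE,
                             group_size = 4L, schedule = sched)
  expect_equal(singly$n_hosts, 4L)
  expect_equal(grouped$n_hosts, 4L)
  expect_equal(singly$result$fed_wild, 0)
  expect_gt(singly$fed_percent, 0)
  # the same hosts bunched into groups are harder to find
  expect_lt(grouped$fed_percent, singly$fed_percent)
  # a longer horizon can only increase cumulative feeding
  longer <- feeding_success(g, "kudu", density = dens, horizon_days = 6L,
                            schedule = sched)
  expect_gt(longer$fed_percent, singly$fed_percent)
})

test_that("target kill rates start at zero and rise with density", {
  g <- make_band(3)
  sched <- cheap_schedule()
  expect_equal(target_efficacy(g, "large_target",
                               density = 0)$kill_percent_per_cycle, 0)
  k1 <- target_efficacy(g, "large_target", density = 50, schedule = sched)
  k2 <- target_efficacy(g, "large_target", density = 200, schedule = sched)
  expect_gt(k1$kill_percent_per_cycle, 0)
  expect_gt(k2$kill_percent_per_cycle, k1$kill_percent_per_cycle)
  expect_equal(k2$n_targets, 4 * k1$n_targets)
})
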