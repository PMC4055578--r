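test_that("mobility multipliers rescale the cycle in 50-step units", {
  expect_equal(sum(step_schedule()$daily_steps), 6000)
  third <- step_schedule(multiplier = 1 / 3)$daily_steps
  triple <- step_schedule(multiplier = 3)$daily_steps
  expect_equal(sum(third), 2000)
  expect_equal(sum(triple), 18000)
  expect_true(all(c(third, triple) %% 50 == 0))
  expect_error(step_schedule(multiplier = 0), "positive")
})

test_that("a homogeneous baitless cycle matches the closed form exactly", {
  g <- veg_grid(matrix(1, 5, 5))
  sched <- cheap_schedule()
  res <- run_cycle(g, schedule = sched)
  expect_equal(res$starved, starved_fraction_wild_only(schedule = sched))
  expect_equal(sum(res$field), 0)  # everyone is resolved by day 6
  expect_equal(sum(res$caught) + res$fed_wild + res$dead + res$starved,
               res$initial_total)
  # per-day tallies are cumulative and monotone
  expect_true(all(diff(res$daily$fed_wild) > 0))
  expect_true(all(diff(res$daily$dead) > 0))
})

test_that("run_step agrees with run_cycle over a full day", {
  g <- veg_grid(matrix(1, 7, 7))
  g$entry[4, 2] <- 0.1
  sched <- cheap_schedule()
  baits <- list(bait_spec("warthog", c(4L, 6L), response = "day"))
  st <- cohort_state(g, baits, schedule = sched)
  for (i in seq_len(sched$daily_steps[1])) st <- run_step(st)
  res <- run_cycle(g, baits, schedule = sched, end_day = 1L)
  expect_equal(st$field, res$field)
  expect_equal(sum(st$tallies$caught), sum(res$caught))
  expect_equal(st$tallies$fed_wild, res$fed_wild)
})

test_that("inactive pools fill during a block and empty at its end", {
  g <- veg_grid(matrix(1, 7, 7))
  baits <- list(bait_spec("warthog", c(4L, 4L), response = "day"))
  st <- cohort_state(g, baits, schedule = cheap_schedule())
  for (i in 1:10) st <- run_step(st)
  expect_gt(st$pools[1], 0)          # 1 - f of recruits held mid-block
  for (i in 11:25) st <- run_step(st)
  expect_equal(unname(st$pools[1]), 0)  # released at the block end
  expect_gt(st$tallies$caught[1], 0)
})

test_that("baits reduce starvation and capture part of the cohort", {
  g <- veg_grid(matrix(1, 9, 9))
  sched <- cheap_schedule()
  base <- run_cycle(g, schedule = sched)
  baited <- run_cycle(g, list(bait_spec("elephant", c(5L, 5L))),
                      schedule = sched)
  expect_gt(sum(baited$caught), 0)
  expect_lt(baited$starved, base$starved)
  expect_lt(baited$fed_wild, base$fed_wild)  # competition for flies
})

test_that("goal seeking recovers the wild-host probability", {
  target <- starved_fraction_wild_only(0.00125)
  p <- goal_seek_wild_prob(target = target)
  expect_equal(p, 0.00125, tolerance = 1e-5 / 0.00125)
  expect_error(goal_seek_wild_prob(target = 0.9, bracket = c(1e-4, 2e-4)),
               "straddle")
})

test_that("starvation probability is a probability and behaves sensibly", {
  g <- make_band(3, n_rows = 9, n_cols = 60)
  sched <- cheap_schedule()
  prm <- cohort_params(p_wild = 0)   # feeding only on the mapped host
  baits <- list(bait_spec("warthog", c(5L, 30L), response = "day"))
  p2 <- starvation_probability(g, baits, day_completed = 2,
                               schedule = sched, params = prm)
  p5 <- starvation_probability(g, baits, day_completed = 5,
                               schedule = sched, params = prm)
  expect_true(p2 > 0 && p2 < 1)
  # flies still unfed late in the cycle are more likely to starve
  expect_gt(p5, p2)
  # more hosts lower the risk
  more <- list(bait_spec("warthog", c(5L, 15L), response = "day"),
               bait_spec("warthog", c(5L, 45L), response = "day"))
  expect_lt(starvation_probability(g, more, day_completed = 2,
                                   schedule = sched, params = prm), p2)
  expect_error(starvation_probability(g, baits, day_completed = 6,
                                      schedule = sched), "between 1 and 5")
})
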