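test_that("detection ranges reproduce the published host table", {
  m <- host_masses
  expect_equal(round(visual_range(m)),
               c(lizard = 2, warthog = 6, kudu = 11, elephant = 28))
  expect_equal(round(olfactory_range(m)),
               c(lizard = 6, warthog = 27, kudu = 76, elephant = 299))
})

test_that("visual footprints match the mass-matched cell blocks", {
  g <- make_block(200)
  at <- c(100L, 100L)
  n_cells <- function(kind, ...)
    nrow(visual_footprint(bait_spec(kind, at, ...), g))
  expect_equal(n_cells("warthog"), 1)
  expect_equal(n_cells("kudu"), 4)
  expect_equal(n_cells("elephant"), 25)
  expect_equal(n_cells("large_target"), 2)

  # sub-cell stimulation fractions
  frac <- function(kind, ...)
    visual_footprint(bait_spec(kind, at, ...), g)$fraction
  expect_equal(frac("lizard"), 0.5)
  expect_equal(frac("lizard", has_odor = TRUE), 0.8)
  expect_equal(frac("tiny_target"), 0.25)
  expect_true(all(frac("elephant") == 1))

  expect_error(bait_spec("tiny_target", at, has_odor = TRUE), "odor")
  expect_error(bait_spec("custom_host", at), "mass")
  expect_equal(n_cells("custom_host", mass = 333), 4)  # kudu-mass custom host
})

test_that("plume rasterisation agrees with a brute-force triangle oracle", {
  g <- make_block(120, n_rows = 120, n_cols = 120)
  at <- c(60L, 30L)
  sp <- bait_spec("elephant", at, has_odor = TRUE, wind = "E")
  fp <- plume_footprint(sp, g)
  # oracle: scan every cell; centre strictly inside the downwind triangle
  R <- olfactory_range(sp$mass)
  tn <- tan(26 * pi / 180)
  oracle <- NULL
  for (r in 1:120) for (co in 1:120) {
    dx <- (co - at[2]) * 10          # downwind (east) distance, m
    dy <- (r - at[1]) * 10           # lateral distance, m
    if (dx > 0 && dx <= R && abs(dy) < dx * tn)
      oracle <- rbind(oracle, c(r, co))
  }
  expect_setequal(paste(fp$row, fp$col), paste(oracle[, 1], oracle[, 2]))
  expect_true(all(fp$fraction == 1))

  # rotating the wind rotates the cell set
  fpN <- plume_footprint(bait_spec("elephant", at, has_odor = TRUE,
                                   wind = "N"), g)
  rotated <- paste(at[1] - (fp$col - at[2]), at[2] + (fp$row - at[1]))
  expect_setequal(paste(fpN$row, fpN$col), rotated)

  # odorless baits and lizards have no plume
  expect_equal(nrow(plume_footprint(bait_spec("elephant", at), g)), 0)
  expect_equal(nrow(plume_footprint(bait_spec("lizard", at,
                                              has_odor = TRUE), g)), 0)
})

test_that("footprints near the map edge are clipped with a warning", {
  g <- make_block(60, n_rows = 60, n_cols = 60)
  sp <- bait_spec("elephant", c(30L, 55L), has_odor = TRUE, wind = "E")
  expect_warning(fp <- bait_footprint(sp, g), "clipped")
  expect_true(all(fp$col <= 60))
  # a large-target plume uses the fixed 60 m artificial-odor range
  lt <- plume_footprint(bait_spec("large_target", c(30L, 30L),
                                  has_odor = TRUE, wind = "E"), g)
  expect_true(all((lt$col - 30) * 10 <= 60))
  expect_gt(nrow(lt), 0)
})

test_that("bait rosters round-trip through CSV", {
  baits <- list(
    bait_spec("lizard", c(5L, 6L)),
    bait_spec("elephant", c(50L, 60L), has_odor = TRUE, wind = "W",
              response = "day"),
    bait_spec("custom_host", c(9L, 9L), mass = 120))
  f <- tempfile(fileext = ".csv")
  write_bait_roster(baits, f)
  back <- read_bait_roster(f)
  expect_equal(length(back), 3)
  for (i in seq_along(baits)) {
    expect_equal(back[[i]]$kind, baits[[i]]$kind)
    expect_equal(back[[i]]$position, baits[[i]]$position)
    expect_equal(back[[i]]$mass, baits[[i]]$mass)
    expect_equal(back[[i]]$has_odor, baits[[i]]$has_odor)
    expect_equal(back[[i]]$wind, baits[[i]]$wind)
    expect_equal(back[[i]]$response, baits[[i]]$response)
  }
})
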