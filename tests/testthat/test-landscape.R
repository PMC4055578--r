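test_that("blocks and straight bands have the documented geometry", {
  g <- make_block(40)
  expect_identical(dim(g), c(200L, 200L))
  expect_setequal(unique(as.vector(g$entry)), c(1, 0.1))
  expect_equal(sum(g$entry == 1), 40^2)
  expect_equal(geometry_summary(g)$good_area_km2, 40^2 * 100 / 1e6)

  gn <- make_block(5, outside = "nogo", n_rows = 21, n_cols = 21)
  expect_setequal(unique(as.vector(gn$entry)), c(1, 0))
  # centred: the central cell is good
  expect_equal(gn$entry[11, 11], 1)

  b <- make_band(5)
  expect_equal(sum(b$entry == 1), 5 * 200)
  expect_equal(length(b$band_path), 200)
  expect_true(all(b$entry[b$band_path] == 1))
  expect_equal(b$band_width, 5L)
  bp <- make_band(3, flank = "poor")
  expect_setequal(unique(as.vector(bp$entry)), c(1, 0.1))

  v <- make_band(5, orientation = "vertical")
  expect_equal(v$entry, t(make_band(5)$entry))

  # areas partition the map
  gs <- geometry_summary(bp)
  expect_equal(gs$good_area_km2 + gs$poor_area_km2 + gs$nogo_area_km2, 4)
})

test_that("the serpentine band is one connected, contiguous path", {
  g <- make_band(1, serpentine = TRUE)
  path <- g$band_path
  expect_true(all(g$entry[path] == 1))
  # successive path cells are 4-neighbours (a fly can walk the band)
  nr <- nrow(g$entry)
  r <- (path - 1L) %% nr + 1L
  co <- (path - 1L) %/% nr + 1L
  expect_true(all(abs(diff(r)) + abs(diff(co)) == 1L))
  # the band is a single component and the gap rows are no-go
  comp <- good_components(g)
  expect_equal(attr(comp, "n_components"), 1L)
  expect_equal(g$entry[2, 100], 0)      # first gap row, mid-map
  # a 1-cell band with 1-row gaps covers about half the map
  expect_gt(length(path), 0.45 * 200 * 200)
})

test_that("vegetation grids reject illegal entry probabilities", {
  expect_error(veg_grid(matrix(0.5, 3, 3)), "entry")
  expect_error(make_band(0), "width")
  expect_error(make_block(300), "width")
})

test_that("bushes carve no-go cells and report lost connectivity", {
  b <- make_band(5, n_rows = 11, n_cols = 40)
  cells <- bush_pattern(b, "spaced", period = 6)
  expect_true(all(b$entry[cells] == 1))
  g2 <- add_bushes(b, cells)
  expect_true(all(g2$entry[cells] == 0))
  expect_equal(attr(good_components(g2), "n_components"), 1L)

  # a full-width wall splits a band and is flagged
  b1 <- make_band(1, n_rows = 5, n_cols = 20)
  wall <- cbind(3, 10)
  expect_warning(add_bushes(b1, wall), "disconnected")
  expect_error(add_bushes(b, cbind(1, 1)), "good habitat")
  expect_error(add_bushes(b, cbind(0, 5)), "on the map")
})

test_that("grids round-trip through the ASCII and CSV formats", {
  g <- make_band(3, flank = "poor", n_rows = 17, n_cols = 23)
  fa <- tempfile(fileext = ".asc")
  write_grid_asc(g, fa)
  g2 <- read_grid_asc(fa)
  expect_equal(g2$entry, g$entry)
  expect_equal(g2$cell_size, g$cell_size)

  fc <- tempfile(fileext = ".csv")
  write_grid_csv(g, fc)
  expect_equal(read_grid_csv(fc)$entry, g$entry)

  # strict readers reject entries outside {1, 0.1, 0}
  bad <- readLines(fa)
  bad[7] <- paste(rep("0.5", 23), collapse = " ")
  writeLines(bad, fa)
  expect_error(read_grid_asc(fa), "entry")
  expect_silent(read_grid_asc(fa, strict = FALSE))
})
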