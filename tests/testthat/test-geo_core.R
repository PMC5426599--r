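test_that("GeoJSON layers round-trip byte-identically", {
  reg <- tiny_region(n = 12, seed = 8)
  lay <- reg$districts
  p1 <- file.path(tempdir(), "rt1.geojson")
  p2 <- file.path(tempdir(), "rt2.geojson")
  write_layer(lay, p1)
  back <- read_layer(p1)
  expect_identical(back$unit_id, lay$unit_id)
  expect_identical(back$population, lay$population)
  expect_identical(back$cases, lay$cases)
  write_layer(back, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("layer reading validates structure", {
  bad <- list(type = "FeatureCollection", features = list(
    list(type = "Feature", properties = list(unit_id = "a", population = 1),
         geometry = list(type = "Polygon",
                         coordinates = list(list(c(0, 0), c(1, 0), c(1, 1), c(0, 0))))),
    list(type = "Feature", properties = list(population = 2),
         geometry = list(type = "Polygon",
                         coordinates = list(list(c(2, 0), c(3, 0), c(3, 1), c(2, 0)))))))
  f <- file.path(tempdir(), "bad.geojson")
  writeLines(jsonlite::toJSON(bad, auto_unbox = TRUE), f)
  expect_error(read_layer(f), "feature 2 is missing property 'unit_id'")

  bad$features[[2]]$properties$unit_id <- "a"  # duplicate
  writeLines(jsonlite::toJSON(bad, auto_unbox = TRUE), f)
  expect_error(read_layer(f), "duplicate")
})

test_that("point counting conserves points and honors the boundary tie-break", {
  lay <- grid_layer(3, 3, side = 1000)
  w <- rect_window(0, 3000, 0, 3000)

  # all points inside one cell
  pat <- pp_pattern(c(150, 450, 820), c(120, 510, 930), window = w)
  cnt <- count_points_in_units(pat, lay)
  expect_equal(cnt$cases[cnt$unit_id == "G0101"], 3)
  expect_equal(sum(cnt$cases), 3)

  # conservation on a random pattern over the partition
  set.seed(3)
  xy <- runif_in_poly(200, w$polys)
  pat2 <- pp_pattern(xy[, 1], xy[, 2], window = w)
  cnt2 <- count_points_in_units(pat2, lay)
  expect_equal(sum(cnt2$cases), 200)

  # a point exactly on the shared edge between G0101 and G0201 (x = 1000):
  # counted once, in the lexicographically smallest unit_id
  pat3 <- pp_pattern(1000, 500, window = w)
  cnt3 <- count_points_in_units(pat3, lay)
  expect_equal(sum(cnt3$cases), 1)
  expect_equal(cnt3$cases[cnt3$unit_id == "G0101"], 1)

  # order invariance: shuffle points and units
  perm_units <- c(5, 3, 9, 1, 7, 2, 8, 6, 4)
  lay_p <- unit_layer(lay$unit_id[perm_units], lay$geoms[perm_units],
                      level = "district")
  set.seed(4)
  pp <- sample(200)
  pat4 <- pp_pattern(pat2$x[pp], pat2$y[pp], window = w)
  cnt4 <- count_points_in_units(pat4, lay_p)
  expect_equal(cnt4$cases[match(lay$unit_id, cnt4$unit_id)], cnt2$cases)

  expect_error(count_points_in_units(pat2, unit_layer(character(0), list())),
               "empty")
})

test_that("centroid parent assignment propagates values, falls back to nearest, is idempotent", {
  parents <- grid_layer(2, 1, side = 1000, level = "zone")
  parents$pp <- c(2.37, 1.29)
  child_in <- unit_layer("c1", list(cbind(c(100, 400, 400, 100),
                                          c(100, 100, 400, 400))))
  got <- assign_parent_by_centroid(child_in, parents, field = "pp")
  expect_equal(got$parent_id, "G0101")
  expect_equal(got$parent_field[1], 2.37)

  # all parents share one value -> all children share it
  parents2 <- parents; parents2$pp <- c(7, 7)
  many <- unit_layer(c("c1", "c2"), list(
    cbind(c(100, 300, 300, 100), c(100, 100, 300, 300)),
    cbind(c(1200, 1700, 1700, 1200), c(200, 200, 600, 600))))
  got2 <- assign_parent_by_centroid(many, parents2, field = "pp")
  expect_equal(got2$parent_field, c(7, 7), ignore_attr = TRUE)

  # centroid outside all parents: nearest-boundary fallback vs error
  far <- unit_layer("c9", list(cbind(c(5000, 5400, 5400, 5000),
                                     c(100, 100, 400, 400))))
  expect_error(assign_parent_by_centroid(far, parents, fallback_nearest = FALSE),
               "c9")
  gotf <- assign_parent_by_centroid(far, parents)
  expect_equal(gotf$parent_id, "G0201")  # nearest parent boundary

  # idempotence
  again <- assign_parent_by_centroid(got, parents, field = "pp")
  expect_identical(again$parent_id, got$parent_id)
  expect_identical(again$parent_field, got$parent_field)
})

test_that("case tables round-trip through CSV", {
  reg <- tiny_region(n = 10, seed = 2, n_cases = 25)
  f <- file.path(tempdir(), "cases.csv")
  write_cases(reg$cases, f)
  back <- read_cases(f, window = reg$window)
  expect_equal(back$x, reg$cases$x, tolerance = 1e-12)
  expect_identical(back$marks, reg$cases$marks)
})
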