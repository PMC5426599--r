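test_that("district tessellation partitions the window", {
  w <- rect_window(0, 100e3, 0, 100e3)

  d1 <- generate_districts(w, 1, seed = 5)
  expect_length(d1, 1)
  expect_equal(poly_area <- sum(layer_areas(d1)), w$area, tolerance = 1e-12)

  for (n in c(10, 50)) {
    d <- generate_districts(w, n, seed = 1)
    expect_length(d, n)
    expect_lt(abs(sum(layer_areas(d)) - w$area) / w$area, 1e-6)
  }

  d312 <- generate_districts(w, 312, seed = 7)
  expect_length(d312, 312)
  expect_lt(abs(sum(layer_areas(d312)) - w$area) / w$area, 1e-6)

  expect_error(generate_districts(w, 0), "n_districts")
})

test_that("district interiors do not overlap (random-probe check)", {
  w <- rect_window(0, 50e3, 0, 50e3)
  d <- generate_districts(w, 25, seed = 3)
  set.seed(42)
  pts <- runif_in_poly(400, w$polys)
  hits <- rowSums(vapply(d$geoms, function(g)
    points_in_poly(pts[, 1], pts[, 2], g, tol = 0), logical(400)))
  # every probe inside at least one cell; >1 only possible on measure-zero edges
  expect_true(all(hits >= 1))
  expect_gte(mean(hits == 1), 0.99)
})

test_that("same seed reproduces districts bit-identically, different seeds differ", {
  w <- rect_window(0, 80e3, 0, 80e3)
  a <- generate_districts(w, 30, seed = 11)
  b <- generate_districts(w, 30, seed = 11)
  c <- generate_districts(w, 30, seed = 12)
  expect_identical(a$geoms, b$geoms)
  expect_false(identical(a$geoms, c$geoms))
})

test_that("zone assignment nests districts exactly once and conserves totals", {
  w <- rect_window(0, 150e3, 0, 150e3)
  d <- generate_districts(w, 312, seed = 7)
  d <- allocate_population(d, 3163546L, 1, seed = 2)
  d$cases <- rep(1:4, length.out = 312)
  az <- assign_zones(d, 10, seed = 3)
  expect_length(az$zones, 10)
  expect_false(anyNA(az$districts$parent_id))
  expect_setequal(unique(az$districts$parent_id), az$zones$unit_id)
  expect_true(all(table(az$districts$parent_id) >= 1))
  expect_identical(sum(az$zones$population), sum(d$population))
  expect_identical(sum(az$zones$cases), sum(d$cases))
  # zones are contiguous on the district queen graph
  Wd <- queen_contiguity(az$districts)
  memb <- match(az$districts$parent_id, az$zones$unit_id)
  for (z in 1:10) {
    idx <- which(memb == z)
    comp <- geoprev:::graph_components_subset(Wd$nb, idx)
    expect_equal(max(comp), 1)
  }

  # identity mapping when n_zones = n_districts
  dd <- generate_districts(w, 8, seed = 1)
  azi <- assign_zones(dd, 8)
  expect_equal(unname(table(azi$districts$parent_id)), rep(1L, 8),
               ignore_attr = TRUE)
  expect_error(assign_zones(dd, 9), "exceeds")
})

test_that("population allocation is exact, equal in the zero-dispersion limit, reproducible", {
  w <- rect_window(0, 60e3, 0, 60e3)
  d <- generate_districts(w, 13, seed = 4)

  d0 <- allocate_population(d, 100003L, 0, seed = 9)
  expect_identical(sum(d0$population), 100003L)
  expect_lte(max(d0$population) - min(d0$population), 1L)

  d1 <- allocate_population(d, 3163546L, 1.5, seed = 9)
  d2 <- allocate_population(d, 3163546L, 1.5, seed = 9)
  d3 <- allocate_population(d, 3163546L, 1.5, seed = 10)
  expect_identical(sum(d1$population), 3163546L)
  expect_identical(d1$population, d2$population)
  expect_false(identical(d1$population, d3$population))

  expect_error(allocate_population(d, -5L, 1), "total_population")
})

test_that("case simulation respects counts, marks and population weighting", {
  w <- rect_window(0, 20e3, 0, 20e3)
  d <- generate_districts(w, 2, seed = 2)
  d$population <- c(9000L, 1000L)

  empty <- simulate_cases(d, synthetic_config(n_districts = 2, n_zones = 1,
                                              n_cases = 0, seed = 1), window = w)
  expect_length(empty$x, 0)

  dz <- d; dz$population <- c(0L, 0L)
  expect_error(simulate_cases(dz, synthetic_config(n_districts = 2, n_zones = 1,
                                                   n_cases = 5, seed = 1),
                              window = w), "zero")

  # binomial expectation oracle: 200 replicates of 1000 proportional cases
  counts <- vapply(1:200, function(s) {
    cfg <- synthetic_config(n_districts = 2, n_zones = 1, n_cases = 1000L,
                            total_population = 10000L, seed = s)
    cs <- simulate_cases(d, cfg, window = w)
    dd <- count_points_in_units(cs, d)
    dd$cases[1]
  }, numeric(1))
  se <- sqrt(0.9 * 0.1 * 1000)        # binomial sd of the per-replicate count
  expect_lt(abs(mean(counts) - 900), 3 * se / sqrt(200))

  # male share across 500 replicates within 3 Monte-Carlo SEs of 0.467
  males <- vapply(1:500, function(s) {
    cfg <- synthetic_config(n_districts = 2, n_zones = 1, n_cases = 511L,
                            male_fraction = 0.467, seed = 1000 + s)
    mean(simulate_cases(d, cfg, window = w)$marks == "M")
  }, numeric(1))
  mc_se <- sqrt(0.467 * 0.533 / (500 * 511))
  expect_lt(abs(mean(males) - 0.467), 3 * mc_se)
})

test_that("proportional allocation passes chi-square GOF in >= 95% of replicates", {
  w <- rect_window(0, 40e3, 0, 40e3)
  d <- generate_districts(w, 8, seed = 6)
  d <- allocate_population(d, 80000L, 0.8, seed = 3)
  pass <- vapply(1:100, function(s) {
    cfg <- synthetic_config(n_districts = 8, n_zones = 2, n_cases = 400L,
                            total_population = 80000L, seed = 500 + s)
    dd <- count_points_in_units(simulate_cases(d, cfg, window = w), d)
    suppressWarnings(stats::chisq.test(
      dd$cases, p = d$population / sum(d$population))$p.value) > 0.01
  }, logical(1))
  expect_gte(mean(pass), 0.95)
})

test_that("clustered mode produces points inside the window with correct count", {
  w <- rect_window(0, 50e3, 0, 50e3)
  d <- generate_districts(w, 10, seed = 2)
  d <- allocate_population(d, 10000L, 1, seed = 1)
  cfg <- synthetic_config(n_districts = 10, n_zones = 2, n_cases = 200L,
                          clustering = "clustered", parent_intensity = 8,
                          cluster_sd = 2000, seed = 77)
  cs <- simulate_cases(d, cfg, window = w)
  expect_length(cs$x, 200)
  expect_true(all(window_contains(w, cs$x, cs$y)))
  # clustered patterns are more aggregated than CSR: K at 3 km above pi r^2
  k3 <- khat(cs, as_rgrid(seq(0, 3000, by = 500)))
  expect_gt(k3[length(k3)], pi * 3000^2)
})

test_that("island windows split districts into components joined by ferry links", {
  w <- split_window(rect_window(0, 100e3, 0, 100e3))
  expect_length(w$polys, 2)
  d <- generate_districts(w, 30, seed = 5)
  W <- queen_contiguity(d)
  expect_gt(n_components(W), 1)
  fl <- ferry_links(d)
  expect_gte(nrow(fl), 1)
  W2 <- augment_links(W, fl)
  expect_lt(n_components(W2), n_components(W))
})
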