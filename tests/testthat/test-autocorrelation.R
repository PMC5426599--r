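test_that("alternating values on a 4-cycle give I = -1 exactly; constant x errors", {
  W <- row_standardize(cycle_weights(4))
  mt <- global_moran(c(1, -1, 1, -1), W, n_perm = 19, seed = 1)
  expect_equal(mt$I, -1, tolerance = 1e-14)
  expect_error(global_moran(rep(2, 4), W, n_perm = 19), "variance")
})

test_that("global, local and bivariate Moran match dense double-loop oracles", {
  for (seed in c(1, 5)) {
    W <- row_standardize(random_weights(20, seed = seed))
    M <- as_matrix_w(W)
    set.seed(seed + 100)
    x <- rnorm(20); y <- 0.5 * x + rnorm(20)
    mt <- global_moran(x, W, n_perm = 19, seed = 1)
    expect_equal(mt$I, bf_global_moran(x, M), tolerance = 1e-12)
    lm1 <- local_moran(x, W, n_perm = 19, seed = 1)
    expect_equal(lm1$Ii, bf_local_moran(x, M), tolerance = 1e-12)
    bm <- bivariate_local_moran(x, y, W, n_perm = 19, seed = 1)
    expect_equal(bm$Ii, bf_bivariate_local(x, y, M), tolerance = 1e-12)
  }
})

test_that("sum of local Moran equals n times global Moran (row-standardized)", {
  for (seed in 1:5) {
    n <- sample(10:40, 1)
    W <- row_standardize(random_weights(n, seed = seed))
    set.seed(seed)
    x <- rnorm(n)
    mt <- global_moran(x, W, n_perm = 19, seed = 1)
    lm1 <- local_moran(x, W, n_perm = 19, seed = 1)
    expect_lt(abs(sum(lm1$Ii) - n * mt$I), 1e-10)
  }
})

test_that("quadrants follow the signs of value and lag; HL spike detected", {
  # one high value surrounded by equal low values on a star-like path
  W <- row_standardize(path_weights(5))
  x <- c(0, 0, 10, 0, 0)
  lm1 <- local_moran(x, W, n_perm = 99, seed = 2)
  expect_equal(lm1$quadrant[3], "HL")
  expect_lt(lm1$Ii[3], 0)
  expect_equal(lm1$quadrant[2], "LH")  # low value next to the spike
})

test_that("bivariate local Moran reduces to univariate when y = x", {
  W <- row_standardize(random_weights(15, seed = 3))
  set.seed(7)
  x <- rnorm(15)
  uni <- local_moran(x, W, n_perm = 19, seed = 1)
  biv <- bivariate_local_moran(x, x, W, n_perm = 19, seed = 1)
  expect_equal(biv$Ii, uni$Ii, tolerance = 1e-12)
})

test_that("3-node path with antisymmetric z gives all-zero bivariate lags", {
  W <- row_standardize(path_weights(3))
  zx <- c(1, 0, -1)
  zy <- c(-1, 0, 1)
  bm <- bivariate_local_moran(zx, zy, W, n_perm = 19, seed = 1)
  expect_equal(bm$lag, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(bm$Ii, c(0, 0, 0), tolerance = 1e-12)
})

test_that("global bivariate Moran is positive when y smooths x over space", {
  reg <- tiny_region(n = 40, seed = 21)
  W <- row_standardize(queen_contiguity(reg$districts))
  set.seed(11)
  x <- rnorm(40)
  # y = spatially smoothed copy of x (self + neighbor average)
  M <- as_matrix_w(W)
  y <- 0.5 * x + 0.5 * as.numeric(M %*% x)
  bm <- global_moran_bv(x, y, W, n_perm = 199, seed = 5)
  expect_gt(bm$I, 0)
  expect_lte(bm$pseudo_p, 0.05)
})

test_that("permutation inference is reproducible, pseudo-p never zero, isolates excluded", {
  W <- row_standardize(random_weights(12, seed = 8))
  set.seed(3)
  x <- rnorm(12)
  a <- global_moran(x, W, n_perm = 99, seed = 42)
  b <- global_moran(x, W, n_perm = 99, seed = 42)
  expect_identical(a$perm_I, b$perm_I)
  expect_gt(a$pseudo_p, 0)
  la <- local_moran(x, W, n_perm = 99, seed = 42)
  lb <- local_moran(x, W, n_perm = 99, seed = 42)
  expect_identical(la$pseudo_p, lb$pseudo_p)
  expect_true(all(la$pseudo_p > 0))

  # a weights object with an isolate: excluded with a warning
  iso <- unit_layer(c("a", "b", "c", "d"), list(
    cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)),
    cbind(c(1, 2, 2, 1), c(0, 0, 1, 1)),
    cbind(c(2, 3, 3, 2), c(0, 0, 1, 1)),
    cbind(c(9, 10, 10, 9), c(0, 0, 1, 1))))
  Wi <- row_standardize(queen_contiguity(iso))
  expect_warning(mi <- global_moran(c(1, 2, 3, 4), Wi, n_perm = 19, seed = 1),
                 "isolate")
  expect_equal(mi$n, 3)
})

test_that("cluster classification applies alpha without correction and validates input", {
  W <- row_standardize(random_weights(20, seed = 4))
  set.seed(5)
  lm1 <- local_moran(rnorm(20), W, n_perm = 99, seed = 9)
  cl <- classify_clusters(lm1, alpha = 0.05)
  expect_true(all(cl$cluster[!cl$significant] == "NS"))
  expect_true(all(cl$cluster[cl$significant] == cl$quadrant[cl$significant]))
  hi <- classify_clusters(lm1, alpha = 0.999999)
  expect_true(all(hi$cluster == hi$quadrant))
  expect_error(classify_clusters(lm1, alpha = 1.5), "alpha")
  expect_error(classify_clusters(lm1, alpha = 0), "alpha")
})

test_that("under an exchangeable null LISA flags about 5% of units", {
  W <- row_standardize(random_weights(50, seed = 14, p = 0.12))
  frac <- vapply(1:100, function(s) {
    set.seed(4000 + s)
    x <- rnorm(50)
    lm1 <- local_moran(x, W, n_perm = 199, seed = 4000 + s)
    mean(lm1$pseudo_p <= 0.05)
  }, numeric(1))
  expect_gte(mean(frac), 0.02)
  expect_lte(mean(frac), 0.10)
})
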