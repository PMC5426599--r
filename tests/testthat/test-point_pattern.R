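test_that("khat matches the hand formula for two points and is monotone", {
  w <- rect_window(0, 10000, 0, 10000)
  p <- pp_pattern(c(1000, 6000), c(1000, 1000), window = w)  # distance 5000
  r <- as_rgrid(seq(0, 8000, by = 1000))
  k <- khat(p, r)
  expect_equal(k[r < 5000], rep(0, sum(r < 5000)))
  expect_equal(k[r >= 5000], rep(w$area, sum(r >= 5000)))

  rp <- random_pattern(40, seed = 2)
  expect_true(all(diff(khat(rp, as_rgrid(seq(0, 800, by = 20)))) >= 0))
  one <- pp_pattern(1, 1, window = w)
  expect_error(khat(one, r), ">= 2")
})

test_that("khat/cross_k match brute-force double loops to 1e-12", {
  for (seed in c(1, 7)) {
    rp <- random_pattern(50, seed = seed)
    r <- as_rgrid(seq(0, 600, by = 50))
    A <- rp$window$area
    expect_equal(khat(rp, r), bf_khat(rp$x, rp$y, A, r), tolerance = 1e-12)
    expect_equal(cross_k(rp, "M", "F", r),
                 bf_cross_k(rp$x, rp$y, rp$marks, "M", "F", A, r),
                 tolerance = 1e-12)
    expect_equal(difference_k(rp, "M", "F", r),
                 bf_khat(rp$x[rp$marks == "M"], rp$y[rp$marks == "M"], A, r) -
                   bf_khat(rp$x[rp$marks == "F"], rp$y[rp$marks == "F"], A, r),
                 tolerance = 1e-12)
  }
})

test_that("cross_k is symmetric; L transform linearizes; coincident pairs count from r = 0", {
  rp <- random_pattern(60, seed = 4)
  r <- as_rgrid(seq(0, 500, by = 25))
  expect_equal(cross_k(rp, "M", "F", r), cross_k(rp, "F", "M", r))
  expect_equal(cross_l(rp, "M", "F", r), sqrt(cross_k(rp, "M", "F", r) / pi))

  w <- rect_window(0, 100, 0, 100)
  dup <- pp_pattern(c(5, 5, 50), c(5, 5, 50), marks = c("M", "F", "M"), window = w)
  expect_equal(cross_k(dup, "M", "F", as_rgrid(c(0, 10)))[1],
               w$area / (2 * 1) * 1)  # the coincident M-F pair at r = 0
})

test_that("difference_k vanishes on identical coordinate sets and is antisymmetric", {
  w <- rect_window(0, 1000, 0, 1000)
  set.seed(5)
  xs <- runif(8, 0, 1000); ys <- runif(8, 0, 1000)
  same <- pp_pattern(c(xs, xs), c(ys, ys),
                     marks = rep(c("M", "F"), each = 8), window = w)
  r <- as_rgrid(seq(0, 800, by = 100))
  expect_equal(difference_k(same, "M", "F", r), rep(0, length(r)))

  rp <- random_pattern(30, seed = 6)
  expect_equal(difference_k(rp, "M", "F", r), -difference_k(rp, "F", "M", r))
})

test_that("uncorrected khat matches its exact CSR expectation (edge bias included)", {
  # 200 uniform patterns of n = 100 on a square of side L. The uncorrected
  # estimator is downward-biased by edge effects; its exact CSR expectation,
  # from the isotropized set covariance of the square, is
  #   E[K(r)] = pi r^2 - 8 r^3 / (3 L) + r^4 / (2 L^2),
  # a 10.4% deficit at r = L/8 relative to pi r^2 - so the mean curve is
  # checked against this closed form (to 2%), not against pi r^2.
  L <- 1000
  w <- rect_window(0, L, 0, L)
  rv <- c(0, 100, 125)
  rg <- structure(rv, spacing = 1, class = c("rgrid", "numeric"))
  set.seed(10)
  ks <- vapply(1:200, function(s) {
    xy <- runif_in_poly(100, w$polys)
    khat(pp_pattern(xy[, 1], xy[, 2], window = w), rg)
  }, numeric(3))
  m <- rowMeans(ks)
  theory <- pi * rv^2 - 8 * rv^3 / (3 * L) + rv^4 / (2 * L^2)
  expect_lt(abs(m[2] - theory[2]) / theory[2], 0.02)
  expect_lt(abs(m[3] - theory[3]) / theory[3], 0.02)
  expect_lt(m[3], pi * 125^2)  # the omitted edge correction biases K downward
})

test_that("envelopes preserve class sizes, collapse when degenerate, and are seed-stable", {
  rp <- random_pattern(40, seed = 8)
  r <- as_rgrid(seq(0, 400, by = 40))
  e1 <- sim_envelope(rp, "cross_l", n_sim = 39, seed = 5, r = r)
  e2 <- sim_envelope(rp, "cross_l", n_sim = 39, seed = 5, r = r)
  expect_identical(e1$simulations, e2$simulations)
  expect_true(all(e1$lo <= e1$hi))
  expect_equal(dim(e1$simulations), c(39, length(r)))

  # all-one-sex random labeling: every permutation is the identity
  w <- rect_window(0, 1000, 0, 1000)
  set.seed(2)
  xy <- runif_in_poly(15, w$polys)
  mono <- pp_pattern(xy[, 1], xy[, 2], marks = rep("M", 15), window = w)
  em <- sim_envelope(mono, "khat", "random_labeling", n_sim = 19, seed = 1, r = r)
  expect_true(all(abs(sweep(em$simulations, 2, em$observed)) < 1e-12))
  expect_equal(em$lo, em$observed)
  expect_equal(em$hi, em$observed)

  expect_error(sim_envelope(rp, "cross_l", n_sim = 5, r = r), "19")
  # csr null on marked statistics keeps class sizes fixed
  ec <- sim_envelope(rp, "cross_l", null = "csr", n_sim = 19, seed = 3, r = r)
  expect_equal(dim(ec$simulations), c(19, length(r)))
  unmarked <- pp_pattern(rp$x, rp$y, window = rp$window)
  expect_error(sim_envelope(unmarked, "cross_l", null = "csr", n_sim = 19,
                            r = r), "marks")
})

test_that("dclf gives u = 0, p = 1 when observed equals the reference everywhere", {
  rp <- random_pattern(30, seed = 3)
  r <- as_rgrid(seq(0, 300, by = 30))
  env <- sim_envelope(rp, "cross_l", n_sim = 39, seed = 2, r = r)
  m <- nrow(env$simulations)
  env$observed <- colMeans(env$simulations)  # force obs = reference
  t1 <- dclf_test(env, alternative = "two_sided")
  expect_equal(t1$u, 0)
  expect_equal(t1$pseudo_p, 1)
  expect_error(dclf_test(structure(list(simulations = NULL), class = "sim_envelope")),
               "simulations")
})

test_that("dclf pseudo-p is calibrated under the random-labeling null", {
  # 200 null replicates, 199 labelings each: rejection at 0.05 in [0.02, 0.09]
  r <- as_rgrid(seq(0, 400, by = 40))
  rej <- vapply(1:200, function(s) {
    rp <- random_pattern(40, seed = 3000 + s)
    env <- sim_envelope(rp, "difference_k", n_sim = 199, seed = 61 + s, r = r)
    dclf_test(env, alternative = "two_sided")$pseudo_p <= 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
})

test_that("theoretical-reference dclf works for khat under csr", {
  rp <- random_pattern(50, seed = 12)
  r <- as_rgrid(seq(0, 250, by = 25))
  env <- sim_envelope(rp, "khat", "csr", n_sim = 39, seed = 4, r = r)
  t1 <- dclf_test(env, reference = "theoretical", alternative = "two_sided")
  expect_gt(t1$pseudo_p, 0.0)
  expect_error(dclf_test(sim_envelope(rp, "difference_k", n_sim = 19, seed = 1,
                                      r = r), reference = "theoretical"),
               "theoretical")
})
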