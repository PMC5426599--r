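# Brute-force oracles (naive double loops, independent of the package's fast
# paths) and small fixture builders shared across the test files.

## ---- fixtures --------------------------------------------------------------

# nx x ny grid of unit squares (side in meters) as a unit_layer
grid_layer <- function(nx, ny, side = 1000, level = "district") {
  ids <- character(0); geoms <- list()
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    x0 <- (ix - 1) * side; y0 <- (iy - 1) * side
    ids <- c(ids, sprintf("G%02d%02d", ix, iy))
    geoms[[length(geoms) + 1]] <-
      cbind(c(x0, x0 + side, x0 + side, x0), c(y0, y0, y0 + side, y0 + side))
  }
  unit_layer(ids, geoms, level = level)
}

# small seeded Voronoi district layer with populations and cases
tiny_region <- function(n = 20, seed = 1, n_cases = 60, window_km = 50) {
  w <- rect_window(0, window_km * 1e3, 0, window_km * 1e3)
  d <- generate_districts(w, n, seed = seed)
  d <- allocate_population(d, 50000L, 1, seed = seed + 1)
  cfg <- synthetic_config(n_districts = n, n_zones = min(3L, n),
                          total_population = 50000L, n_cases = n_cases,
                          seed = seed + 2)
  cases <- simulate_cases(d, cfg, window = w)
  d <- count_points_in_units(cases, d)
  list(window = w, districts = d, cases = cases)
}

# random marked point pattern on the unit-km square
random_pattern <- function(n, seed, window = rect_window(0, 1000, 0, 1000),
                           p_male = 0.5) {
  set.seed(seed)
  xy <- runif_in_poly(n, window$polys)
  pp_pattern(xy[, 1], xy[, 2],
             marks = ifelse(runif(n) < p_male, "M", "F"), window = window)
}

# hand-built weights: cycle graph 1-2-...-n-1
cycle_weights <- function(n) {
  nb <- lapply(seq_len(n), function(i)
    sort(c(if (i == 1) n else i - 1L, if (i == n) 1L else i + 1L)))
  spatial_weights(sprintf("u%02d", seq_len(n)), nb)
}

# hand-built weights: path graph 1-2-...-n
path_weights <- function(n) {
  nb <- lapply(seq_len(n), function(i)
    sort(c(if (i > 1) i - 1L, if (i < n) i + 1L)))
  spatial_weights(sprintf("u%02d", seq_len(n)), nb)
}

# random symmetric weights on n units (Erdos-Renyi, no isolates by retry)
random_weights <- function(n, p = 0.25, seed = 1) {
  set.seed(seed)
  repeat {
    A <- matrix(runif(n * n) < p, n, n)
    A[lower.tri(A, diag = TRUE)] <- FALSE
    A <- A | t(A)
    if (all(rowSums(A) > 0)) break
  }
  spatial_weights(sprintf("u%02d", seq_len(n)),
                  lapply(seq_len(n), function(i) which(A[i, ])))
}

## ---- oracles ---------------------------------------------------------------

bf_khat <- function(x, y, area, r) {
  n <- length(x)
  vapply(r, function(rv) {
    s <- 0
    for (i in seq_len(n)) for (j in seq_len(n))
      if (i != j && sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) <= rv) s <- s + 1
    area / (n * (n - 1)) * s
  }, numeric(1))
}

bf_cross_k <- function(x, y, marks, a, b, area, r) {
  ia <- which(marks == a); ib <- which(marks == b)
  vapply(r, function(rv) {
    s <- 0
    for (i in ia) for (j in ib)
      if (sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) <= rv) s <- s + 1
    area / (length(ia) * length(ib)) * s
  }, numeric(1))
}

# dense weight matrix from a spatial_weights object
as_matrix_w <- function(W) {
  n <- length(W$ids)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) M[i, W$nb[[i]]] <- W$wts[[i]]
  M
}

bf_global_moran <- function(x, M) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in 1:n) for (j in 1:n) num <- num + M[i, j] * z[i] * z[j]
  (n / sum(M)) * num / sum(z^2)
}

bf_local_moran <- function(x, M) {
  n <- length(x)
  z <- x - mean(x)
  m2 <- sum(z^2) / n
  vapply(1:n, function(i) z[i] / m2 * sum(M[i, ] * z), numeric(1))
}

bf_bivariate_local <- function(x, y, M) {
  n <- length(x)
  sdp <- function(v) sqrt(sum((v - mean(v))^2) / n)
  zx <- (x - mean(x)) / sdp(x)
  zy <- (y - mean(y)) / sdp(y)
  vapply(1:n, function(i) zx[i] * sum(M[i, ] * zy), numeric(1))
}

bf_q <- function(values, strata) {
  sst <- sum((values - mean(values))^2)
  ssw <- 0
  for (l in unique(strata)) {
    v <- values[strata == l]
    ssw <- ssw + sum((v - mean(v))^2)
  }
  1 - ssw / sst
}
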