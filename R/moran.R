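# Global, local and bivariate Moran's I with permutation inference.
#
# Conventions (standard LISA):
#   global   I   = (n/S0) * sum_ij w_ij z_i z_j / sum_i z_i^2,  z = x - mean(x)
#   local    I_i = (z_i / m2) * sum_j w_ij z_j,  m2 = sum_k z_k^2 / n
#   bivariate I_i = zx_i * sum_j w_ij zy_j, zx/zy standardized to mean 0 and
#                   unit population variance
# Isolates (empty weight rows) are dropped from n, S0 and m2 with a warning.

# drop isolates and return triplet + kept index
.moran_prep <- function(x, W) {
  stopifnot(inherits(W, "spatial_weights"))
  n_all <- length(W$ids)
  if (length(x) != n_all)
    stop_invalid("x length (%d) != number of units (%d)", length(x), n_all)
  deg <- vapply(W$nb, length, integer(1))
  keep <- which(deg > 0)
  if (length(keep) < n_all) {
    warning(sprintf("excluding %d isolate(s) from Moran computation: %s",
                    n_all - length(keep),
                    paste(W$ids[deg == 0], collapse = ", ")), call. = FALSE)
    # references to dropped units cannot exist if W is symmetric in structure;
    # for safety, drop any stray links into isolates
  }
  pos <- match(seq_len(n_all), keep)
  nb <- lapply(W$nb[keep], function(v) pos[v])
  wts <- W$wts[keep]
  bad <- vapply(nb, anyNA, logical(1))
  if (any(bad)) {
    for (i in which(bad)) {
      ok <- !is.na(nb[[i]])
      nb[[i]] <- nb[[i]][ok]; wts[[i]] <- wts[[i]][ok]
    }
  }
  i <- rep(seq_along(nb), vapply(nb, length, integer(1)))
  list(x = x[keep], ids = W$ids[keep], keep = keep,
       tr = list(i = i, j = unlist(nb, use.names = FALSE),
                 w = unlist(wts, use.names = FALSE)),
       nb = nb, wts = wts)
}

.moran_stat <- function(z, tr, S0) {
  n <- length(z)
  (n / S0) * sum(tr$w * z[tr$i] * z[tr$j]) / sum(z^2)
}

#' Global Moran's I with permutation inference
#'
#' Tests spatial autocorrelation of `x` under the weights `W`. The null
#' distribution comes from `n_perm` full random permutations of `x` over the
#' units; the default alternative is `greater` (positive autocorrelation),
#' with pseudo-p `(1 + #{I_perm >= I_obs}) / (1 + n_perm)`.
#'
#' @param x Numeric vector, one value per unit of `W` (same order).
#' @param W A [spatial_weights()] (row-standardized or binary).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @param alternative `"greater"` (default), `"less"` or `"two_sided"`.
#' @return Object of class `moran_test`: `I`, `pseudo_p`, `perm_I`, `n`,
#'   `S0`, `alternative`, `seed`.
#' @export
global_moran <- function(x, W, n_perm = 999, seed = 1L,
                         alternative = c("greater", "less", "two_sided")) {
  alternative <- match.arg(alternative)
  prep <- .moran_prep(x, W)
  n <- length(prep$x)
  if (n < 3) stop_invalid("need >= 3 non-isolate units")
  if (stats::var(prep$x) == 0) stop_invalid("x has zero variance")
  z <- prep$x - mean(prep$x)
  S0 <- sum(prep$tr$w)
  I_obs <- .moran_stat(z, prep$tr, S0)
  perm_I <- with_seed(seed, vapply(seq_len(n_perm), function(p) {
    zp <- z[sample.int(n)]
    .moran_stat(zp, prep$tr, S0)
  }, numeric(1)))
  p <- switch(alternative,
    greater = pseudo_p(I_obs, perm_I, "greater"),
    less = pseudo_p(I_obs, perm_I, "less"),
    two_sided = min(1, 2 * min(pseudo_p(I_obs, perm_I, "greater"),
                               pseudo_p(I_obs, perm_I, "less"))))
  structure(list(I = I_obs, pseudo_p = p, perm_I = perm_I, n = n, S0 = S0,
                 n_perm = as.integer(n_perm), alternative = alternative,
                 seed = seed),
            class = "moran_test")
}

#' @export
print.moran_test <- function(x, ...) {
  cat(sprintf("global Moran's I = %.6g, pseudo-p = %.4g (%s, %d permutations, n = %d)\n",
              x$I, x$pseudo_p, x$alternative, x$n_perm, x$n))
  invisible(x)
}

# conditional permutation engine shared by local and bivariate local Moran:
# for unit i, draw its k_i neighbor values from pool[-i] without replacement,
# n_perm times; returns the matrix of permuted spatial lags (n_perm x 1 per
# unit, as a list column). `scale_i` multiplies the lag into the statistic.
.cond_perm_p <- function(scale_i, lag_obs, pool, nb, wts, n_perm, seed) {
  n <- length(scale_i)
  I_obs <- scale_i * lag_obs
  p <- numeric(n)
  with_seed(seed, {
    for (i in seq_len(n)) {
      k <- length(nb[[i]])
      other <- pool[-i]
      w <- wts[[i]]
      idx <- vapply(seq_len(n_perm), function(s) sample.int(n - 1L, k),
                    integer(k))
      lag_perm <- as.numeric(w %*% matrix(other[idx], nrow = k))
      p[i] <- pseudo_p(I_obs[i], scale_i[i] * lag_perm, "two_sided")
    }
  })
  p
}

.quadrant <- function(zval, lag) {
  ifelse(zval >= 0,
         ifelse(lag >= 0, "HH", "HL"),
         ifelse(lag >= 0, "LH", "LL"))
}

#' Local Moran's I (LISA) with conditional permutation
#'
#' Per-unit decomposition of Moran's I, `I_i = (z_i / m2) * lag_i` with
#' `m2 = sum(z^2)/n` (population variance) and `lag_i` the weighted average of
#' neighboring deviations. Significance is by conditional permutation: unit
#' i's value is held fixed while its neighbors' values are drawn without
#' replacement from the other n-1 values, `n_perm` times; the pseudo-p is
#' two-sided on `|I_i|`, since both positive (HH/LL) and negative (HL/LH)
#' cluster centers are of interest.
#'
#' @inheritParams global_moran
#' @param n_perm Conditional permutations per unit (default 9999).
#' @return A data frame of class `local_moran`: `unit_id`, `x`, `z`, `lag`,
#'   `Ii`, `pseudo_p`, `quadrant`. Isolates are excluded.
#' @export
local_moran <- function(x, W, n_perm = 9999, seed = 1L) {
  prep <- .moran_prep(x, W)
  n <- length(prep$x)
  if (n < 3) stop_invalid("need >= 3 non-isolate units")
  if (stats::var(prep$x) == 0) stop_invalid("x has zero variance")
  z <- prep$x - mean(prep$x)
  m2 <- sum(z^2) / n
  lag <- vapply(seq_len(n), function(i) sum(prep$wts[[i]] * z[prep$nb[[i]]]),
                numeric(1))
  Ii <- z / m2 * lag
  p <- .cond_perm_p(z / m2, lag, z, prep$nb, prep$wts, n_perm, seed)
  out <- data.frame(unit_id = prep$ids, x = prep$x, z = z, lag = lag, Ii = Ii,
                    pseudo_p = p, quadrant = .quadrant(z, lag),
                    stringsAsFactors = FALSE)
  attr(out, "n_perm") <- as.integer(n_perm)
  attr(out, "seed") <- seed
  attr(out, "kind") <- "univariate"
  class(out) <- c("local_moran", "data.frame")
  out
}

#' Bivariate local Moran's I across scales
#'
#' Measures the local association between `x` at each unit and `y` in the
#' unit's neighbors — here, district prevalence against zone prevalence copied
#' down to districts. Both variables are standardized to mean 0 and unit
#' population variance; `I_i = zx_i * sum_j w_ij zy_j`. The conditional
#' permutation holds `x` fixed and permutes `y` over the other n-1 units.
#'
#' @param x Child-level variable (one value per unit of `W`).
#' @param y Second variable on the same units (for example the parent value
#'   assigned by [assign_parent_by_centroid()]).
#' @inheritParams local_moran
#' @return A `local_moran` data frame (columns as [local_moran()], plus `y`,
#'   `zy`).
#' @export
bivariate_local_moran <- function(x, y, W, n_perm = 9999, seed = 1L) {
  stopifnot(length(x) == length(y))
  prep <- .moran_prep(x, W)
  y <- y[prep$keep]
  n <- length(prep$x)
  if (n < 3) stop_invalid("need >= 3 non-isolate units")
  if (stats::var(prep$x) == 0 || stats::var(y) == 0)
    stop_invalid("degenerate (constant) variable")
  sdp <- function(v) sqrt(sum((v - mean(v))^2) / length(v))
  zx <- (prep$x - mean(prep$x)) / sdp(prep$x)
  zy <- (y - mean(y)) / sdp(y)
  lag <- vapply(seq_len(n), function(i) sum(prep$wts[[i]] * zy[prep$nb[[i]]]),
                numeric(1))
  Ii <- zx * lag
  p <- .cond_perm_p(zx, lag, zy, prep$nb, prep$wts, n_perm, seed)
  out <- data.frame(unit_id = prep$ids, x = prep$x, y = y, z = zx, zy = zy,
                    lag = lag, Ii = Ii, pseudo_p = p,
                    quadrant = .quadrant(zx, lag), stringsAsFactors = FALSE)
  attr(out, "n_perm") <- as.integer(n_perm)
  attr(out, "seed") <- seed
  attr(out, "kind") <- "bivariate"
  class(out) <- c("local_moran", "data.frame")
  out
}

#' Global bivariate Moran's I
#'
#' `I = (n/S0) * sum_i zx_i lag(zy)_i / n` with both variables standardized
#' to unit population variance; the permutation null permutes `y` wholly while
#' holding `x` fixed.
#'
#' @inheritParams bivariate_local_moran
#' @param alternative As in [global_moran()].
#' @return A `moran_test` object.
#' @export
global_moran_bv <- function(x, y, W, n_perm = 999, seed = 1L,
                            alternative = c("greater", "less", "two_sided")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) == length(y))
  prep <- .moran_prep(x, W)
  y <- y[prep$keep]
  n <- length(prep$x)
  if (n < 3) stop_invalid("need >= 3 non-isolate units")
  if (stats::var(prep$x) == 0 || stats::var(y) == 0)
    stop_invalid("degenerate (constant) variable")
  sdp <- function(v) sqrt(sum((v - mean(v))^2) / length(v))
  zx <- (prep$x - mean(prep$x)) / sdp(prep$x)
  zy <- (y - mean(y)) / sdp(y)
  S0 <- sum(prep$tr$w)
  stat <- function(zyv) (n / S0) * sum(prep$tr$w * zx[prep$tr$i] * zyv[prep$tr$j]) / n
  I_obs <- stat(zy)
  perm_I <- with_seed(seed, vapply(seq_len(n_perm), function(p)
    stat(zy[sample.int(n)]), numeric(1)))
  p <- switch(alternative,
    greater = pseudo_p(I_obs, perm_I, "greater"),
    less = pseudo_p(I_obs, perm_I, "less"),
    two_sided = min(1, 2 * min(pseudo_p(I_obs, perm_I, "greater"),
                               pseudo_p(I_obs, perm_I, "less"))))
  structure(list(I = I_obs, pseudo_p = p, perm_I = perm_I, n = n, S0 = S0,
                 n_perm = as.integer(n_perm), alternative = alternative,
                 seed = seed),
            class = "moran_test")
}

#' Classify LISA cluster centers
#'
#' Labels units with `pseudo_p <= alpha` by their quadrant (HH, LL, HL, LH)
#' and all others `NS`. No multiple-testing correction is applied — by
#' design the map is exploratory, so a flagged unit is an unusual occurrence
#' rather than a confirmed cluster.
#'
#' @param table A [local_moran()] result.
#' @param alpha Significance level in (0, 1), default 0.05.
#' @return The table with `significant` (logical) and `cluster` columns.
#' @export
classify_clusters <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "local_moran"))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop_invalid("alpha must be in (0, 1)")
  table$significant <- table$pseudo_p <= alpha
  table$cluster <- ifelse(table$significant, table$quadrant, "NS")
  attr(table, "alpha") <- alpha
  table
}

#' Export a local Moran table (and optional cluster GeoJSON)
#'
#' @param table A classified [local_moran()] table.
#' @param path CSV destination.
#' @param layer Optional [unit_layer()]; when given, a cluster map GeoJSON
#'   with a `cluster` property is written next to `path`.
#' @return The data frame invisibly.
#' @export
write_local_moran <- function(table, path, layer = NULL) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  if (!is.null(layer)) {
    idx <- match(layer$unit_id, table$unit_id)
    cl <- table$cluster[idx]
    cl[is.na(cl)] <- "excluded"
    gj <- sub("\\.csv$", ".geojson", path)
    lay <- layer
    lay$pp <- layer$pp
    write_layer_with_property(lay, gj, cluster = cl)
  }
  invisible(as.data.frame(table))
}

# plain cluster-map export: standard layer GeoJSON plus one extra property
write_layer_with_property <- function(layer, path, ...) {
  extra <- list(...)
  tmp <- write_layer(layer, path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (nm in names(extra)) {
    v <- extra[[nm]]
    for (i in seq_along(gj$features)) gj$features[[i]]$properties[[nm]] <- v[i]
  }
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = NA, null = "null"),
             path)
  invisible(path)
}
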