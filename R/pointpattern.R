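#' Planar marked point patterns
#'
#' Case locations in planar meters with optional sex marks and an observation
#' window. All points must lie inside (or on the boundary of) the window.
#'
#' @param x,y Numeric coordinate vectors (meters).
#' @param marks Optional per-point labels (for example `"M"`/`"F"`).
#' @param window A [study_window()].
#' @param id Optional per-point ids.
#' @return An object of class `pp_pattern`.
#' @export
pp_pattern <- function(x, y, marks = NULL, window, id = NULL) {
  stopifnot(inherits(window, "study_window"), length(x) == length(y))
  if (!is.null(marks) && length(marks) != length(x))
    stop_invalid("marks length (%d) != number of points (%d)",
                 length(marks), length(x))
  if (length(x) > 0 && !all(window_contains(window, x, y)))
    stop_invalid("%d point(s) outside the window",
                 sum(!window_contains(window, x, y)))
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 marks = if (is.null(marks)) NULL else as.character(marks),
                 window = window, id = id),
            class = "pp_pattern")
}

#' @export
print.pp_pattern <- function(x, ...) {
  cat(sprintf("pp_pattern: %d points in window of %.4g km^2",
              length(x$x), x$window$area / 1e6))
  if (!is.null(x$marks)) {
    tb <- table(x$marks)
    cat(sprintf(" (marks: %s)", paste(names(tb), tb, sep = "=", collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' Distance grid for summary functions
#'
#' Uniformly spaced distances starting at 0. The default, 0 to 80 km in 160 m
#' steps (501 values), is the interval the sex-dependency tests evaluate.
#'
#' @param rmax Maximum distance, meters.
#' @param rstep Grid spacing, meters.
#' @return Numeric vector of class `rgrid` with attribute `spacing`.
#' @export
rgrid <- function(rmax = 80000, rstep = 160) {
  stopifnot(rmax > 0, rstep > 0)
  r <- seq(0, rmax, by = rstep)
  structure(r, spacing = rstep, class = c("rgrid", "numeric"))
}

as_rgrid <- function(r) {
  if (inherits(r, "rgrid")) return(r)
  dr <- diff(r)
  if (r[1] != 0 || any(abs(dr - dr[1]) > 1e-9 * dr[1]))
    stop_invalid("r grid must start at 0 with uniform spacing")
  structure(as.numeric(r), spacing = dr[1], class = c("rgrid", "numeric"))
}

# ---- pair-distance binning --------------------------------------------------
# All estimators reduce to counting point pairs with d <= r_k. Distances are
# computed once; counts come from a cumulative tabulation of bin indices, so
# envelope simulations that only relabel marks cost one tabulate() each.

# bin index such that cumulative counts up to bin k give #{d <= r[k]}
pair_bins <- function(d, r) {
  findInterval(d, r, left.open = TRUE) + 1L
}

bin_cumcount <- function(bins, nr) {
  cumsum(tabulate(bins, nbins = nr + 1L))[seq_len(nr)]
}

# full unordered pair table for a pattern: indices i < j, distance bin
pattern_pairs <- function(pattern, r) {
  n <- length(pattern$x)
  d <- stats::dist(cbind(pattern$x, pattern$y))
  # dist() stores pairs in column-major lower-triangle order: (2,1),(3,1)...
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(k) (k + 1):n), use.names = FALSE)
  list(i = i, j = j, bins = pair_bins(as.numeric(d), r), n = n)
}

#' Ripley's K (uncorrected estimator)
#'
#' `K(r) = (A / (n (n-1))) * sum_{i != j} 1[d_ij <= r]` with `A` the window
#' area. No edge correction is applied anywhere in the package: the
#' sex-dependency tests condition every simulation on the same window and
#' point counts, so the (positive at large r) bias of the uncorrected
#' estimator cancels between observed and simulated curves. Comparisons with
#' the theoretical CSR curve `pi r^2` are therefore only meaningful at small r.
#'
#' @param pattern A [pp_pattern()] with at least 2 points.
#' @param r An [rgrid()] (or uniform vector starting at 0).
#' @return Numeric vector of K estimates along `r`.
#' @export
khat <- function(pattern, r = rgrid()) {
  r <- as_rgrid(r)
  n <- length(pattern$x)
  if (n < 2) stop_invalid("khat needs >= 2 points")
  d <- as.numeric(stats::dist(cbind(pattern$x, pattern$y)))
  cnt <- bin_cumcount(pair_bins(d, r), length(r))
  pattern$window$area / (n * (n - 1)) * 2 * cnt
}

#' Cross-type K and L functions
#'
#' `K_ab(r) = (A / (n_a n_b)) * sum_{i in a} sum_{j in b} 1[d_ij <= r]`,
#' symmetric in the two types; `L_ab = sqrt(K_ab / pi)` linearizes it
#' (`L(r) = r` when `K = pi r^2`).
#'
#' @param pattern A marked [pp_pattern()].
#' @param mark_a,mark_b The two mark values (default `"M"`, `"F"`).
#' @inheritParams khat
#' @return Numeric vector along `r`.
#' @export
cross_k <- function(pattern, mark_a = "M", mark_b = "F", r = rgrid()) {
  r <- as_rgrid(r)
  if (is.null(pattern$marks)) stop_invalid("pattern has no marks")
  a <- which(pattern$marks == mark_a)
  b <- which(pattern$marks == mark_b)
  if (length(a) == 0 || length(b) == 0)
    stop_invalid("empty mark class ('%s': %d, '%s': %d points)",
                 mark_a, length(a), mark_b, length(b))
  dx <- outer(pattern$x[a], pattern$x[b], "-")
  dy <- outer(pattern$y[a], pattern$y[b], "-")
  d <- sqrt(dx * dx + dy * dy)
  cnt <- bin_cumcount(pair_bins(as.numeric(d), r), length(r))
  pattern$window$area / (length(a) * length(b)) * cnt
}

#' @rdname cross_k
#' @export
cross_l <- function(pattern, mark_a = "M", mark_b = "F", r = rgrid()) {
  sqrt(cross_k(pattern, mark_a, mark_b, r) / pi)
}

#' Difference-K between the two mark classes
#'
#' `D(r) = K_a(r) - K_b(r)` using the uncorrected estimator on each
#' sub-pattern (same window area). Departure from 0 under random labeling
#' indicates mark-conditional clustering or dispersion.
#'
#' @inheritParams cross_k
#' @return Numeric vector along `r`.
#' @export
difference_k <- function(pattern, mark_a = "M", mark_b = "F", r = rgrid()) {
  r <- as_rgrid(r)
  sub <- function(mk) {
    sel <- pattern$marks == mk
    if (sum(sel) < 2) stop_invalid("mark class '%s' has < 2 points", mk)
    pp_pattern(pattern$x[sel], pattern$y[sel], window = pattern$window)
  }
  khat(sub(mark_a), r) - khat(sub(mark_b), r)
}

# statistic evaluated from a fixed pair table and a mark vector (fast path
# used by sim_envelope: one tabulate() per simulated labeling)
.stat_from_pairs <- function(stat, pairs, marks, area, mark_a, mark_b, nr) {
  ia <- marks[pairs$i] == mark_a; ja <- marks[pairs$j] == mark_a
  ib <- marks[pairs$i] == mark_b; jb <- marks[pairs$j] == mark_b
  na <- sum(marks == mark_a); nb <- sum(marks == mark_b)
  if (stat == "cross_l" || stat == "cross_k") {
    sel <- (ia & jb) | (ib & ja)
    k <- area / (na * nb) * bin_cumcount(pairs$bins[sel], nr)
    if (stat == "cross_l") sqrt(k / pi) else k
  } else if (stat == "khat") {  # K of the mark_a subpattern
    area / (na * (na - 1)) * 2 * bin_cumcount(pairs$bins[ia & ja], nr)
  } else {  # difference_k
    ka <- area / (na * (na - 1)) * 2 * bin_cumcount(pairs$bins[ia & ja], nr)
    kb <- area / (nb * (nb - 1)) * 2 * bin_cumcount(pairs$bins[ib & jb], nr)
    ka - kb
  }
}

#' Pointwise simulation envelopes
#'
#' Computes the observed summary function and `n_sim` simulated curves under
#' the chosen null, returning rank-1 pointwise envelopes (min/max of the
#' simulations) and the full simulation matrix for the DCLF test. Under
#' `random_labeling` the locations are fixed and the marks permuted,
#' preserving class sizes; under `csr` (for `khat` only) locations are redrawn
#' uniformly in the window.
#'
#' @details The two nulls answer different questions. `random_labeling` holds
#' the locations fixed and permutes the marks, testing whether the labels are
#' associated with the locations (the right null for Difference-K); it cannot
#' detect attraction between two components that share the same clusters,
#' because the labels are then exchangeable. `csr` redraws all locations
#' uniformly in the window, holding class sizes fixed, so the components are
#' independent under the null — the attraction-sensitive null for Cross-L.
#'
#' @param pattern A [pp_pattern()].
#' @param statistic `"cross_l"`, `"cross_k"`, `"difference_k"` or `"khat"`.
#' @param null `"random_labeling"` or `"csr"`.
#' @param n_sim Number of simulations (>= 19; the convention is 199).
#' @param seed Integer seed.
#' @param r An [rgrid()].
#' @param mark_a,mark_b Mark values for the two classes.
#' @return Object of class `sim_envelope` with fields `r`, `observed`,
#'   `simulations` (n_sim x length(r)), `lo`, `hi`, `statistic`, `null`,
#'   `n_sim`, `seed`.
#' @export
sim_envelope <- function(pattern,
                         statistic = c("cross_l", "cross_k", "difference_k", "khat"),
                         null = c("random_labeling", "csr"),
                         n_sim = 199, seed = 1L, r = rgrid(),
                         mark_a = "M", mark_b = "F") {
  statistic <- match.arg(statistic)
  null <- match.arg(null)
  r <- as_rgrid(r)
  if (n_sim < 19) stop_invalid("n_sim must be >= 19")
  nr <- length(r)
  area <- pattern$window$area
  if (null == "random_labeling") {
    if (is.null(pattern$marks)) stop_invalid("random labeling needs marks")
    pairs <- pattern_pairs(pattern, r)
    obs <- .stat_from_pairs(statistic, pairs, pattern$marks, area, mark_a, mark_b, nr)
    sims <- with_seed(seed, {
      t(vapply(seq_len(n_sim), function(s) {
        mk <- sample(pattern$marks)
        .stat_from_pairs(statistic, pairs, mk, area, mark_a, mark_b, nr)
      }, numeric(nr)))
    })
  } else {
    if (statistic != "khat" && is.null(pattern$marks))
      stop_invalid("csr null for marked statistics needs marks")
    n <- length(pattern$x)
    obs <- if (statistic == "khat") khat(pattern, r) else {
      pairs <- pattern_pairs(pattern, r)
      .stat_from_pairs(statistic, pairs, pattern$marks, area, mark_a, mark_b, nr)
    }
    sims <- with_seed(seed, {
      t(vapply(seq_len(n_sim), function(s) {
        xy <- runif_in_poly(n, pattern$window$polys)
        sp <- pp_pattern(xy[, 1], xy[, 2], marks = pattern$marks,
                         window = pattern$window)
        if (statistic == "khat") khat(sp, r) else {
          pr <- pattern_pairs(sp, r)
          .stat_from_pairs(statistic, pr, sp$marks, area, mark_a, mark_b, nr)
        }
      }, numeric(nr)))
    })
  }
  structure(list(r = r, observed = obs, simulations = sims,
                 lo = apply(sims, 2, min), hi = apply(sims, 2, max),
                 statistic = statistic, null = null,
                 n_sim = as.integer(n_sim), seed = seed),
            class = "sim_envelope")
}

#' @export
print.sim_envelope <- function(x, ...) {
  cat(sprintf("sim_envelope: %s under %s, %d simulations, r in [0, %g] m\n",
              x$statistic, x$null, x$n_sim, max(x$r)))
  invisible(x)
}

#' Diggle-Cressie-Loosmore-Ford test
#'
#' Integrates the deviation of the observed curve from a reference over the
#' distance grid, `u = sum_k delta(r_k)^2 * dr`, with
#' `delta = obs - ref` for `two_sided` and `delta = max(obs - ref, 0)` for
#' `greater` (positive deviations only: a one-tailed test for attraction).
#' The same functional is applied to every simulated curve; with
#' `reference = "mean_of_simulations"` each simulation is compared to the mean
#' of the *other* simulations (leave-one-out) while the observed curve is
#' compared to the mean of all of them. The pseudo p-value is
#' `(1 + #{u_sim >= u_obs}) / (1 + n_sim)`.
#'
#' @param env A [sim_envelope()].
#' @param reference `"mean_of_simulations"` (default) or `"theoretical"`
#'   (`pi r^2`; only for `khat` under `csr`).
#' @param alternative `"two_sided"` or `"greater"`.
#' @param rmin,rmax Optional integration sub-interval.
#' @return List of class `dclf_test`: `u`, `pseudo_p`, `u_sim`, `alternative`,
#'   `reference`, `n_sim`.
#' @export
dclf_test <- function(env, reference = c("mean_of_simulations", "theoretical"),
                      alternative = c("two_sided", "greater"),
                      rmin = NULL, rmax = NULL) {
  stopifnot(inherits(env, "sim_envelope"))
  reference <- match.arg(reference)
  alternative <- match.arg(alternative)
  if (is.null(env$simulations) || nrow(env$simulations) == 0)
    stop_invalid("envelope has no stored simulations")
  r <- env$r
  keep <- rep(TRUE, length(r))
  if (!is.null(rmin)) keep <- keep & r >= rmin
  if (!is.null(rmax)) keep <- keep & r <= rmax
  dr <- attr(r, "spacing")
  obs <- env$observed[keep]
  sims <- env$simulations[, keep, drop = FALSE]
  m <- nrow(sims)
  dev_u <- function(delta) {
    if (alternative == "greater") delta <- pmax(delta, 0)
    sum(delta^2) * dr
  }
  if (reference == "theoretical") {
    if (!(env$statistic == "khat" && env$null == "csr"))
      stop_invalid("theoretical reference is only defined for khat under csr")
    ref <- pi * r[keep]^2
    u_obs <- dev_u(obs - ref)
    u_sim <- apply(sims, 1, function(s) dev_u(s - ref))
  } else {
    colsum <- colSums(sims)
    u_obs <- dev_u(obs - colsum / m)
    u_sim <- vapply(seq_len(m), function(i)
      dev_u(sims[i, ] - (colsum - sims[i, ]) / (m - 1)), numeric(1))
  }
  structure(list(u = u_obs, pseudo_p = pseudo_p(u_obs, u_sim, "greater"),
                 u_sim = u_sim, alternative = alternative,
                 reference = reference, n_sim = m),
            class = "dclf_test")
}

#' @export
print.dclf_test <- function(x, ...) {
  cat(sprintf("DCLF test (%s, ref = %s): u = %.6g, pseudo-p = %.4g (%d simulations)\n",
              x$alternative, x$reference, x$u, x$pseudo_p, x$n_sim))
  invisible(x)
}

#' Export envelope curves as CSV
#'
#' @param env A [sim_envelope()].
#' @param path CSV destination (`r,observed,lo,hi`).
#' @return The data frame invisibly.
#' @export
write_envelope <- function(env, path) {
  df <- data.frame(r = as.numeric(env$r), observed = env$observed,
                   lo = env$lo, hi = env$hi)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
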