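#' Synthetic geography and case-pattern generator
#'
#' Builds artificial study regions with the statistical structure the analysis
#' pipeline assumes: a Voronoi tessellation of districts nested in contiguous
#' zones, log-normally dispersed populations summing exactly to a stated total,
#' and sex-marked case point patterns allocated either proportionally to
#' population or by a Thomas-style cluster process. Defaults emulate a
#' regional health-service geography: 312 districts in 10 zones, 3.16 million
#' people and 511 cases with a 46.7% male share.
#'
#' @param n_districts,n_zones Number of districts and of zones (zones <=
#'   districts).
#' @param total_population Total population allocated over districts.
#' @param population_dispersion Sigma of the log-normal district weights; 0
#'   gives equal populations.
#' @param n_cases Number of case points.
#' @param male_fraction Probability that a case is male.
#' @param clustering `"proportional"` or `"clustered"`.
#' @param parent_intensity Expected number of cluster parents (clustered mode).
#' @param cluster_sd Isotropic Gaussian displacement of offspring around their
#'   parent, meters (clustered mode).
#' @param seed Integer seed driving all generator randomness.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_districts = 312L, n_zones = 10L,
                             total_population = 3163546L,
                             population_dispersion = 1,
                             n_cases = 511L, male_fraction = 0.467,
                             clustering = c("proportional", "clustered"),
                             parent_intensity = 15, cluster_sd = 4000,
                             seed = 1L) {
  clustering <- match.arg(clustering)
  stopifnot(n_districts >= 1, n_zones >= 1, n_zones <= n_districts,
            total_population >= 0, population_dispersion >= 0, n_cases >= 0,
            male_fraction >= 0, male_fraction <= 1,
            parent_intensity > 0, cluster_sd > 0)
  structure(list(n_districts = as.integer(n_districts),
                 n_zones = as.integer(n_zones),
                 total_population = as.integer(total_population),
                 population_dispersion = population_dispersion,
                 n_cases = as.integer(n_cases),
                 male_fraction = male_fraction,
                 clustering = clustering,
                 parent_intensity = parent_intensity,
                 cluster_sd = cluster_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a district tessellation
#'
#' Districts are the Voronoi cells of uniformly random generator points,
#' clipped to the window; they partition the window exactly. Multi-component
#' windows (islands) are tessellated per component, with generator points
#' allocated to components proportionally to area, so no district spans water.
#'
#' @param window A [study_window()] whose components are convex.
#' @param n_districts Number of districts (>= 1).
#' @param seed Integer seed.
#' @return A [unit_layer()] at district level with ids `D001`, `D002`, ...
#' @export
generate_districts <- function(window, n_districts, seed = 1L) {
  stopifnot(inherits(window, "study_window"))
  if (n_districts < 1) stop_invalid("n_districts must be >= 1")
  n_districts <- as.integer(n_districts)
  ncomp <- length(window$polys)
  areas <- vapply(window$polys, ring_area, numeric(1))
  geoms <- with_seed(seed, {
    per <- if (ncomp == 1) n_districts else {
      p <- largest_remainder(n_districts, areas)
      # every component keeps at least one district when possible
      while (any(p == 0) && any(p > 1)) {
        p[which.max(p)] <- p[which.max(p)] - 1L
        p[which(p == 0)[1]] <- 1L
      }
      p
    }
    out <- list()
    for (ci in seq_len(ncomp)) {
      if (per[ci] == 0) next
      ring <- window$polys[[ci]]
      sites <- runif_in_poly(per[ci], list(ring))
      cells <- voronoi_cells(sites, ring)
      out <- c(out, lapply(cells, list))
    }
    out
  })
  ids <- sprintf("D%03d", seq_along(geoms))
  unit_layer(ids, geoms, level = "district")
}

#' Group districts into contiguous zones
#'
#' Zones are formed by k-means on district centroids (k = `n_zones`); any zone
#' that is not contiguous on the district adjacency graph is repaired by
#' reassigning stranded districts to the adjacent zone with the nearest zone
#' centroid. Zone geometry is the multipolygon of member districts; population
#' and case counts are sums over members.
#'
#' @param districts District [unit_layer()].
#' @param n_zones Number of zones (1..n_districts).
#' @param seed Integer seed for k-means starts.
#' @return A list with `districts` (with `parent_id` filled) and `zones`
#'   (a zone-level [unit_layer()] with ids `Z01`, ...).
#' @export
assign_zones <- function(districts, n_zones, seed = 1L) {
  n <- length(districts)
  if (n_zones > n) stop_invalid("n_zones (%d) exceeds n_districts (%d)", n_zones, n)
  if (n_zones < 1) stop_invalid("n_zones must be >= 1")
  n_zones <- as.integer(n_zones)
  ctr <- layer_centroids(districts)
  memb <- if (n_zones == n) seq_len(n) else with_seed(seed, {
    km <- stats::kmeans(ctr, centers = n_zones, nstart = 5, iter.max = 100)
    km$cluster
  })
  if (n_zones < n) {
    nb <- queen_neighbor_indices(districts$geoms)
    memb <- repair_contiguity(memb, nb, ctr)
  }
  zid <- sprintf("Z%02d", seq_len(n_zones))
  districts$parent_id <- zid[memb]
  zgeoms <- lapply(seq_len(n_zones), function(z)
    unlist(districts$geoms[memb == z], recursive = FALSE))
  zones <- unit_layer(zid, zgeoms,
                      population = vapply(seq_len(n_zones), function(z)
                        sum(districts$population[memb == z]), numeric(1)),
                      cases = vapply(seq_len(n_zones), function(z)
                        sum(districts$cases[memb == z]), numeric(1)),
                      level = "zone")
  list(districts = districts, zones = zones)
}

# Reassign districts stranded outside their zone's main component to the
# neighboring zone with nearest member-centroid mean. Bounded iteration.
repair_contiguity <- function(memb, nb, ctr) {
  for (pass in 1:50) {
    moved <- FALSE
    for (z in sort(unique(memb))) {
      idx <- which(memb == z)
      if (length(idx) <= 1) next
      comp <- graph_components_subset(nb, idx)
      if (max(comp) == 1) next
      sizes <- tabulate(comp)
      main <- which.max(sizes)
      for (s in idx[comp != main]) {
        nbr_zones <- setdiff(unique(memb[nb[[s]]]), z)
        if (length(nbr_zones) == 0) next  # island with no other-zone neighbor
        zc <- vapply(nbr_zones, function(w)
          sum((colMeans(ctr[memb == w, , drop = FALSE]) - ctr[s, ])^2), numeric(1))
        memb[s] <- nbr_zones[which.min(zc)]
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  memb
}

# Connected components of the subgraph induced by `idx` (BFS).
graph_components_subset <- function(nb, idx) {
  pos <- match(seq_along(nb), idx)
  comp <- rep(0L, length(idx))
  cur <- 0L
  for (s in seq_along(idx)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in nb[[idx[v]]]) {
        pw <- pos[w]
        if (!is.na(pw) && comp[pw] == 0L) { comp[pw] <- cur; queue <- c(queue, pw) }
      }
    }
  }
  comp
}

#' Allocate a population total over districts
#'
#' District weights are log-normal, `exp(rnorm(n, 0, dispersion))`, normalized
#' and converted to integers by largest-remainder rounding, so the allocation
#' sums to `total_population` exactly. `dispersion = 0` gives the equal-weights
#' limit (all districts within one person of `total/n`).
#'
#' @param districts District [unit_layer()].
#' @param total_population Non-negative integer.
#' @param dispersion Non-negative sigma of the log-normal weights.
#' @param seed Integer seed.
#' @return The layer with `population` filled.
#' @export
allocate_population <- function(districts, total_population, dispersion = 1,
                                seed = 1L) {
  if (total_population < 0) stop_invalid("total_population must be >= 0")
  if (dispersion < 0) stop_invalid("dispersion must be >= 0")
  n <- length(districts)
  w <- with_seed(seed, exp(stats::rnorm(n, 0, dispersion)))
  districts$population <- largest_remainder(as.integer(total_population), w)
  districts
}

#' Simulate a sex-marked case point pattern
#'
#' Under `proportional` allocation each case's district is drawn with
#' probability proportional to district population and its location uniformly
#' within that district. Under `clustered`, Poisson-many cluster parents are
#' placed uniformly in the window, each case picks a parent (probability
#' weighted by the population of the district containing the parent) and is
#' displaced by an isotropic Gaussian with sd `cluster_sd`, resampled until it
#' falls inside the window. Each case is labeled `M` with probability
#' `male_fraction`, else `F`.
#'
#' @param districts District [unit_layer()] with populations allocated.
#' @param cfg A [synthetic_config()].
#' @param window Optional [study_window()]; defaults to the union of district
#'   polygons.
#' @return A [pp_pattern()] with marks `M`/`F`.
#' @export
simulate_cases <- function(districts, cfg, window = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (is.null(window)) window <- layer_window(districts)
  n <- cfg$n_cases
  if (n == 0)
    return(pp_pattern(numeric(0), numeric(0), marks = character(0), window = window))
  if (sum(districts$population) == 0)
    stop_invalid("cannot place %d cases: all district populations are zero", n)
  with_seed(cfg$seed, {
    if (cfg$clustering == "proportional") {
      di <- sample.int(length(districts), n, replace = TRUE,
                       prob = districts$population)
      xy <- matrix(NA_real_, n, 2)
      for (d in unique(di)) {
        sel <- di == d
        xy[sel, ] <- runif_in_poly(sum(sel), districts$geoms[[d]])
      }
    } else {
      n_par <- max(1L, stats::rpois(1, cfg$parent_intensity))
      par_xy <- runif_in_poly(n_par, window$polys)
      # weight parents by the population of the district they fall in
      pw <- rep(1, n_par)
      for (d in seq_along(districts$geoms)) {
        inside <- points_in_poly(par_xy[, 1], par_xy[, 2], districts$geoms[[d]])
        pw[inside] <- districts$population[d] + 1
      }
      pid <- sample.int(n_par, n, replace = TRUE, prob = pw)
      xy <- matrix(NA_real_, n, 2)
      todo <- seq_len(n)
      while (length(todo)) {
        m <- length(todo)
        cand <- par_xy[pid[todo], , drop = FALSE] +
          matrix(stats::rnorm(2 * m, 0, cfg$cluster_sd), m, 2)
        ok <- window_contains(window, cand[, 1], cand[, 2])
        xy[todo[ok], ] <- cand[ok, , drop = FALSE]
        todo <- todo[!ok]
      }
    }
    sex <- ifelse(stats::runif(n) < cfg$male_fraction, "M", "F")
    pp_pattern(xy[, 1], xy[, 2], marks = sex, window = window,
               id = sprintf("C%04d", seq_len(n)))
  })
}

#' Carve a window into island and mainland components
#'
#' Splits a rectangular window by deleting a vertical sea strip, producing a
#' two-component window that exercises the ferry-link augmentation path of the
#' weights module.
#'
#' @param window A single-component rectangular [study_window()].
#' @param at Fraction of the width at which the strip starts (default 0.72).
#' @param strip_frac Width of the deleted strip as a fraction (default 0.05).
#' @return A two-component [study_window()].
#' @export
split_window <- function(window, at = 0.72, strip_frac = 0.05) {
  stopifnot(inherits(window, "study_window"), length(window$polys) == 1)
  bb <- window_bbox(window)
  w <- bb["xmax"] - bb["xmin"]
  x1 <- bb["xmin"] + at * w
  x2 <- x1 + strip_frac * w
  stopifnot(x2 < bb["xmax"])
  study_window(list(
    cbind(c(bb["xmin"], x1, x1, bb["xmin"]),
          c(bb["ymin"], bb["ymin"], bb["ymax"], bb["ymax"])),
    cbind(c(x2, bb["xmax"], bb["xmax"], x2),
          c(bb["ymin"], bb["ymin"], bb["ymax"], bb["ymax"]))))
}

#' Propose ferry links joining disconnected components
#'
#' Finds the district components of a layer (queen contiguity) and links each
#' secondary component to the main one through the pair of districts with the
#' closest centroids, mimicking island-to-mainland ferry routes.
#'
#' @param districts District [unit_layer()].
#' @param n_links Links per secondary component (default 1).
#' @return Data frame `unit_id_a,unit_id_b,kind` (possibly 0 rows).
#' @export
ferry_links <- function(districts, n_links = 1L) {
  nb <- queen_neighbor_indices(districts$geoms)
  comp <- graph_components_subset(nb, seq_along(nb))
  out <- data.frame(unit_id_a = character(0), unit_id_b = character(0),
                    kind = character(0), stringsAsFactors = FALSE)
  if (max(comp) == 1) return(out)
  ctr <- layer_centroids(districts)
  main <- which.max(tabulate(comp))
  for (cc in setdiff(seq_len(max(comp)), main)) {
    a <- which(comp == cc); b <- which(comp == main)
    d <- outer(seq_along(a), seq_along(b), function(i, j)
      sqrt((ctr[a[i], 1] - ctr[b[j], 1])^2 + (ctr[a[i], 2] - ctr[b[j], 2])^2))
    ord <- order(d)[seq_len(min(n_links, length(d)))]
    for (k in ord) {
      ij <- arrayInd(k, dim(d))
      out <- rbind(out, data.frame(unit_id_a = districts$unit_id[a[ij[1]]],
                                   unit_id_b = districts$unit_id[b[ij[2]]],
                                   kind = "ferry", stringsAsFactors = FALSE))
    }
  }
  out
}

#' Generate a complete synthetic region
#'
#' Convenience wrapper chaining [generate_districts()],
#' [allocate_population()], [assign_zones()] and [simulate_cases()], optionally
#' with an island-carved window and ferry links.
#'
#' @param cfg A [synthetic_config()].
#' @param window Optional [study_window()]; default is a 300 km square.
#' @param islands Carve the window into two components and emit ferry links?
#' @return List with `window`, `districts`, `zones`, `cases` (a
#'   [pp_pattern()]) and `links` (data frame, possibly empty).
#' @export
generate_region <- function(cfg = synthetic_config(), window = NULL,
                            islands = FALSE) {
  if (is.null(window)) window <- rect_window(0, 300e3, 0, 300e3)
  if (islands) window <- split_window(window)
  d <- generate_districts(window, cfg$n_districts, seed = cfg$seed)
  d <- allocate_population(d, cfg$total_population, cfg$population_dispersion,
                           seed = derive_seed(cfg$seed, "population"))
  cases <- simulate_cases(d, cfg, window = window)
  d <- count_points_in_units(cases, d)
  az <- assign_zones(d, cfg$n_zones, seed = derive_seed(cfg$seed, "zones"))
  links <- if (islands) ferry_links(az$districts) else
    data.frame(unit_id_a = character(0), unit_id_b = character(0),
               kind = character(0), stringsAsFactors = FALSE)
  list(window = window, districts = az$districts, zones = az$zones,
       cases = cases, links = links)
}
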