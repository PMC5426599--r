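# Low-level planar geometry.
#
# All coordinates are planar meters (UTM-like). Polygons are numeric matrices
# with columns x, y; rings are implicitly closed (last vertex != first).
# A "multipolygon" is a list of such rings, all exterior (holes unsupported).

# Signed area (shoelace); positive for counter-clockwise rings.
ring_signed_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

ring_area <- function(ring) abs(ring_signed_area(ring))

poly_area <- function(geom) sum(vapply(geom, ring_area, numeric(1)))

# Area centroid of a ring (standard shoelace centroid).
ring_centroid <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

# Area-weighted centroid of a multipolygon.
poly_centroid <- function(geom) {
  a <- vapply(geom, ring_area, numeric(1))
  ctr <- vapply(geom, ring_centroid, numeric(2))
  if (sum(a) <= 0) return(rowMeans(ctr))
  as.numeric(ctr %*% (a / sum(a)))
}

poly_bbox <- function(geom) {
  xs <- unlist(lapply(geom, function(r) r[, 1]), use.names = FALSE)
  ys <- unlist(lapply(geom, function(r) r[, 2]), use.names = FALSE)
  c(xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys))
}

# Ray-casting point-in-ring test returning "in", "out" or "boundary".
# Vectorized over points; `tol` is the absolute boundary tolerance in meters.
points_in_ring <- function(px, py, ring, tol = 1e-9) {
  n <- length(px)
  x <- ring[, 1]; y <- ring[, 2]
  m <- length(x)
  xj <- c(x[m], x[-m]); yj <- c(y[m], y[-m])  # previous vertex
  inside <- logical(n)
  boundary <- logical(n)
  for (e in seq_len(m)) {
    x1 <- xj[e]; y1 <- yj[e]; x2 <- x[e]; y2 <- y[e]
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      t <- ((px - x1) * dx + (py - y1) * dy) / len2
      t <- pmin(1, pmax(0, t))
      d2 <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
      boundary <- boundary | d2 <= tol * tol
    } else {
      boundary <- boundary | ((px - x1)^2 + (py - y1)^2 <= tol * tol)
    }
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- x1 + (py - y1) * dx / dy
      flip <- crosses & (px < xint)
      inside <- xor(inside, flip)
    }
  }
  out <- ifelse(boundary, "boundary", ifelse(inside, "in", "out"))
  out
}

# TRUE when the point is inside or on the boundary of any ring of `geom`.
points_in_poly <- function(px, py, geom, tol = 1e-9) {
  res <- rep(FALSE, length(px))
  bb <- poly_bbox(geom)
  cand <- px >= bb["xmin"] - tol & px <= bb["xmax"] + tol &
    py >= bb["ymin"] - tol & py <= bb["ymax"] + tol
  if (!any(cand)) return(res)
  for (ring in geom) {
    st <- points_in_ring(px[cand], py[cand], ring, tol = tol)
    res[cand] <- res[cand] | st != "out"
    if (all(res[cand])) break
  }
  res
}

# Strictly-on-boundary test for the counting tie-break.
points_on_poly_boundary <- function(px, py, geom, tol = 1e-9) {
  res <- rep(FALSE, length(px))
  for (ring in geom) {
    st <- points_in_ring(px, py, ring, tol = tol)
    res <- res | st == "boundary"
  }
  res
}

# Clip a convex ring by the half-plane {p : (p - m) . d <= 0}
# (Sutherland-Hodgman against a single line). Returns NULL when empty.
clip_halfplane <- function(ring, m, d) {
  f <- (ring[, 1] - m[1]) * d[1] + (ring[, 2] - m[2]) * d[2]
  n <- nrow(ring)
  keep <- f <= 0
  if (all(keep)) return(ring)
  if (!any(keep)) return(NULL)
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (keep[i]) out <- rbind(out, ring[i, ])
    if (keep[i] != keep[j]) {
      t <- f[i] / (f[i] - f[j])
      out <- rbind(out, ring[i, ] + t * (ring[j, ] - ring[i, ]))
    }
  }
  if (nrow(out) < 3) return(NULL)
  out
}

# Voronoi cells of `sites` (n x 2) clipped to a convex ring. Each cell is the
# intersection of the window with the bisector half-planes against the other
# sites; sites are visited nearest-first with an early exit once no remaining
# site can cut the cell.
voronoi_cells <- function(sites, window_ring) {
  n <- nrow(sites)
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    cell <- window_ring
    if (n > 1) {
      d2 <- (sites[, 1] - sites[i, 1])^2 + (sites[, 2] - sites[i, 2])^2
      ord <- order(d2)
      ord <- ord[ord != i]
      for (j in ord) {
        maxr2 <- max((cell[, 1] - sites[i, 1])^2 + (cell[, 2] - sites[i, 2])^2)
        if (d2[j] / 4 > maxr2) break
        m <- (sites[i, ] + sites[j, ]) / 2
        dvec <- sites[j, ] - sites[i, ]
        cell <- clip_halfplane(cell, m, dvec)
        if (is.null(cell)) break
      }
    }
    if (is.null(cell)) stop_invalid("degenerate Voronoi cell for site %d (duplicate sites?)", i)
    cells[[i]] <- cell
  }
  cells
}

# Minimum distance between two segments p1-p2 and q1-q2 (each length-2).
seg_seg_dist <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1; d2 <- q2 - q1; r <- p1 - q1
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  if (a <= 0 && e <= 0) return(sqrt(sum(r * r)))
  if (a <= 0) {
    t <- min(1, max(0, f / e))
    dd <- p1 - (q1 + t * d2); return(sqrt(sum(dd * dd)))
  }
  cc <- sum(d1 * r)
  if (e <= 0) {
    s <- min(1, max(0, -cc / a))
    dd <- (p1 + s * d1) - q1; return(sqrt(sum(dd * dd)))
  }
  b <- sum(d1 * d2)
  den <- a * e - b * b
  s <- if (den > 0) min(1, max(0, (b * f - cc * e) / den)) else 0
  t <- (b * s + f) / e
  if (t < 0) { t <- 0; s <- min(1, max(0, -cc / a)) }
  else if (t > 1) { t <- 1; s <- min(1, max(0, (b - cc) / a)) }
  dd <- (p1 + s * d1) - (q1 + t * d2)
  sqrt(sum(dd * dd))
}

geom_segments <- function(geom) {
  do.call(rbind, lapply(geom, function(ring) {
    n <- nrow(ring)
    cbind(ring, ring[c(2:n, 1), , drop = FALSE])
  }))
}

# Minimum boundary-to-boundary distance between two multipolygons, with an
# early exit once any pair of segments comes within `stop_below`.
poly_boundary_dist <- function(ga, gb, stop_below = 0) {
  sa <- geom_segments(ga); sb <- geom_segments(gb)
  best <- Inf
  for (i in seq_len(nrow(sa))) {
    p1 <- sa[i, 1:2]; p2 <- sa[i, 3:4]
    for (j in seq_len(nrow(sb))) {
      d <- seg_seg_dist(p1, p2, sb[j, 1:2], sb[j, 3:4])
      if (d < best) {
        best <- d
        if (best <= stop_below) return(best)
      }
    }
  }
  best
}

# Distance from a single point to the boundary of a multipolygon.
point_poly_dist <- function(pt, geom) {
  segs <- geom_segments(geom)
  min(vapply(seq_len(nrow(segs)), function(j)
    seg_seg_dist(pt, pt, segs[j, 1:2], segs[j, 3:4]), numeric(1)))
}

# Uniform random points inside a multipolygon by bbox rejection.
runif_in_poly <- function(n, geom) {
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  bb <- poly_bbox(geom)
  out <- matrix(NA_real_, n, 2)
  got <- 0L
  while (got < n) {
    m <- max(2L * (n - got), 32L)
    px <- runif(m, bb["xmin"], bb["xmax"])
    py <- runif(m, bb["ymin"], bb["ymax"])
    ok <- points_in_poly(px, py, geom)
    take <- min(sum(ok), n - got)
    if (take > 0) {
      idx <- which(ok)[seq_len(take)]
      out[got + seq_len(take), ] <- cbind(px[idx], py[idx])
      got <- got + take
    }
  }
  colnames(out) <- c("x", "y")
  out
}
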