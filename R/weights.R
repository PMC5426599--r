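#' Spatial weights objects
#'
#' Neighbor structure over the units of a layer: per-unit neighbor index lists
#' with numeric weights, a `style` flag (`"B"` binary, `"W"` row-standardized)
#' and the total weight `S0 = sum_ij w_ij`. Units with no neighbors (isolates)
#' are kept in the object, flagged in `$islands`, and excluded from Moran
#' computations with a warning.
#'
#' @param ids Character unit ids (ordered).
#' @param nb List of integer neighbor index vectors.
#' @param wts List of numeric weight vectors (same shapes as `nb`).
#' @param style `"B"` or `"W"`.
#' @return Object of class `spatial_weights`.
#' @export
spatial_weights <- function(ids, nb, wts = NULL, style = "B") {
  n <- length(ids)
  stopifnot(length(nb) == n)
  if (is.null(wts)) wts <- lapply(nb, function(x) rep(1, length(x)))
  for (i in seq_len(n)) {
    if (any(nb[[i]] == i)) stop_invalid("self-neighbor at unit %s", ids[i])
    if (length(nb[[i]]) != length(wts[[i]]))
      stop_invalid("neighbor/weight length mismatch at unit %s", ids[i])
  }
  structure(list(ids = as.character(ids), nb = nb, wts = wts, style = style,
                 S0 = sum(unlist(wts, use.names = FALSE), 0),
                 islands = ids[vapply(nb, length, integer(1)) == 0]),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  k <- vapply(x$nb, length, integer(1))
  cat(sprintf("spatial_weights: %d units, %d links, style %s, S0 = %.4g, %d component(s)%s\n",
              length(x$ids), sum(k), x$style, x$S0, n_components(x),
              if (length(x$islands)) sprintf(", %d isolate(s)", length(x$islands)) else ""))
  invisible(x)
}

# internal: queen neighbor index lists for a list of multipolygons.
# Two units are neighbors iff their boundaries come within `snap` meters
# (shared edge or single shared vertex alike). Bounding boxes prefilter pairs.
queen_neighbor_indices <- function(geoms, snap = 1e-3) {
  n <- length(geoms)
  bb <- t(vapply(geoms, poly_bbox, numeric(4)))
  nb <- vector("list", n)
  for (i in seq_len(n)) nb[[i]] <- integer(0)
  if (n < 2) return(nb)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (bb[i, 1] > bb[j, 2] + snap || bb[j, 1] > bb[i, 2] + snap ||
          bb[i, 3] > bb[j, 4] + snap || bb[j, 3] > bb[i, 4] + snap) next
      if (poly_boundary_dist(geoms[[i]], geoms[[j]], stop_below = snap) <= snap) {
        nb[[i]] <- c(nb[[i]], j)
        nb[[j]] <- c(nb[[j]], i)
      }
    }
  }
  lapply(nb, sort)
}

#' First-order queen contiguity weights
#'
#' Units are neighbors iff their polygons share at least one boundary point —
#' a shared edge or a single shared vertex (corner contact counts). Contact is
#' detected by boundary distance with tolerance `snap`, which absorbs the
#' floating-point jitter of independently computed tessellation edges.
#'
#' @param layer A [unit_layer()].
#' @param snap Contact tolerance in meters (default 1e-3).
#' @return Binary symmetric [spatial_weights()]; isolates flagged.
#' @export
queen_contiguity <- function(layer, snap = 1e-3) {
  stopifnot(inherits(layer, "unit_layer"))
  nb <- queen_neighbor_indices(layer$geoms, snap = snap)
  spatial_weights(layer$unit_id, nb)
}

#' Add explicit links (ferry connections) to a weights object
#'
#' Each edge is added symmetrically with weight 1 before row standardization.
#' Duplicate edges and edges already implied by contiguity leave the object
#' unchanged (idempotent).
#'
#' @param W Binary [spatial_weights()].
#' @param edges Data frame with columns `unit_id_a`, `unit_id_b` (extra
#'   columns ignored), or a 2-column character matrix.
#' @return The augmented [spatial_weights()].
#' @export
augment_links <- function(W, edges) {
  stopifnot(inherits(W, "spatial_weights"))
  if (W$style != "B") stop_invalid("augment links before row standardization")
  if (is.matrix(edges)) edges <- data.frame(unit_id_a = edges[, 1],
                                            unit_id_b = edges[, 2])
  nb <- W$nb
  for (k in seq_len(nrow(edges))) {
    a <- match(edges$unit_id_a[k], W$ids)
    b <- match(edges$unit_id_b[k], W$ids)
    if (is.na(a) || is.na(b))
      stop_invalid("link %s-%s references unknown unit id",
                   edges$unit_id_a[k], edges$unit_id_b[k])
    if (a == b) next
    if (!(b %in% nb[[a]])) nb[[a]] <- sort(c(nb[[a]], b))
    if (!(a %in% nb[[b]])) nb[[b]] <- sort(c(nb[[b]], a))
  }
  spatial_weights(W$ids, nb)
}

#' k-nearest-neighbor weights
#'
#' Each unit's neighbors are the `k` units with nearest centroids (Euclidean);
#' the matrix is generally asymmetric. Distance ties are broken toward the
#' smallest `unit_id` for determinism.
#'
#' @param layer A [unit_layer()].
#' @param k Number of neighbors (1 <= k < number of units).
#' @return Binary [spatial_weights()] with exactly `k` neighbors per unit.
#' @export
knn_weights <- function(layer, k = 4L) {
  stopifnot(inherits(layer, "unit_layer"))
  n <- length(layer)
  if (k >= n) stop_invalid("k (%d) must be < number of units (%d)", k, n)
  if (k < 1) stop_invalid("k must be >= 1")
  ctr <- layer_centroids(layer)
  idrank <- rank(layer$unit_id, ties.method = "first")
  nb <- vector("list", n)
  for (i in seq_len(n)) {
    d <- sqrt((ctr[, 1] - ctr[i, 1])^2 + (ctr[, 2] - ctr[i, 2])^2)
    d[i] <- Inf
    # round to 10 significant digits so geometrically equal distances tie
    # exactly despite centroid floating-point jitter
    ord <- order(signif(d, 10), idrank)  # ties -> smallest unit_id
    nb[[i]] <- sort(ord[seq_len(k)])
  }
  spatial_weights(layer$unit_id, nb)
}

#' Lift child contiguity to a parent level
#'
#' Two parent units are queen neighbors iff any pair of their member children
#' are neighbors (or the members touch across the parent boundary), which for
#' dissolved-union geometries is equivalent to computing queen contiguity on
#' the dissolved polygons but much cheaper.
#'
#' @param child_W Queen [spatial_weights()] on the child layer.
#' @param parent_id Parent id per child (same order as `child_W$ids`).
#' @param parent_ids Ordering of parent units for the result; default sorted
#'   unique `parent_id`.
#' @return Binary [spatial_weights()] on the parents.
#' @export
lift_contiguity <- function(child_W, parent_id, parent_ids = NULL) {
  stopifnot(inherits(child_W, "spatial_weights"),
            length(parent_id) == length(child_W$ids))
  if (is.null(parent_ids)) parent_ids <- sort(unique(parent_id))
  pidx <- match(parent_id, parent_ids)
  np <- length(parent_ids)
  nb <- lapply(seq_len(np), function(z) integer(0))
  tr <- weights_triplet(child_W)
  pa <- pidx[tr$i]; pb <- pidx[tr$j]
  keep <- pa != pb
  for (k in which(keep)) {
    a <- pa[k]; b <- pb[k]
    if (!(b %in% nb[[a]])) nb[[a]] <- c(nb[[a]], b)
    if (!(a %in% nb[[b]])) nb[[b]] <- c(nb[[b]], a)
  }
  spatial_weights(parent_ids, lapply(nb, sort))
}

#' Row-standardize a weights object
#'
#' Scales each non-isolate row to sum to 1; isolate rows stay empty and are
#' reported in `$islands`. For binary input the recomputed `S0` equals the
#' number of non-isolate units. Idempotent.
#'
#' @param W A [spatial_weights()].
#' @return Row-standardized [spatial_weights()] (style `"W"`).
#' @export
row_standardize <- function(W) {
  stopifnot(inherits(W, "spatial_weights"))
  wts <- lapply(W$wts, function(w) if (length(w)) w / sum(w) else w)
  out <- spatial_weights(W$ids, W$nb, wts, style = "W")
  out
}

#' Number of connected components of the neighbor graph
#'
#' Treats the graph as undirected (a kNN link counts either way). Ferry
#' augmentation joining islands to the mainland reduces this count.
#'
#' @param W A [spatial_weights()].
#' @return Integer component count (isolates count as singleton components).
#' @export
n_components <- function(W) {
  n <- length(W$ids)
  und <- W$nb
  for (i in seq_len(n)) for (j in W$nb[[i]])
    if (!(i %in% und[[j]])) und[[j]] <- c(und[[j]], i)
  max(graph_components_subset(und, seq_len(n)))
}

# triplet (i, j, w) representation over a subset of non-isolated units,
# used by the Moran statistics
weights_triplet <- function(W) {
  i <- rep(seq_along(W$nb), vapply(W$nb, length, integer(1)))
  list(i = i, j = unlist(W$nb, use.names = FALSE),
       w = unlist(W$wts, use.names = FALSE))
}

#' Serialize weights as sparse edge list
#'
#' Writes `<base>.csv` (`i,j,w` with unit ids) and `<base>.json` (ordering,
#' style, S0, isolates); [read_weights()] restores the object.
#'
#' @param W A [spatial_weights()].
#' @param base Path without extension.
#' @return `base`, invisibly.
#' @export
write_weights <- function(W, base) {
  tr <- weights_triplet(W)
  utils::write.csv(data.frame(i = W$ids[tr$i], j = W$ids[tr$j], w = tr$w),
                   paste0(base, ".csv"), row.names = FALSE, quote = FALSE)
  hdr <- list(ids = W$ids, style = W$style, S0 = W$S0, islands = W$islands)
  writeLines(jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA),
             paste0(base, ".json"))
  invisible(base)
}

#' @rdname write_weights
#' @export
read_weights <- function(base) {
  hdr <- jsonlite::fromJSON(paste0(base, ".json"))
  df <- utils::read.csv(paste0(base, ".csv"), stringsAsFactors = FALSE)
  ids <- as.character(hdr$ids)
  nb <- lapply(ids, function(id) integer(0))
  wts <- lapply(ids, function(id) numeric(0))
  ii <- match(df$i, ids); jj <- match(df$j, ids)
  for (k in seq_len(nrow(df))) {
    nb[[ii[k]]] <- c(nb[[ii[k]]], jj[k])
    wts[[ii[k]]] <- c(wts[[ii[k]]], df$w[k])
  }
  ord <- lapply(nb, order)
  spatial_weights(ids, mapply(function(x, o) x[o], nb, ord, SIMPLIFY = FALSE),
                  mapply(function(x, o) x[o], wts, ord, SIMPLIFY = FALSE),
                  style = hdr$style)
}
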