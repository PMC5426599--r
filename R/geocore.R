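#' Count case points within spatial units
#'
#' The point-in-polygon spatial join: sets each unit's `cases` to the number of
#' pattern points falling inside its polygon. A point lying exactly on a shared
#' boundary is counted once, in the unit with the lexicographically smallest
#' `unit_id` among the units whose boundary it touches — a deterministic,
#' order-independent tie-break.
#'
#' @param pattern A [pp_pattern()].
#' @param layer A [unit_layer()] whose polygons cover the pattern.
#' @param tol Boundary tolerance in meters (default 1e-9).
#' @return The layer with `cases` filled.
#' @export
count_points_in_units <- function(pattern, layer, tol = 1e-9) {
  stopifnot(inherits(pattern, "pp_pattern"), inherits(layer, "unit_layer"))
  if (length(layer) == 0) stop_invalid("empty layer")
  n <- length(pattern$x)
  assigned <- rep(NA_character_, n)
  # visit units in lexicographic id order: first hit wins, which realizes the
  # smallest-id boundary tie-break without collecting all containers
  for (i in order(layer$unit_id)) {
    if (!any(is.na(assigned))) break
    todo <- which(is.na(assigned))
    inside <- points_in_poly(pattern$x[todo], pattern$y[todo],
                             layer$geoms[[i]], tol = tol)
    assigned[todo[inside]] <- layer$unit_id[i]
  }
  cnt <- table(factor(assigned, levels = layer$unit_id))
  layer$cases <- as.integer(cnt)
  layer
}

#' Assign each child unit a parent by centroid containment
#'
#' The centroid-based spatial join used to push zone-level values down to
#' districts: each child's area centroid is located within the parent polygons;
#' the child receives the parent's `unit_id` as `parent_id` and, optionally,
#' a copy of one parent attribute.
#'
#' @param child,parent [unit_layer()] objects.
#' @param field Name of a parent column to copy onto the child (for example
#'   `"pp"`), or `NULL` to assign ids only.
#' @param fallback_nearest When a centroid falls in no parent polygon, assign
#'   the parent with the nearest boundary (default `TRUE`); with `FALSE` such
#'   children raise an error listing their ids.
#' @return The child layer with `parent_id` (and, when `field` is given, an
#'   attribute column `parent_<field>` attached as `x$parent_field`).
#' @export
assign_parent_by_centroid <- function(child, parent, field = NULL,
                                      fallback_nearest = TRUE) {
  stopifnot(inherits(child, "unit_layer"), inherits(parent, "unit_layer"))
  ctr <- layer_centroids(child)
  pid <- rep(NA_character_, length(child))
  for (j in order(parent$unit_id)) {
    todo <- which(is.na(pid))
    if (!length(todo)) break
    inside <- points_in_poly(ctr[todo, 1], ctr[todo, 2], parent$geoms[[j]])
    pid[todo[inside]] <- parent$unit_id[j]
  }
  if (anyNA(pid)) {
    miss <- which(is.na(pid))
    if (!fallback_nearest)
      stop_invalid("child centroid(s) outside all parents: %s",
                   paste(child$unit_id[miss], collapse = ", "))
    for (i in miss) {
      d <- vapply(parent$geoms, function(g) point_poly_dist(ctr[i, ], g),
                  numeric(1))
      pid[i] <- parent$unit_id[which.min(d)]
    }
  }
  child$parent_id <- pid
  if (!is.null(field)) {
    vals <- parent[[field]]
    if (is.null(vals)) stop_invalid("parent layer has no field '%s'", field)
    child$parent_field <- vals[match(pid, parent$unit_id)]
    attr(child$parent_field, "field") <- field
  }
  child
}
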