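#' Spatial unit layers
#'
#' A `unit_layer` holds the polygon units of one aggregation level (districts,
#' zones, or random zones) together with their attributes: unique `unit_id`,
#' population, case count, period prevalence (`pp`, cases per 10,000) and an
#' optional `parent_id` linking each unit to a coarser level.
#'
#' Geometries are multipolygons: a list (one element per unit) of lists of
#' rings, each ring an n x 2 matrix of planar-meter coordinates. Holes are not
#' supported.
#'
#' @param unit_id Character vector of unique ids.
#' @param geoms List of multipolygons (one per unit).
#' @param population Integer vector (default 0).
#' @param cases Integer vector (default 0).
#' @param pp Numeric vector of period prevalences, or `NA` when not computed.
#' @param parent_id Character vector of parent unit ids, or `NA`.
#' @param level One of `"district"`, `"zone"`, `"random_zone"`.
#' @return An object of class `unit_layer`.
#' @export
unit_layer <- function(unit_id, geoms, population = 0L, cases = 0L,
                       pp = NA_real_, parent_id = NA_character_,
                       level = c("district", "zone", "random_zone")) {
  level <- match.arg(level)
  unit_id <- as.character(unit_id)
  n <- length(unit_id)
  if (anyDuplicated(unit_id))
    stop_invalid("duplicate unit_id: %s",
                 paste(unique(unit_id[duplicated(unit_id)]), collapse = ", "))
  stopifnot(is.list(geoms), length(geoms) == n)
  geoms <- lapply(geoms, function(g) if (is.matrix(g)) list(g) else g)
  population <- rep_len(as.integer(population), n)
  cases <- rep_len(as.integer(cases), n)
  pp <- rep_len(as.numeric(pp), n)
  parent_id <- rep_len(as.character(parent_id), n)
  if (any(population < 0, na.rm = TRUE)) stop_invalid("population must be >= 0")
  if (any(cases < 0, na.rm = TRUE)) stop_invalid("cases must be >= 0")
  if (any(pp < 0, na.rm = TRUE)) stop_invalid("pp must be >= 0 when set")
  structure(list(unit_id = unit_id, geoms = geoms, population = population,
                 cases = cases, pp = pp, parent_id = parent_id, level = level),
            class = "unit_layer")
}

#' @export
print.unit_layer <- function(x, ...) {
  cat(sprintf("unit_layer: %d %s units, population %s, cases %d\n",
              length(x$unit_id), x$level,
              format(sum(x$population), big.mark = ","), sum(x$cases)))
  invisible(x)
}

#' @export
length.unit_layer <- function(x) length(x$unit_id)

#' @export
as.data.frame.unit_layer <- function(x, ...) {
  data.frame(unit_id = x$unit_id, level = x$level, parent_id = x$parent_id,
             population = x$population, cases = x$cases, pp = x$pp,
             stringsAsFactors = FALSE)
}

layer_centroids <- function(layer) {
  t(vapply(layer$geoms, poly_centroid, numeric(2)))
}

layer_areas <- function(layer) {
  vapply(layer$geoms, poly_area, numeric(1))
}

# The union of a layer's polygons as a study_window (components = all rings).
layer_window <- function(layer) {
  study_window(unlist(layer$geoms, recursive = FALSE))
}

## ---- GeoJSON i/o -----------------------------------------------------------

geojson_precision <- 6  # decimal digits on write: 1e-6 m reproducibility

ring_to_coords <- function(ring) {
  ring <- round(ring, geojson_precision)
  ring <- rbind(ring, ring[1, , drop = FALSE])  # GeoJSON rings are closed
  lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
}

#' Read and write unit layers as GeoJSON
#'
#' Layers are stored as a `FeatureCollection` of `Polygon`/`MultiPolygon`
#' features with properties `unit_id`, `parent_id`, `population`, `cases`,
#' `pp` and `level`. Coordinates are written at fixed 1e-6 m precision so a
#' write-read-write round trip is byte-identical.
#'
#' @param path File path.
#' @param layer A [unit_layer()].
#' @return `read_layer` returns a [unit_layer()]; `write_layer` returns
#'   `path` invisibly.
#' @export
read_layer <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stop_invalid("%s: not a GeoJSON FeatureCollection", path)
  feats <- gj$features
  n <- length(feats)
  if (n == 0) stop_invalid("%s: empty FeatureCollection", path)
  ids <- character(n); pop <- integer(n); cas <- integer(n)
  pp <- numeric(n); par <- character(n); geoms <- vector("list", n)
  for (i in seq_len(n)) {
    f <- feats[[i]]
    pr <- f$properties
    if (is.null(pr$unit_id))
      stop_invalid("%s: feature %d is missing property 'unit_id'", path, i)
    if (is.null(pr$population))
      stop_invalid("%s: feature %d is missing property 'population'", path, i)
    ids[i] <- as.character(pr$unit_id)
    pop[i] <- as.integer(pr$population)
    cas[i] <- as.integer(pr$cases %||% 0L)
    pp[i] <- as.numeric(pr$pp %||% NA_real_)
    par[i] <- as.character(pr$parent_id %||% NA_character_)
    g <- f$geometry
    rings <- switch(g$type,
      Polygon = list(g$coordinates[[1]]),
      MultiPolygon = lapply(g$coordinates, function(p) p[[1]]),
      stop_invalid("%s: feature %d has unsupported geometry '%s'", path, i, g$type)
    )
    geoms[[i]] <- lapply(rings, function(r) {
      m <- do.call(rbind, lapply(r, function(pt) c(pt[[1]], pt[[2]])))
      m[-nrow(m), , drop = FALSE]  # drop closing vertex
    })
  }
  level <- gj$level %||% (feats[[1]]$properties$level %||% "district")
  unit_layer(ids, geoms, pop, cas, pp, par, level = level)
}

#' @rdname read_layer
#' @export
write_layer <- function(layer, path) {
  stopifnot(inherits(layer, "unit_layer"))
  feats <- lapply(seq_along(layer$unit_id), function(i) {
    g <- layer$geoms[[i]]
    geometry <- if (length(g) == 1) {
      list(type = "Polygon", coordinates = list(ring_to_coords(g[[1]])))
    } else {
      list(type = "MultiPolygon",
           coordinates = lapply(g, function(r) list(ring_to_coords(r))))
    }
    props <- list(unit_id = layer$unit_id[i],
                  population = layer$population[i],
                  cases = layer$cases[i],
                  level = layer$level)
    props$pp <- if (is.na(layer$pp[i])) NULL else layer$pp[i]
    props$parent_id <- if (is.na(layer$parent_id[i])) NULL else layer$parent_id[i]
    list(type = "Feature", properties = props, geometry = geometry)
  })
  obj <- list(type = "FeatureCollection", level = layer$level, features = feats)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(json, path)
  invisible(path)
}

## ---- case table and edge-list i/o -----------------------------------------

#' Read and write case point tables
#'
#' Cases are CSV files with columns `case_id,x,y,sex` (sex in M/F; meters).
#'
#' @param path CSV path.
#' @param window Optional [study_window()]; when given, points are validated
#'   against it and the returned pattern carries it.
#' @return `read_cases` returns a [pp_pattern()].
#' @export
read_cases <- function(path, window = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "x", "y", "sex")
  if (!all(need %in% names(df)))
    stop_invalid("%s: case table needs columns %s", path, paste(need, collapse = ","))
  if (is.null(window)) {
    pad <- 1
    window <- rect_window(min(df$x) - pad, max(df$x) + pad,
                          min(df$y) - pad, max(df$y) + pad)
  }
  pp_pattern(df$x, df$y, marks = df$sex, window = window, id = df$case_id)
}

#' @rdname read_cases
#' @param pattern A [pp_pattern()].
#' @export
write_cases <- function(pattern, path) {
  df <- data.frame(case_id = pattern$id %||% seq_along(pattern$x),
                   x = pattern$x, y = pattern$y,
                   sex = pattern$marks %||% NA_character_)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a link edge list (for example ferry connections)
#'
#' @param path CSV with columns `unit_id_a,unit_id_b,kind`.
#' @return Data frame with character columns `unit_id_a`, `unit_id_b`, `kind`.
#' @export
read_links <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("unit_id_a", "unit_id_b")
  if (!all(need %in% names(df)))
    stop_invalid("%s: link table needs columns %s", path, paste(need, collapse = ","))
  if (is.null(df$kind)) df$kind <- "ferry"
  df[] <- lapply(df, as.character)
  df
}
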