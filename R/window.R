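#' Observation windows
#'
#' A study window is one or more disjoint convex polygons in planar meters
#' (UTM-like coordinates). Multi-component windows emulate island/mainland
#' geographies.
#'
#' @param polys A single ring (numeric matrix, columns x and y, vertices not
#'   repeated) or a list of such rings.
#' @return An object of class `study_window` with elements `polys` (list of
#'   rings) and `area` (square meters).
#' @examples
#' w <- rect_window(0, 100e3, 0, 100e3)
#' w$area
#' @export
study_window <- function(polys) {
  if (is.matrix(polys)) polys <- list(polys)
  stopifnot(is.list(polys), length(polys) >= 1)
  for (p in polys) {
    if (!is.matrix(p) || ncol(p) != 2 || nrow(p) < 3)
      stop_invalid("window rings must be n x 2 matrices with n >= 3")
  }
  area <- sum(vapply(polys, ring_area, numeric(1)))
  if (area <= 0) stop_invalid("window area must be positive")
  structure(list(polys = polys, area = area), class = "study_window")
}

#' @rdname study_window
#' @param xmin,xmax,ymin,ymax Rectangle bounds in meters.
#' @export
rect_window <- function(xmin = 0, xmax = 100e3, ymin = 0, ymax = 100e3) {
  stopifnot(xmax > xmin, ymax > ymin)
  study_window(cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax)))
}

#' @export
print.study_window <- function(x, ...) {
  bb <- poly_bbox(x$polys)
  cat(sprintf("study window: %d component(s), area %.4g km^2, bbox [%.0f, %.0f] x [%.0f, %.0f] m\n",
              length(x$polys), x$area / 1e6, bb[1], bb[2], bb[3], bb[4]))
  invisible(x)
}

window_contains <- function(window, x, y, tol = 1e-6) {
  points_in_poly(x, y, window$polys, tol = tol)
}

window_bbox <- function(window) poly_bbox(window$polys)

# Diameter of the bounding box; upper bound for K-function distances.
window_diameter <- function(window) {
  bb <- window_bbox(window)
  sqrt((bb["xmax"] - bb["xmin"])^2 + (bb["ymax"] - bb["ymin"])^2)
}
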