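#' Period prevalence per 10,000
#'
#' Cases accumulated over the study period divided by the unit population,
#' scaled to cases per 10,000 persons. Reported tables round half-up to two
#' decimals ([pp_round()]); full precision is kept internally so downstream
#' statistics accumulate no rounding error.
#'
#' @param cases Non-negative integer vector.
#' @param population Positive integer vector.
#' @return Numeric vector, cases per 10,000.
#' @examples
#' pp_round(period_prevalence(81, 373670))  # 2.17
#' @export
period_prevalence <- function(cases, population) {
  if (any(population <= 0))
    stop_invalid("undefined prevalence: population <= 0 (cases=%s)",
                 paste(cases[population <= 0], collapse = ","))
  if (any(cases < 0)) stop_invalid("cases must be >= 0")
  10000 * cases / population
}

#' @rdname period_prevalence
#' @param x Numeric vector of prevalences.
#' @param digits Decimals for reporting (default 2).
#' @export
pp_round <- function(x, digits = 2) round_half_up(x, digits)

#' Compute period prevalence for every unit of a layer
#'
#' Sets `pp = 10000 * cases / population` for units with positive population.
#' Zero-population units get `pp = NA` and are reported with a warning; they
#' are excluded from autocorrelation analyses downstream rather than assigned
#' zero (0/0 is undefined).
#'
#' @param layer A [unit_layer()] with `cases` and `population` set.
#' @return The layer with `pp` filled.
#' @export
layer_prevalence <- function(layer) {
  stopifnot(inherits(layer, "unit_layer"))
  ok <- layer$population > 0
  layer$pp <- rep(NA_real_, length(layer))
  layer$pp[ok] <- period_prevalence(layer$cases[ok], layer$population[ok])
  if (any(!ok))
    warning(sprintf("%d unit(s) with zero population excluded from prevalence: %s",
                    sum(!ok), paste(layer$unit_id[!ok], collapse = ", ")),
            call. = FALSE)
  layer
}

#' Aggregate a child layer into parent units by pooled counts
#'
#' Parent prevalence is always computed from pooled counts,
#' `10000 * sum(cases) / sum(population)`, never by averaging child rates.
#'
#' @param child A [unit_layer()] with `parent_id` set.
#' @param level Level label for the output layer.
#' @return A parent-level [unit_layer()] (geometry = member multipolygons).
#' @export
aggregate_by_parent <- function(child, level = c("zone", "random_zone")) {
  level <- match.arg(level)
  if (anyNA(child$parent_id)) stop_invalid("child layer has unassigned parent_id")
  pids <- sort(unique(child$parent_id))
  geoms <- lapply(pids, function(p)
    unlist(child$geoms[child$parent_id == p], recursive = FALSE))
  out <- unit_layer(pids, geoms,
                    population = vapply(pids, function(p)
                      sum(child$population[child$parent_id == p]), numeric(1)),
                    cases = vapply(pids, function(p)
                      sum(child$cases[child$parent_id == p]), numeric(1)),
                    level = level)
  layer_prevalence(out)
}

#' Export a prevalence table
#'
#' @param layer A [unit_layer()] with pp computed.
#' @param path Optional CSV path; when given the table is written there.
#' @param digits Reporting decimals (half-up).
#' @return Data frame `unit_id,level,cases,population,pp` (pp rounded).
#' @export
prevalence_table <- function(layer, path = NULL, digits = 2) {
  df <- data.frame(unit_id = layer$unit_id, level = layer$level,
                   cases = layer$cases, population = layer$population,
                   pp = pp_round(layer$pp, digits), stringsAsFactors = FALSE)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  df
}
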