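#' One random Voronoi zonation of a district layer
#'
#' The zonation procedure of the MAUP sensitivity experiment: sample `n_zones`
#' district centroids without replacement, form the Voronoi tessellation of
#' those generators (clipped to the layer's bounding window), assign every
#' district to the Voronoi cell containing its centroid, dissolve, pool cases
#' and population, and compute prevalence from the pooled counts. Assignment
#' uses the defining property of a Voronoi cell — nearest generator — with
#' centroid ties broken toward the smaller generator `unit_id`. Each generator
#' district lies in its own cell, so all `n_zones` random zones are non-empty.
#'
#' @param districts District [unit_layer()] with `cases`/`population` set.
#' @param n_zones Number of random zones (default 10).
#' @param seed Integer seed.
#' @return List of class `zonation`: `generators` (district ids), `assignment`
#'   (named character vector district -> random zone), `layer` (the
#'   random-zone [unit_layer()] with pooled counts and pp).
#' @export
random_zonation <- function(districts, n_zones = 10L, seed = 1L) {
  n <- length(districts)
  if (n_zones > n) stop_invalid("n_zones (%d) exceeds n_districts (%d)", n_zones, n)
  ctr <- layer_centroids(districts)
  gen <- with_seed(seed, sample.int(n, n_zones))
  gen <- gen[order(districts$unit_id[gen])]  # cell ids in id order
  d2 <- vapply(gen, function(g) (ctr[, 1] - ctr[g, 1])^2 + (ctr[, 2] - ctr[g, 2])^2,
               numeric(n))
  d2 <- matrix(d2, nrow = n)
  zone_of <- max.col(-d2, ties.method = "first")  # nearest; tie -> smaller id
  zid <- districts$unit_id[gen]
  tmp <- districts
  tmp$parent_id <- zid[zone_of]
  layer <- suppressWarnings(aggregate_by_parent(tmp, level = "random_zone"))
  structure(list(generators = zid,
                 assignment = stats::setNames(zid[zone_of], districts$unit_id),
                 layer = layer, seed = seed),
            class = "zonation")
}

#' MAUP sensitivity experiment by random zonation
#'
#' Repeats [random_zonation()] `n_replicates` times; for each replicate and
#' each spatial-dependence scheme, global Moran's I of the random-zone
#' prevalence is tested with `n_perm` permutations (one-sided, greater). The
#' summary reports, per scheme, the fraction of zonations significant at
#' `alpha`, plus the union fraction ("significant using either definition").
#' Replicates with degenerate prevalence (zero variance) are retained, counted
#' as non-significant and flagged.
#'
#' @param districts District [unit_layer()] (counts and populations set).
#' @param n_zones Zones per replicate (default 10).
#' @param n_replicates Number of random zonations (default 200).
#' @param schemes Character subset of `c("queen", "knn4")`.
#' @param n_perm Permutations per Moran test (default 999).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed; replicate r uses sub-seed `seed + r`.
#' @param k Neighbors for the kNN scheme (default 4).
#' @param district_W Optional precomputed queen [spatial_weights()] on the
#'   districts (computed once otherwise).
#' @return Object of class `maup_summary`: `results` (per replicate x scheme
#'   data frame with `replicate,scheme,I,pseudo_p,significant,degenerate`),
#'   `fraction_significant` (per scheme), `fraction_union`, `n_replicates`,
#'   `alpha`, `seed`.
#' @export
maup_experiment <- function(districts, n_zones = 10L, n_replicates = 200L,
                            schemes = c("queen", "knn4"), n_perm = 999,
                            alpha = 0.05, seed = 1L, k = 4L,
                            district_W = NULL) {
  schemes <- match.arg(schemes, c("queen", "knn4"), several.ok = TRUE)
  if ("queen" %in% schemes && is.null(district_W))
    district_W <- queen_contiguity(districts)
  rows <- list()
  for (r in seq_len(n_replicates)) {
    zn <- random_zonation(districts, n_zones, seed = seed + r)
    lay <- zn$layer
    ok <- !is.na(lay$pp)
    for (sch in schemes) {
      Wz <- if (sch == "queen") {
        lift_contiguity(district_W, zn$assignment, parent_ids = lay$unit_id)
      } else {
        knn_weights(lay, k = min(k, length(lay$unit_id) - 1L))
      }
      non_iso <- sum(vapply(Wz$nb, length, integer(1)) > 0)
      degenerate <- sum(ok) < 3 || isTRUE(stats::var(lay$pp[ok]) == 0) ||
        anyNA(lay$pp) || non_iso < 3
      if (degenerate) {
        rows[[length(rows) + 1]] <- data.frame(
          replicate = r, scheme = sch, I = NA_real_, pseudo_p = 1,
          significant = FALSE, degenerate = TRUE, stringsAsFactors = FALSE)
        next
      }
      mt <- tryCatch(
        suppressWarnings(global_moran(lay$pp, row_standardize(Wz),
                                      n_perm = n_perm,
                                      seed = derive_seed(seed + r, sch),
                                      alternative = "greater")),
        error = function(e) NULL)
      rows[[length(rows) + 1]] <- if (is.null(mt)) {
        data.frame(replicate = r, scheme = sch, I = NA_real_, pseudo_p = 1,
                   significant = FALSE, degenerate = TRUE,
                   stringsAsFactors = FALSE)
      } else {
        data.frame(replicate = r, scheme = sch, I = mt$I,
                   pseudo_p = mt$pseudo_p,
                   significant = mt$pseudo_p <= alpha, degenerate = FALSE,
                   stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  frac <- vapply(schemes, function(s) mean(res$significant[res$scheme == s]),
                 numeric(1))
  union_sig <- tapply(res$significant, res$replicate, any)
  structure(list(results = res,
                 fraction_significant = stats::setNames(frac, schemes),
                 fraction_union = mean(union_sig),
                 n_replicates = as.integer(n_replicates),
                 n_perm = as.integer(n_perm), alpha = alpha, seed = seed),
            class = "maup_summary")
}

#' @export
print.maup_summary <- function(x, ...) {
  cat(sprintf("MAUP random-zonation experiment: %d replicates, alpha = %g\n",
              x$n_replicates, x$alpha))
  for (s in names(x$fraction_significant))
    cat(sprintf("  %-6s fraction significant: %.3f\n", s,
                x$fraction_significant[[s]]))
  cat(sprintf("  union  fraction significant: %.3f\n", x$fraction_union))
  invisible(x)
}
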