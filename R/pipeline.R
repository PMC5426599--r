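#' Run configuration
#'
#' Builds and validates the configuration driving [run_pipeline()]. Defaults
#' mirror the analysis conventions: 199 envelope simulations, 999 global and
#' 9999 local permutations, 200 random zonations, alpha 0.05, k = 4, r grid
#' 0-80 km in 160 m steps.
#'
#' @param cases,districts,zones,links Input paths (links optional, `NULL` if
#'   none).
#' @param out_dir Output directory (created if missing).
#' @param rmax,rstep Distance grid parameters, meters.
#' @param n_sim Envelope simulations.
#' @param n_perm_global,n_perm_local Permutation counts.
#' @param n_zonations MAUP replicates.
#' @param alpha Significance level in (0, 1).
#' @param schemes Weights schemes, subset of `c("queen", "knn4")`.
#' @param k kNN neighbor count.
#' @param seed Master seed; every stage derives a named sub-seed from it.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(cases, districts, zones = NULL, links = NULL,
                       out_dir = "geoprev_out", rmax = 80000, rstep = 160,
                       n_sim = 199, n_perm_global = 999, n_perm_local = 9999,
                       n_zonations = 200, alpha = 0.05,
                       schemes = c("queen", "knn4"), k = 4, seed = 1L) {
  cfg <- list(cases = cases, districts = districts, zones = zones,
              links = links, out_dir = out_dir, rmax = rmax, rstep = rstep,
              n_sim = n_sim, n_perm_global = n_perm_global,
              n_perm_local = n_perm_local, n_zonations = n_zonations,
              alpha = alpha, schemes = schemes, k = k, seed = seed)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  for (f in c("n_sim", "n_perm_global", "n_perm_local", "n_zonations", "k",
              "rmax", "rstep"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      stop_invalid("config field '%s' must be a positive number", f)
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1)
    stop_invalid("config field 'alpha' must be in (0, 1)")
  cfg$schemes <- match.arg(cfg$schemes, c("queen", "knn4"), several.ok = TRUE)
  for (f in c("cases", "districts"))
    if (is.null(cfg[[f]])) stop_invalid("config field '%s' is required", f)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from JSON (or YAML)
#'
#' JSON is the native format; `.yaml`/`.yml` files are parsed when the `yaml`
#' package is available. Relative input paths are resolved against the config
#' file's directory.
#'
#' @param path Config file path.
#' @return A validated `run_config`.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_invalid("YAML config requires the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  base <- dirname(normalizePath(path))
  for (f in c("cases", "districts", "zones", "links"))
    if (!is.null(cfg[[f]]) && !grepl("^/", cfg[[f]]))
      cfg[[f]] <- file.path(base, cfg[[f]])
  defaults <- formals(run_config)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]]) && !nm %in% c("cases", "districts"))
      cfg[[nm]] <- eval(defaults[[nm]])
  validate_config(cfg[names(cfg) %in% names(defaults)])
}

stage_log <- function(stage, seed, t0, ...) {
  msg <- paste(sprintf("%s=%s", names(list(...)), unlist(list(...))),
               collapse = " ")
  message(sprintf("[geoprev] stage=%s seed=%s elapsed=%.2fs %s",
                  stage, seed %||% "NA",
                  as.numeric(proc.time()[3] - t0), msg))
}

#' Run the full multi-scale analysis pipeline
#'
#' Executes, in order: sex-dependency point-pattern tests (Cross-L one-sided
#' and Difference-K two-sided DCLF), period prevalence at district and zone
#' level, spatial weights construction (queen + ferry links, kNN), global
#' Moran's I per level and scheme, local Moran cluster classification at both
#' levels, bivariate district-zone local Moran, the q-statistic for stratified
#' heterogeneity, and the MAUP random-zonation experiment. Per-stage artifacts
#' are written under `out_dir/<stage>/` and a consolidated report to
#' `report.json` and `report.md`. All randomness derives from the single
#' config seed through named sub-seeds, so identical configs give identical
#' reports.
#'
#' The MAUP stage is cached: its parameter hash is stored beside its output
#' and the stage is skipped when inputs and parameters are unchanged.
#'
#' @param config A [run_config()] or path to a config file.
#' @return The report as a list (class `geoprev_report`), invisibly writes
#'   artifacts.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  config <- validate_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = config[setdiff(names(config), "out_dir")])
  r <- rgrid(config$rmax, config$rstep)

  # ---- load ----
  t0 <- proc.time()[3]
  districts <- read_layer(config$districts)
  window <- layer_window(districts)
  cases <- read_cases(config$cases, window = window)
  links <- if (!is.null(config$links)) read_links(config$links) else NULL
  stage_log("load", NA, t0, districts = length(districts),
            cases = length(cases$x))

  # ---- sex dependency ----
  t0 <- proc.time()[3]
  dir.create(file.path(out, "sexdep"), showWarnings = FALSE)
  s_cl <- derive_seed(config$seed, "sexdep_crossl")
  env_cl <- sim_envelope(cases, "cross_l", "csr",
                         n_sim = config$n_sim, seed = s_cl, r = r)
  dclf_cl <- dclf_test(env_cl, alternative = "greater")
  s_dk <- derive_seed(config$seed, "sexdep_diffk")
  env_dk <- sim_envelope(cases, "difference_k", "random_labeling",
                         n_sim = config$n_sim, seed = s_dk, r = r)
  dclf_dk <- dclf_test(env_dk, alternative = "two_sided")
  write_envelope(env_cl, file.path(out, "sexdep", "cross_l.csv"))
  write_envelope(env_dk, file.path(out, "sexdep", "difference_k.csv"))
  report$sex_dependency <- list(
    n_male = sum(cases$marks == "M"), n_female = sum(cases$marks == "F"),
    cross_l = list(u = dclf_cl$u, pseudo_p = dclf_cl$pseudo_p,
                   alternative = "greater", n_sim = config$n_sim),
    difference_k = list(u = dclf_dk$u, pseudo_p = dclf_dk$pseudo_p,
                        alternative = "two_sided", n_sim = config$n_sim))
  stage_log("sexdep", s_cl, t0, p_crossl = dclf_cl$pseudo_p,
            p_diffk = dclf_dk$pseudo_p)

  # ---- prevalence ----
  t0 <- proc.time()[3]
  dir.create(file.path(out, "prevalence"), showWarnings = FALSE)
  districts <- count_points_in_units(cases, districts)
  districts <- suppressWarnings(layer_prevalence(districts))
  zones <- if (!is.null(config$zones)) {
    z <- read_layer(config$zones)
    if (anyNA(districts$parent_id))
      districts <- assign_parent_by_centroid(districts, z)
    zz <- suppressWarnings(aggregate_by_parent(districts, "zone"))
    # keep the read layer's geometry/order, counts from pooled districts
    idx <- match(z$unit_id, zz$unit_id)
    z$population <- zz$population[idx]; z$cases <- zz$cases[idx]
    suppressWarnings(layer_prevalence(z))
  } else {
    suppressWarnings(aggregate_by_parent(districts, "zone"))
  }
  pt_d <- prevalence_table(districts,
                           file.path(out, "prevalence", "districts.csv"))
  pt_z <- prevalence_table(zones, file.path(out, "prevalence", "zones.csv"))
  report$prevalence <- list(districts = pt_d, zones = pt_z)
  stage_log("prevalence", NA, t0, total_cases = sum(districts$cases))

  # ---- weights ----
  t0 <- proc.time()[3]
  dir.create(file.path(out, "weights"), showWarnings = FALSE)
  build_weights <- function(layer, scheme, level) {
    W <- if (scheme == "queen") {
      Wq <- queen_contiguity(layer)
      if (!is.null(links) && nrow(links)) {
        ed <- links
        if (level == "zone") {
          m <- match(ed$unit_id_a, districts$unit_id)
          m2 <- match(ed$unit_id_b, districts$unit_id)
          ed <- data.frame(unit_id_a = districts$parent_id[m],
                           unit_id_b = districts$parent_id[m2])
          ed <- ed[!is.na(ed$unit_id_a) & !is.na(ed$unit_id_b) &
                     ed$unit_id_a != ed$unit_id_b, , drop = FALSE]
        }
        if (nrow(ed)) Wq <- augment_links(Wq, ed)
      }
      Wq
    } else {
      knn_weights(layer, k = min(config$k, length(layer$unit_id) - 1L))
    }
    write_weights(W, file.path(out, "weights", paste0(level, "_", scheme)))
    row_standardize(W)
  }
  Wd <- lapply(stats::setNames(config$schemes, config$schemes),
               function(s) build_weights(districts, s, "district"))
  Wz <- lapply(stats::setNames(config$schemes, config$schemes),
               function(s) build_weights(zones, s, "zone"))
  stage_log("weights", NA, t0, schemes = paste(config$schemes, collapse = ","))

  # ---- global Moran ----
  t0 <- proc.time()[3]
  dir.create(file.path(out, "moran"), showWarnings = FALSE)
  gm <- list()
  for (lev in c("district", "zone")) {
    lay <- if (lev == "district") districts else zones
    Ws <- if (lev == "district") Wd else Wz
    ok <- !is.na(lay$pp)
    for (s in config$schemes) {
      mt <- suppressWarnings(global_moran(
        lay$pp[ok], subset_weights(Ws[[s]], which(ok)),
        n_perm = config$n_perm_global,
        seed = derive_seed(config$seed, paste0("global_", lev, "_", s))))
      gm[[paste(lev, s, sep = "_")]] <-
        list(level = lev, scheme = s, I = mt$I, pseudo_p = mt$pseudo_p,
             n = mt$n, n_perm = mt$n_perm, alternative = mt$alternative)
    }
  }
  report$global_moran <- gm
  stage_log("global_moran", config$seed, t0)

  # ---- local Moran (univariate, queen scheme) ----
  t0 <- proc.time()[3]
  sch1 <- config$schemes[1]
  lm_d <- classify_clusters(suppressWarnings(local_moran(
    districts$pp, Wd[[sch1]], n_perm = config$n_perm_local,
    seed = derive_seed(config$seed, "local_district"))), config$alpha)
  lm_z <- classify_clusters(suppressWarnings(local_moran(
    zones$pp, Wz[[sch1]], n_perm = config$n_perm_local,
    seed = derive_seed(config$seed, "local_zone"))), config$alpha)
  write_local_moran(lm_d, file.path(out, "moran", "local_districts.csv"),
                    layer = districts)
  write_local_moran(lm_z, file.path(out, "moran", "local_zones.csv"),
                    layer = zones)
  report$local_moran <- list(
    district = cluster_counts(lm_d), zone = cluster_counts(lm_z))
  stage_log("local_moran", config$seed, t0,
            flagged_districts = sum(lm_d$significant))

  # ---- bivariate district-zone ----
  t0 <- proc.time()[3]
  districts2 <- assign_parent_by_centroid(districts, zones, field = "pp")
  zone_pp_on_district <- districts2$parent_field
  keep <- !is.na(districts$pp) & !is.na(zone_pp_on_district)
  Wb <- Wd[[sch1]]
  bm <- suppressWarnings(global_moran_bv(
    districts$pp[keep], zone_pp_on_district[keep],
    subset_weights(Wb, which(keep)), n_perm = config$n_perm_global,
    seed = derive_seed(config$seed, "global_bivariate")))
  blm <- classify_clusters(suppressWarnings(bivariate_local_moran(
    districts$pp[keep], zone_pp_on_district[keep],
    subset_weights(Wb, which(keep)), n_perm = config$n_perm_local,
    seed = derive_seed(config$seed, "local_bivariate"))), config$alpha)
  write_local_moran(blm, file.path(out, "moran", "bivariate_districts.csv"),
                    layer = districts)
  report$bivariate_moran <- list(
    global = list(I = bm$I, pseudo_p = bm$pseudo_p, n = bm$n),
    clusters = cluster_counts(blm))
  stage_log("bivariate", config$seed, t0, I = bm$I, p = bm$pseudo_p)

  # ---- q-statistic ----
  t0 <- proc.time()[3]
  dir.create(file.path(out, "qstat"), showWarnings = FALSE)
  qs <- q_significance(districts$pp, districts2$parent_id,
                       n_perm = config$n_perm_global,
                       seed = derive_seed(config$seed, "qstat"))
  writeLines(jsonlite::toJSON(list(q = qs$q, pseudo_p = qs$pseudo_p,
                                   n = qs$n, L = qs$L, n_perm = qs$n_perm),
                              auto_unbox = TRUE, digits = NA),
             file.path(out, "qstat", "qstat.json"))
  report$q_statistic <- list(q = qs$q, pseudo_p = qs$pseudo_p, n = qs$n,
                             L = qs$L)
  stage_log("qstat", config$seed, t0, q = qs$q, p = qs$pseudo_p)

  # ---- MAUP (cached) ----
  t0 <- proc.time()[3]
  dir.create(file.path(out, "maup"), showWarnings = FALSE)
  maup_key <- jsonlite::toJSON(list(n_zonations = config$n_zonations,
                                    n_perm = config$n_perm_global,
                                    alpha = config$alpha,
                                    schemes = config$schemes,
                                    seed = config$seed,
                                    districts = unname(tools::md5sum(config$districts)),
                                    cases = unname(tools::md5sum(config$cases))),
                               auto_unbox = TRUE)
  keyfile <- file.path(out, "maup", "cache_key.json")
  sumfile <- file.path(out, "maup", "summary.json")
  cached <- file.exists(keyfile) && file.exists(sumfile) &&
    identical(readLines(keyfile, warn = FALSE), as.character(maup_key))
  if (cached) {
    maup_sum <- jsonlite::fromJSON(sumfile)
    report$maup <- maup_sum
    stage_log("maup", config$seed, t0, cached = TRUE)
  } else {
    Wd_bin <- queen_contiguity(districts)
    if (!is.null(links) && nrow(links)) Wd_bin <- augment_links(Wd_bin, links)
    mp <- maup_experiment(districts, n_zones = length(zones$unit_id),
                          district_W = Wd_bin,
                          n_replicates = config$n_zonations,
                          schemes = config$schemes,
                          n_perm = config$n_perm_global, alpha = config$alpha,
                          seed = derive_seed(config$seed, "maup"),
                          k = config$k)
    utils::write.csv(mp$results, file.path(out, "maup", "replicates.csv"),
                     row.names = FALSE, quote = FALSE)
    report$maup <- list(
      n_replicates = mp$n_replicates,
      fraction_significant = as.list(mp$fraction_significant),
      fraction_union = mp$fraction_union, alpha = mp$alpha)
    writeLines(jsonlite::toJSON(report$maup, auto_unbox = TRUE, digits = NA),
               sumfile)
    writeLines(as.character(maup_key), keyfile)
    stage_log("maup", config$seed, t0,
              union_frac = mp$fraction_union)
  }

  # ---- report ----
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                              dataframe = "rows", null = "null"),
             file.path(out, "report.json"))
  writeLines(render_report_md(report), file.path(out, "report.md"))
  invisible(structure(report, class = "geoprev_report"))
}

cluster_counts <- function(tab) {
  as.list(table(factor(tab$cluster, levels = c("HH", "LL", "HL", "LH", "NS"))))
}

# restrict a weights object to a unit subset (drops external links)
subset_weights <- function(W, idx) {
  pos <- match(seq_along(W$ids), idx)
  nbm <- lapply(W$nb[idx], function(v) pos[v][!is.na(pos[v])])
  wts <- mapply(function(v, w) w[!is.na(pos[v])], W$nb[idx], W$wts[idx],
                SIMPLIFY = FALSE)
  spatial_weights(W$ids[idx], nbm, wts, style = W$style)
}

render_report_md <- function(rep) {
  fmtp <- function(p) sprintf("%.4g", p)
  c("# geoprev run report",
    "",
    "## Sex dependency",
    sprintf("- Cross-L DCLF (one-sided, attraction): u = %.6g, pseudo-p = %s",
            rep$sex_dependency$cross_l$u, fmtp(rep$sex_dependency$cross_l$pseudo_p)),
    sprintf("- Difference-K DCLF (two-sided): u = %.6g, pseudo-p = %s",
            rep$sex_dependency$difference_k$u,
            fmtp(rep$sex_dependency$difference_k$pseudo_p)),
    "",
    "## Period prevalence (zones)",
    "",
    "| unit_id | cases | population | pp |",
    "|---|---|---|---|",
    sprintf("| %s | %d | %d | %.2f |", rep$prevalence$zones$unit_id,
            rep$prevalence$zones$cases, rep$prevalence$zones$population,
            rep$prevalence$zones$pp),
    "",
    "## Global Moran's I",
    vapply(rep$global_moran, function(g)
      sprintf("- %s / %s: I = %.6g, pseudo-p = %s (n = %d)",
              g$level, g$scheme, g$I, fmtp(g$pseudo_p), g$n), character(1)),
    "",
    "## Bivariate district-zone Moran's I",
    sprintf("- global I = %.6g, pseudo-p = %s",
            rep$bivariate_moran$global$I, fmtp(rep$bivariate_moran$global$pseudo_p)),
    "",
    "## Stratified heterogeneity",
    sprintf("- q = %.4g, pseudo-p = %s (n = %d districts, L = %d zones)",
            rep$q_statistic$q, fmtp(rep$q_statistic$pseudo_p),
            rep$q_statistic$n, rep$q_statistic$L),
    "",
    "## MAUP random zonations",
    sprintf("- replicates: %s", rep$maup$n_replicates),
    vapply(names(rep$maup$fraction_significant), function(s)
      sprintf("- %s fraction significant: %.3f", s,
              rep$maup$fraction_significant[[s]]), character(1)),
    sprintf("- union fraction significant: %.3f", rep$maup$fraction_union))
}

#' Write a packaged synthetic fixture
#'
#' Emits `cases.csv`, `districts.geojson`, `zones.geojson`, `ferries.csv` and
#' `config.json` for a synthetic region. The `full_scale` preset matches the
#' emulation targets (312 districts, 10 zones, 3,163,546 people, 511 cases,
#' male fraction 0.467, island components joined by ferry links); `tiny`
#' (20 districts, 3 zones, 50 cases) runs the full pipeline in seconds for
#' tests.
#'
#' @param out_dir Destination directory (created).
#' @param preset `"full_scale"` or `"tiny"`.
#' @param seed Integer seed.
#' @return Invisible character vector of file paths.
#' @export
make_fixture <- function(out_dir, preset = c("full_scale", "tiny"),
                         seed = 1L) {
  preset <- match.arg(preset)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- if (preset == "full_scale") {
    synthetic_config(seed = seed)
  } else {
    synthetic_config(n_districts = 20L, n_zones = 3L,
                     total_population = 50000L, n_cases = 50L, seed = seed)
  }
  window <- if (preset == "full_scale") rect_window(0, 300e3, 0, 300e3)
            else rect_window(0, 60e3, 0, 60e3)
  reg <- generate_region(cfg, window = window, islands = TRUE)
  paths <- c(cases = file.path(out_dir, "cases.csv"),
             districts = file.path(out_dir, "districts.geojson"),
             zones = file.path(out_dir, "zones.geojson"),
             links = file.path(out_dir, "ferries.csv"),
             config = file.path(out_dir, "config.json"))
  write_cases(reg$cases, paths["cases"])
  write_layer(reg$districts, paths["districts"])
  write_layer(reg$zones, paths["zones"])
  utils::write.csv(reg$links, paths["links"], row.names = FALSE, quote = FALSE)
  run_cfg <- list(cases = "cases.csv", districts = "districts.geojson",
                  zones = "zones.geojson", links = "ferries.csv",
                  out_dir = file.path(out_dir, "out"), seed = seed)
  if (preset == "tiny")
    run_cfg <- c(run_cfg, list(n_sim = 39, n_perm_global = 99,
                               n_perm_local = 99, n_zonations = 5,
                               rmax = 30000, rstep = 600))
  writeLines(jsonlite::toJSON(run_cfg, auto_unbox = TRUE, digits = NA),
             paths["config"])
  invisible(paths)
}
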