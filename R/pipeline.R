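#' Run the full siting tradeoff pipeline on a scenario bundle
#'
#' Stages: distance to shore from the land mask; per-cell wind-farm NPV;
#' cumulative bird sensitivity; low-density masking and aggregate monthly
#' cetacean score; axis normalisation (negative-NPV cells excluded);
#' average utility over the weighting sweep; quadrant classification; site
#' selection and ranking; and the per-site monthly profile with its
#' minimum month.
#'
#' @param bundle a `scenario_bundle` (from [make_scenario()],
#'   [make_known_optimum()] or [read_scenario()]).
#' @param turbine a [turbine_spec()].
#' @param farm a [farm_spec()].
#' @param econ an [econ_params()].
#' @param uparams a [utility_params()].
#' @param n_label maximum number of labelled sites.
#' @return list of class `tradeoff_run` with elements `dist`, `npv`,
#'   `bird`, `cet_mask`, `cet_aggregate`, `W`, `Bsens`, `u_bar`,
#'   `quadrants`, `sites`, and `log` (named list of every parameter and
#'   derived threshold used).
#' @export
run_pipeline <- function(bundle,
                         turbine = turbine_spec(),
                         farm = farm_spec(),
                         econ = econ_params(),
                         uparams = utility_params(),
                         n_label = 26L) {
  stopifnot(inherits(bundle, "scenario_bundle"))
  dist <- distance_grid(bundle$land, bundle$wind$scale)

  npv_grid <- valuation_map(bundle$wind$shape, bundle$wind$scale, dist,
                            turbine, farm, econ,
                            reference_height = bundle$wind$reference_height)

  bird <- bird_pixel_score(bundle$birds$layers, bundle$birds$values)

  cet_mask <- mask_low_density(bundle$cetaceans$stacks)
  cet_agg <- cetacean_score_map(bundle$cetaceans$stacks,
                                bundle$cetaceans$scores, mask = cet_mask)

  axes <- normalize_axes(npv_grid, bird)
  u_bar <- average_utility(axes$W, axes$Bsens, uparams)
  quad <- quadrant_classify(axes$W, axes$Bsens, uparams)
  sites <- select_sites(u_bar, uparams, n_label = n_label)
  sites <- site_report(sites, cet_agg, npv_grid, axes$Bsens)

  qc <- quantile_classify(u_bar, probs = uparams$quantile_major)
  run_log <- list(
    turbine = unclass(turbine), farm = unclass(farm), econ = unclass(econ),
    utility = unclass(uparams),
    n_bird_species = length(bundle$birds$layers),
    bird_values = as.list(bundle$birds$values),
    n_cetacean_units = length(bundle$cetaceans$stacks),
    cetacean_scores = as.list(bundle$cetaceans$scores),
    cells_total = length(u_bar$values),
    cells_excluded_negative_npv = sum(axes$excluded),
    cells_cetacean_masked = sum(!is.finite(cet_mask$values) &
                                  is.finite(bundle$land$values) &
                                  bundle$land$values == 0),
    utility_top_threshold = qc$thresholds$value[1L],
    n_sites = nrow(sites)
  )
  structure(list(dist = dist, npv = npv_grid, bird = bird,
                 cet_mask = cet_mask, cet_aggregate = cet_agg,
                 W = axes$W, Bsens = axes$Bsens, u_bar = u_bar,
                 quadrants = quad, sites = sites, log = run_log),
            class = "tradeoff_run")
}

#' @export
print.tradeoff_run <- function(x, ...) {
  cat("<tradeoff_run>\n")
  cat(sprintf("  %d cells (%d excluded for negative NPV), %d sites\n",
              x$log$cells_total, x$log$cells_excluded_negative_npv,
              x$log$n_sites))
  print(x$sites[, c("label", "lon", "lat", "bird_sensitivity",
                    "wind_profitability", "average_utility", "rank",
                    "best_month")])
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Emits the site table (CSV + GeoJSON points), the average-utility and NPV
#' surfaces (ASCII grids), hotspot region outlines (GeoJSON), and a
#' JSON-lines run log recording every parameter value, mask count and
#' threshold used — including every defaulted parameter, so a run is
#' auditable from its artifacts alone.
#'
#' @param run a `tradeoff_run`.
#' @param dir output directory (created if needed).
#' @return invisibly `dir`.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "tradeoff_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_sites(run$sites, csv_path = file.path(dir, "sites.csv"),
              geojson_path = file.path(dir, "sites.geojson"))
  write_grid(run$u_bar, file.path(dir, "average_utility.asc"))
  write_grid(run$npv, file.path(dir, "npv.asc"))
  write_grid(run$bird, file.path(dir, "bird_sensitivity.asc"))
  qc <- quantile_classify(run$u_bar, probs = 0.2)
  top <- run$u_bar
  top$values <- ifelse(!is.na(qc$categories) & qc$categories == 1L, 1, 0)
  write_regions_geojson(connected_regions(top)$labels,
                        file.path(dir, "hotspot_regions.geojson"))
  con <- file(file.path(dir, "run_log.jsonl"), open = "wt")
  on.exit(close(con))
  for (nm in names(run$log)) {
    writeLines(jsonlite::toJSON(list(key = nm, value = run$log[[nm]]),
                                auto_unbox = TRUE, digits = NA, null = "null"),
               con)
  }
  invisible(dir)
}
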