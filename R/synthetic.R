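#' Synthetic study-scenario configuration
#'
#' Defines a fully in-silico coastal study area with known ground truth:
#' land along the western edge, Weibull wind speeds increasing offshore and
#' northward, seabird densities with a strong north-high latitudinal
#' gradient (log-normal around a deterministic surface, so the log
#' transform of the bird score sees realistic heavy tails), and cetacean
#' monthly stacks in which one migratory high-concern species follows a
#' piecewise-linear coastal path through the year while resident species
#' are constant across months. The migrant passes the mid-coast northbound
#' in March and southbound in November and sits far north in mid-summer, so
#' nearshore/mid-latitude cells show the two-peaked seasonal profile with a
#' mid-summer trough.
#'
#' @param nrow,ncol grid dimensions (row 1 = north).
#' @param cell_km cell size, km.
#' @param seed RNG seed; a fixed seed makes the bundle byte-identical.
#' @param wind list: `shape`, `lambda_base` (m/s at the south-west sea
#'   corner), `grad_offshore` and `grad_north` (m/s per km), `noise_sd`
#'   (additive m/s).
#' @param birds data frame: `species`, `value` (sensitivity 1-5), `d0`
#'   (baseline density), `beta_lat` (log-density change south to north;
#'   positive = north-high), `sdlog` (log-normal noise).
#' @param cetaceans list describing the migrant (`species`, `rank`,
#'   `peak`, `path_frac` of 12 along-coast fractions, `sd_along_km`,
#'   `center_off_km`, `sd_cross_km`, `resident_floor`, `sdlog`) and the
#'   residents (data frame `species`, `rank`, `d0`, `beta_off`, `sdlog`).
#' @param georef lon/lat anchor of the projected origin, for reporting.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(
    nrow = 60, ncol = 40, cell_km = 10, seed = 1,
    wind = list(shape = 2, lambda_base = 6, grad_offshore = 0.005,
                grad_north = 0.002, noise_sd = 0.1),
    birds = data.frame(
      species = c("Great Black-backed Gull", "Herring Gull",
                  "Northern Gannet", "Common Tern", "Long-tailed Duck",
                  "Dovekie"),
      value = c(5, 5, 4, 3, 2, 1),
      d0 = c(4, 5, 3, 2, 2, 1),
      beta_lat = c(2.5, 2.2, 2.0, 1.8, 2.0, 1.5),
      sdlog = 0.5
    ),
    cetaceans = list(
      migrant = list(
        species = "North Atlantic right whale", rank = "G1", peak = 50,
        path_frac = c(0.00, 0.15, 0.30, 0.50, 0.70, 0.85, 0.95,
                      0.85, 0.70, 0.50, 0.30, 0.15),
        sd_along_km = 150, center_off_km = 100, sd_cross_km = 120,
        resident_floor = 1.5, sdlog = 0.1
      ),
      residents = data.frame(
        species = c("Humpback whale", "Sei whale",
                    "Common bottlenose dolphin"),
        rank = c("G4", "G3", "G5"),
        d0 = c(3, 2, 8),
        beta_off = c(0.5, 1.0, -1.5),
        sdlog = 0.3
      )
    ),
    georef = list(lon0 = -76.5, lat0 = 34.0)) {
  stopifnot(nrow >= 4, ncol >= 4, cell_km > 0)
  structure(list(nrow = nrow, ncol = ncol, cell_km = cell_km, seed = seed,
                 wind = wind, birds = birds, cetaceans = cetaceans,
                 georef = georef),
            class = "scenario_config")
}

# fraction of coast length (0 = south) and offshore distance (km) per cell
scenario_geometry <- function(config) {
  nr <- config$nrow; nc <- config$ncol
  latfrac <- matrix(rep((nr - seq_len(nr) + 0.5) / nr, nc), nr, nc)
  # column 1 is land; offshore distance from the land/sea boundary
  off_km <- matrix(rep((seq_len(nc) - 1.5) * config$cell_km, each = nr), nr, nc)
  off_km[, 1L] <- 0
  list(latfrac = latfrac, off_km = off_km, sea = col(latfrac) > 1L)
}

new_scenario_grid <- function(values, config, sea = NULL) {
  if (!is.null(sea)) values[!sea] <- NA_real_
  wind_grid(values, cell_km = config$cell_km, xmin = 0, ymin = 0,
            proj = "synthetic-albers-km", georef = config$georef)
}

#' Generate a full synthetic input bundle
#'
#' @param config a [scenario_config()].
#' @return list of class `scenario_bundle` with elements `land` (1 = land),
#'   `wind` (`shape`, `scale` grids at 10 m reference), `birds` (`layers`,
#'   `values`), `cetaceans` (`stacks`, `scores`), `truth` (including the
#'   migration `trough_month` implied by the path geometry), and `config`.
#' @export
make_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  geo <- scenario_geometry(config)
  nr <- config$nrow; nc <- config$ncol
  coast_km <- nr * config$cell_km

  land <- new_scenario_grid(ifelse(geo$sea, 0, 1), config)

  w <- config$wind
  lambda <- w$lambda_base + w$grad_offshore * geo$off_km +
    w$grad_north * geo$latfrac * coast_km +
    matrix(stats::rnorm(nr * nc, 0, w$noise_sd), nr, nc)
  lambda <- pmax(lambda, 0.5)
  k_grid <- new_scenario_grid(matrix(w$shape, nr, nc), config, geo$sea)
  lambda_grid <- new_scenario_grid(lambda, config, geo$sea)

  layers <- list(); values <- numeric(0)
  for (i in seq_len(nrow(config$birds))) {
    b <- config$birds[i, ]
    mu <- log(b$d0) + b$beta_lat * geo$latfrac
    dens <- exp(mu + matrix(stats::rnorm(nr * nc, 0, b$sdlog), nr, nc))
    layers[[b$species]] <- new_scenario_grid(dens, config, geo$sea)
    values[b$species] <- b$value
  }

  cet <- config$cetaceans
  stacks <- list(); scores <- numeric(0)
  mig <- cet$migrant
  y <- (nr - row(geo$latfrac) + 0.5) * config$cell_km   # northing, km
  xoff <- geo$off_km
  mig_months <- vector("list", 12L)
  for (m in 1:12) {
    yc <- mig$path_frac[m] * coast_km
    plume <- mig$peak *
      exp(-((y - yc) / mig$sd_along_km)^2 / 2) *
      exp(-((xoff - mig$center_off_km) / mig$sd_cross_km)^2 / 2)
    dens <- (plume + mig$resident_floor) *
      exp(matrix(stats::rnorm(nr * nc, 0, mig$sdlog), nr, nc))
    mig_months[[m]] <- new_scenario_grid(dens, config, geo$sea)
  }
  stacks[[mig$species]] <- monthly_stack(mig_months, mig$species)
  scores[mig$species] <- status_score(mig$rank)
  for (i in seq_len(nrow(cet$residents))) {
    r <- cet$residents[i, ]
    field <- r$d0 * exp(r$beta_off * geo$off_km / max(geo$off_km) +
                        matrix(stats::rnorm(nr * nc, 0, r$sdlog), nr, nc))
    g <- new_scenario_grid(field, config, geo$sea)
    stacks[[r$species]] <- monthly_stack(rep(list(g), 12L), r$species)
    scores[r$species] <- status_score(r$rank)
  }

  # ground truth from the generator's own geometry: the trough month at a
  # coastal latitude is the month whose plume centre lies farthest away
  trough_at <- function(latfrac) {
    which.min(exp(-((latfrac - mig$path_frac) * coast_km /
                    mig$sd_along_km)^2 / 2))
  }
  truth <- list(
    coast = "west",
    trough_at = trough_at,
    trough_month_midcoast = trough_at(1 / 3),
    migration_path_frac = mig$path_frac
  )

  structure(list(land = land,
                 wind = list(shape = k_grid, scale = lambda_grid,
                             reference_height = 10),
                 birds = list(layers = layers, values = values),
                 cetaceans = list(stacks = stacks, scores = scores),
                 truth = truth, config = config),
            class = "scenario_bundle")
}

#' Generate the known-optimum scenario
#'
#' Plants one rectangular region with wind scale 15% above the background
#' maximum and bird densities suppressed to 1% of their generated values,
#' so the true utility argmax lies inside the region by construction. The
#' planted cetacean trough month for the region is derived from the
#' migration geometry at the region's latitude.
#'
#' @param config a [scenario_config()].
#' @param region list with integer vectors `rows`, `cols`.
#' @return a `scenario_bundle` whose `truth` carries `region` and
#'   `trough_month`.
#' @export
make_known_optimum <- function(config = scenario_config(),
                               region = list(rows = 36:44, cols = 24:30)) {
  if (any(region$rows < 1 | region$rows > config$nrow) ||
      any(region$cols < 2 | region$cols > config$ncol))
    stop("requested region lies off-grid (or on land)")
  bundle <- make_scenario(config)
  lam <- bundle$wind$scale$values
  boost <- 1.15 * max(lam, na.rm = TRUE)
  lam[region$rows, region$cols] <- boost
  bundle$wind$scale$values <- lam
  for (sp in names(bundle$birds$layers)) {
    v <- bundle$birds$layers[[sp]]$values
    v[region$rows, region$cols] <- v[region$rows, region$cols] * 0.01
    bundle$birds$layers[[sp]]$values <- v
  }
  latfrac <- (config$nrow - mean(region$rows) + 0.5) / config$nrow
  bundle$truth$region <- region
  bundle$truth$trough_month <- bundle$truth$trough_at(latfrac)
  bundle
}

slugify <- function(x) gsub("[^a-z0-9]+", "_", tolower(x))

#' Write a scenario bundle to disk in pipeline input formats
#'
#' Emits ASCII grids plus CSV manifests (the same formats real inputs
#' would use), a YAML scenario descriptor and a YAML ground-truth sidecar,
#' so synthetic and real runs are format-identical.
#'
#' @param bundle a `scenario_bundle`.
#' @param dir output directory (created if needed).
#' @return invisibly `dir`.
#' @export
write_scenario <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "birds"), showWarnings = FALSE)
  dir.create(file.path(dir, "cetaceans"), showWarnings = FALSE)
  write_grid(bundle$land, file.path(dir, "land.asc"))
  write_grid(bundle$wind$shape, file.path(dir, "wind_k.asc"))
  write_grid(bundle$wind$scale, file.path(dir, "wind_lambda.asc"))
  bm <- data.frame(species = names(bundle$birds$layers),
                   value = unname(bundle$birds$values[names(bundle$birds$layers)]),
                   file = file.path("birds",
                                    paste0(slugify(names(bundle$birds$layers)), ".asc")))
  for (i in seq_len(nrow(bm)))
    write_grid(bundle$birds$layers[[bm$species[i]]], file.path(dir, bm$file[i]))
  utils::write.csv(bm, file.path(dir, "birds_manifest.csv"), row.names = FALSE)
  cm <- do.call(rbind, lapply(names(bundle$cetaceans$stacks), function(sp) {
    data.frame(species = sp, score = unname(bundle$cetaceans$scores[sp]),
               month = 1:12,
               file = file.path("cetaceans",
                                sprintf("%s_m%02d.asc", slugify(sp), 1:12)))
  }))
  for (i in seq_len(nrow(cm)))
    write_grid(bundle$cetaceans$stacks[[cm$species[i]]]$months[[cm$month[i]]],
               file.path(dir, cm$file[i]))
  utils::write.csv(cm, file.path(dir, "cetaceans_manifest.csv"),
                   row.names = FALSE)
  cfg <- bundle$config
  cfg$birds <- as.list(as.data.frame(cfg$birds))
  cfg$cetaceans$residents <- as.list(as.data.frame(cfg$cetaceans$residents))
  yaml::write_yaml(unclass(cfg), file.path(dir, "scenario.yml"))
  truth <- bundle$truth
  truth$trough_at <- NULL    # closures are not serialisable
  yaml::write_yaml(truth, file.path(dir, "truth.yml"))
  invisible(dir)
}

#' Read a scenario bundle written by [write_scenario()]
#'
#' @param dir scenario directory.
#' @return a `scenario_bundle` (without the generator's truth closure).
#' @export
read_scenario <- function(dir) {
  need <- file.path(dir, c("land.asc", "wind_k.asc", "wind_lambda.asc",
                           "birds_manifest.csv", "cetaceans_manifest.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop("scenario input(s) missing: ", paste(missing, collapse = ", "))
  land <- read_grid(file.path(dir, "land.asc"))
  kg <- read_grid(file.path(dir, "wind_k.asc"))
  lg <- read_grid(file.path(dir, "wind_lambda.asc"))
  bm <- utils::read.csv(file.path(dir, "birds_manifest.csv"),
                        stringsAsFactors = FALSE)
  layers <- list(); values <- numeric(0)
  for (i in seq_len(nrow(bm))) {
    layers[[bm$species[i]]] <- read_grid(file.path(dir, bm$file[i]))
    values[bm$species[i]] <- bm$value[i]
  }
  cm <- utils::read.csv(file.path(dir, "cetaceans_manifest.csv"),
                        stringsAsFactors = FALSE)
  stacks <- list(); scores <- numeric(0)
  for (sp in unique(cm$species)) {
    rows <- cm[cm$species == sp, ]
    rows <- rows[order(rows$month), ]
    grids <- lapply(rows$file, function(f) read_grid(file.path(dir, f)))
    stacks[[sp]] <- monthly_stack(grids, sp)
    scores[sp] <- rows$score[1L]
  }
  truth <- if (file.exists(file.path(dir, "truth.yml")))
    yaml::read_yaml(file.path(dir, "truth.yml")) else NULL
  config <- if (file.exists(file.path(dir, "scenario.yml")))
    yaml::read_yaml(file.path(dir, "scenario.yml")) else NULL
  structure(list(land = land,
                 wind = list(shape = kg, scale = lg, reference_height = 10),
                 birds = list(layers = layers, values = values),
                 cetaceans = list(stacks = stacks, scores = scores),
                 truth = truth, config = config),
            class = "scenario_bundle")
}

#' Draw wind-speed samples at one cell of a scenario
#'
#' Samples from the cell's generating Weibull distribution at reference
#' height; used to close the loop between the generator and
#' [fit_weibull()].
#'
#' @param bundle a `scenario_bundle`.
#' @param row,col cell indices.
#' @param n number of samples.
#' @return numeric vector of speeds, m/s.
#' @export
draw_wind_samples <- function(bundle, row, col, n = 1000L) {
  k <- bundle$wind$shape$values[row, col]
  lam <- bundle$wind$scale$values[row, col]
  if (!is.finite(k) || !is.finite(lam)) stop("cell has no wind resource")
  stats::rweibull(n, shape = k, scale = lam)
}
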