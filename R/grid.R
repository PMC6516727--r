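#' Gridded layer on the analysis grid
#'
#' All analysis layers live on one common equal-area grid of square cells
#' (10 km cells by default, mirroring typical cetacean density products).
#' A `wind_grid` stores a numeric matrix whose first row is the *northern*
#' edge (row-major from the north-west corner), the cell size in km, the
#' projected coordinate of the south-west corner of the grid (km), a free-text
#' projection descriptor, and an optional geographic anchor used only for
#' reporting cell-centre lon/lat.
#'
#' `NA` cells are nodata and are excluded from every statistic.
#'
#' @param values numeric matrix; row 1 = northern row. `NA` marks nodata.
#' @param cell_km cell size in km (square cells).
#' @param xmin,ymin projected coordinates (km) of the south-west grid corner.
#' @param proj projection descriptor (free text, must match across layers).
#' @param georef optional `list(lon0, lat0)` giving the lon/lat of the
#'   projected origin `(x = 0, y = 0)`, used by [cell_lonlat()].
#' @return an object of class `wind_grid`.
#' @export
wind_grid <- function(values, cell_km = 10, xmin = 0, ymin = 0,
                      proj = "albers-equal-area-km", georef = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_km) || length(cell_km) != 1L || cell_km <= 0)
    stop("`cell_km` must be a single positive number")
  structure(
    list(values = values, cell_km = cell_km, xmin = xmin, ymin = ymin,
         proj = proj, georef = georef),
    class = "wind_grid"
  )
}

#' @export
print.wind_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<wind_grid> %d x %d cells of %g km [%s]\n",
              nrow(v), ncol(v), x$cell_km, x$proj))
  ok <- is.finite(v)
  if (any(ok)) {
    cat(sprintf("  valid: %d/%d  range: [%g, %g]\n",
                sum(ok), length(v), min(v[ok]), max(v[ok])))
  } else {
    cat("  all cells nodata\n")
  }
  invisible(x)
}

is_wind_grid <- function(x) inherits(x, "wind_grid")

#' Check that grids share shape, cell size and projection
#'
#' Fails loudly rather than broadcasting: every multi-layer operation in the
#' package calls this first.
#'
#' @param ... `wind_grid` objects.
#' @return invisibly `TRUE`; otherwise an error.
#' @export
check_congruent <- function(...) {
  gs <- list(...)
  gs <- gs[!vapply(gs, is.null, logical(1))]
  if (length(gs) < 2L) return(invisible(TRUE))
  ref <- gs[[1L]]
  for (g in gs[-1L]) {
    if (!is_wind_grid(g)) stop("not a wind_grid")
    if (!identical(dim(g$values), dim(ref$values)))
      stop(sprintf("grid shape mismatch: %dx%d vs %dx%d",
                   nrow(g$values), ncol(g$values),
                   nrow(ref$values), ncol(ref$values)))
    if (!isTRUE(all.equal(g$cell_km, ref$cell_km)))
      stop("grid cell size mismatch")
    if (!identical(g$proj, ref$proj))
      stop("grid projection mismatch")
  }
  invisible(TRUE)
}

# Projected x (east) / y (north) coordinates of cell centres, km.
cell_centers <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  x <- grid$xmin + (seq_len(nc) - 0.5) * grid$cell_km
  y <- grid$ymin + (nr - seq_len(nr) + 0.5) * grid$cell_km  # row 1 = north
  list(x = x, y = y)
}

#' Cell-centre longitude/latitude for reporting
#'
#' Uses the grid's geographic anchor and an equirectangular approximation
#' (adequate for reporting at the 10 km scale of the analysis grid). Falls
#' back to projected km when the grid carries no anchor.
#'
#' @param grid a `wind_grid`.
#' @param row,col cell indices (vectors of equal length).
#' @return a data frame with columns `lon`, `lat`.
#' @export
cell_lonlat <- function(grid, row, col) {
  cc <- cell_centers(grid)
  x <- cc$x[col]; y <- cc$y[row]
  if (is.null(grid$georef)) {
    return(data.frame(lon = x, lat = y))
  }
  km_per_deg <- 111.32
  lat <- grid$georef$lat0 + y / km_per_deg
  lon <- grid$georef$lon0 + x / (km_per_deg * cos(lat * pi / 180))
  data.frame(lon = lon, lat = lat)
}

#' Read a single-band raster from an ESRI ASCII grid file
#'
#' Parses the standard `.asc` header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, optional `NODATA_value`), honours nodata, and
#' reads a projection descriptor from a `.prj` sidecar when present.
#'
#' @param path path to an `.asc` file.
#' @return a [wind_grid()].
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  lines <- readLines(path, n = 6L, warn = FALSE)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    key <- tolower(parts[1L])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                   "cellsize", "nodata_value") && length(parts) == 2L) {
      hdr[[key]] <- as.numeric(parts[2L])
      n_hdr <- n_hdr + 1L
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)) || anyNA(unlist(hdr[need])))
    stop(sprintf("'%s' is not a raster (missing or malformed ASCII grid header)", path))
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  vals <- scan(path, what = double(), skip = n_hdr, quiet = TRUE)
  if (length(vals) != nr * nc) {
    bands <- length(vals) / (nr * nc)
    if (bands > 1 && abs(bands - round(bands)) < 1e-9)
      stop(sprintf("multi-band input: expected 1 band, found %d", round(bands)))
    stop(sprintf("'%s' is not a raster (expected %d values, found %d)",
                 path, nr * nc, length(vals)))
  }
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA_real_
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)  # first data row = north
  proj <- "unspecified"
  georef <- NULL
  prj <- sub("\\.asc$", ".prj", path)
  if (!identical(prj, path) && file.exists(prj)) {
    pl <- readLines(prj, warn = FALSE)
    if (length(pl) >= 1L) proj <- pl[[1L]]
    anchor <- grep("^ORIGIN_LONLAT ", pl, value = TRUE)
    if (length(anchor) == 1L) {
      ll <- as.numeric(strsplit(anchor, "\\s+")[[1L]][2:3])
      georef <- list(lon0 = ll[1L], lat0 = ll[2L])
    }
  }
  wind_grid(m, cell_km = hdr$cellsize, xmin = hdr$xllcorner,
            ymin = hdr$yllcorner, proj = proj, georef = georef)
}

#' Write a grid as an ESRI ASCII grid file
#'
#' Values are written at full double precision so finite values round-trip
#' bit-compatibly through [read_grid()]. A `.prj` sidecar records the
#' projection descriptor and geographic anchor.
#'
#' @param grid a [wind_grid()].
#' @param path output path (`.asc`).
#' @param nodata value written for `NA` cells.
#' @return invisibly `path`.
#' @export
write_grid <- function(grid, path, nodata = -9999) {
  stopifnot(is_wind_grid(grid))
  v <- grid$values
  if (any(is.finite(v) & v == nodata))
    stop("nodata sentinel collides with a data value; choose another")
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.17g", grid$xmin),
    sprintf("yllcorner %.17g", grid$ymin),
    sprintf("cellsize %.17g", grid$cell_km),
    sprintf("NODATA_value %.17g", nodata)
  )
  out <- v
  out[!is.finite(out)] <- nodata
  rows <- apply(out, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(hdr, rows), con)
  prj <- sub("\\.asc$", ".prj", path)
  if (!identical(prj, path)) {
    pl <- grid$proj
    if (!is.null(grid$georef))
      pl <- c(pl, sprintf("ORIGIN_LONLAT %.10g %.10g",
                          grid$georef$lon0, grid$georef$lat0))
    writeLines(pl, prj)
  }
  invisible(path)
}

#' Euclidean distance to the nearest target cell
#'
#' Distance in km from each valid cell centre of `study` to the nearest
#' target cell centre (e.g. shoreline cells, as the proxy for grid
#' connection points). Distances are planar in the projected km of the
#' equal-area grid; target cells get 0.
#'
#' @param targets `wind_grid` whose nonzero, non-`NA` cells are targets.
#' @param study `wind_grid` defining validity (`NA` cells stay `NA`).
#' @return a `wind_grid` of distances (km).
#' @export
distance_grid <- function(targets, study) {
  check_congruent(targets, study)
  tm <- targets$values
  tidx <- which(is.finite(tm) & tm != 0, arr.ind = TRUE)
  if (nrow(tidx) == 0L) stop("empty target mask: no target cells")
  cc <- cell_centers(study)
  tx <- cc$x[tidx[, 2L]]; ty <- cc$y[tidx[, 1L]]
  nr <- nrow(study$values); nc <- ncol(study$values)
  px <- rep(cc$x, each = nr)          # column-major cell coords
  py <- rep(cc$y, times = nc)
  d2min <- rep(Inf, nr * nc)
  # chunk over targets to bound memory
  step <- max(1L, floor(2e6 / length(px)))
  for (j0 in seq(1L, length(tx), by = step)) {
    jj <- j0:min(j0 + step - 1L, length(tx))
    d2 <- outer(px, tx[jj], "-")^2 + outer(py, ty[jj], "-")^2
    d2min <- pmin(d2min, do.call(pmin, asplit(d2, 2L)))
  }
  dm <- matrix(sqrt(d2min), nrow = nr, ncol = nc)
  dm[!is.finite(study$values)] <- NA_real_
  out <- study
  out$values <- dm
  out
}

#' Quantile classification of a surface
#'
#' Classifies valid cells into ordered concern categories by empirical
#' quantile, following the 20%/60% "major concern"/"concern" convention of
#' seabird vulnerability mapping. Category 1 is the most extreme tail; ties
#' at a threshold are assigned to the higher-concern category (the inclusive
#' reading of "top 60%").
#'
#' @param grid a `wind_grid`.
#' @param probs tail probabilities in (0,1), e.g. `c(0.2, 0.6)`.
#' @param direction `"upper_tail"` (top-p = highest values) or
#'   `"lower_tail"`.
#' @return object of class `quantile_classes`: list with `thresholds`
#'   (data frame `prob`, `value`), integer `categories` matrix (`NA` on
#'   nodata; 1 = most extreme tail, `length(probs)+1` = remainder),
#'   `direction` and `labels`.
#' @export
quantile_classify <- function(grid, probs = c(0.2, 0.6),
                              direction = c("upper_tail", "lower_tail")) {
  direction <- match.arg(direction)
  stopifnot(is_wind_grid(grid))
  if (any(probs <= 0 | probs >= 1)) stop("probs must lie in (0, 1)")
  probs <- sort(unique(probs))
  v <- grid$values
  ok <- is.finite(v)
  if (!any(ok)) stop("no valid cells to classify")
  x <- v[ok]
  thr <- if (direction == "upper_tail") {
    stats::quantile(x, 1 - probs, type = 7, names = FALSE)
  } else {
    stats::quantile(x, probs, type = 7, names = FALSE)
  }
  cat_m <- matrix(NA_integer_, nrow(v), ncol(v))
  cat_m[ok] <- length(probs) + 1L
  # assign from least to most extreme so the tightest tail wins ties
  for (k in rev(seq_along(probs))) {
    inside <- if (direction == "upper_tail") v >= thr[k] else v <= thr[k]
    cat_m[ok & inside] <- k
  }
  labels <- c(sprintf("top-%g", probs), "rest")
  structure(
    list(thresholds = data.frame(prob = probs, value = thr),
         categories = cat_m, direction = direction, labels = labels),
    class = "quantile_classes"
  )
}

#' @export
print.quantile_classes <- function(x, ...) {
  cat("<quantile_classes>", x$direction, "\n")
  print(x$thresholds)
  tab <- table(factor(x$categories, levels = seq_along(x$labels), labels = x$labels))
  print(tab)
  invisible(x)
}

#' Label connected regions of a boolean mask
#'
#' 8-neighbour connected-component labelling (diagonals connect, matching
#' contour-like hotspot regions). Labels are assigned in row-major scan
#' order from the north-west corner.
#'
#' @param mask `wind_grid`; cells with nonzero, non-`NA` values are in the
#'   mask.
#' @return list with `labels` (a `wind_grid` of integer labels, 0 outside
#'   the mask) and `regions` (tibble `region`, `n_cells`).
#' @export
connected_regions <- function(mask) {
  stopifnot(is_wind_grid(mask))
  m <- is.finite(mask$values) & mask$values != 0
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  nbr <- expand.grid(dr = -1:1, dc = -1:1)
  nbr <- nbr[!(nbr$dr == 0 & nbr$dc == 0), ]
  next_lab <- 0L
  counts <- integer(0)
  for (start in which(m)) {
    if (lab[start] != 0L) next
    next_lab <- next_lab + 1L
    queue <- start
    lab[start] <- next_lab
    n_in <- 0L
    while (length(queue)) {
      cur <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      n_in <- n_in + 1L
      r <- (cur - 1L) %% nr + 1L
      cl <- (cur - 1L) %/% nr + 1L
      rr <- r + nbr$dr; cc <- cl + nbr$dc
      keep <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      idx <- (cc[keep] - 1L) * nr + rr[keep]
      idx <- idx[m[idx] & lab[idx] == 0L]
      if (length(idx)) {
        lab[idx] <- next_lab
        queue <- c(queue, idx)
      }
    }
    counts[next_lab] <- n_in
  }
  lg <- mask
  lg$values <- lab * 1.0
  list(labels = lg,
       regions = tibble::tibble(region = seq_len(next_lab), n_cells = counts))
}

#' Write region outlines or site points as GeoJSON
#'
#' Regions are emitted cell-exactly: each region becomes a MultiPolygon of
#' its cell squares (in lon/lat when the grid carries a geographic anchor,
#' otherwise in projected km).
#'
#' @param labels a `wind_grid` of integer region labels (0 = background),
#'   as returned by [connected_regions()].
#' @param path output `.geojson` path.
#' @return invisibly `path`.
#' @export
write_regions_geojson <- function(labels, path) {
  stopifnot(is_wind_grid(labels))
  lab <- labels$values
  ids <- sort(unique(lab[is.finite(lab) & lab > 0]))
  cc <- cell_centers(labels)
  half <- labels$cell_km / 2
  corner_ll <- function(x, y) {
    if (is.null(labels$georef)) return(c(x, y))
    km <- 111.32
    lat <- labels$georef$lat0 + y / km
    c(labels$georef$lon0 + x / (km * cos(lat * pi / 180)), lat)
  }
  feats <- lapply(ids, function(id) {
    cells <- which(lab == id, arr.ind = TRUE)
    polys <- lapply(seq_len(nrow(cells)), function(i) {
      x <- cc$x[cells[i, 2L]]; y <- cc$y[cells[i, 1L]]
      ring <- list(corner_ll(x - half, y - half), corner_ll(x + half, y - half),
                   corner_ll(x + half, y + half), corner_ll(x - half, y + half),
                   corner_ll(x - half, y - half))
      list(ring)
    })
    list(type = "Feature",
         properties = list(region = id, n_cells = nrow(cells)),
         geometry = list(type = "MultiPolygon", coordinates = polys))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
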