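#' Utility-simulation parameters
#'
#' @param a_grid weighting values for the utility simulation (default 0 to
#'   1 in steps of 0.1, the naive 11-value sweep).
#' @param quantile_major tail probability for "major concern" / hotspot
#'   contours (default 0.20).
#' @param quantile_concern tail probability for "concern" (default 0.60).
#' @return object of class `utility_params`.
#' @export
utility_params <- function(a_grid = seq(0, 1, by = 0.1),
                           quantile_major = 0.20, quantile_concern = 0.60) {
  if (length(a_grid) == 0L || any(a_grid < 0 | a_grid > 1))
    stop("a_grid must be a non-empty subset of [0, 1]")
  if (any(c(quantile_major, quantile_concern) <= 0) ||
      any(c(quantile_major, quantile_concern) >= 1))
    stop("quantiles must lie in (0, 1)")
  structure(list(a_grid = a_grid, quantile_major = quantile_major,
                 quantile_concern = quantile_concern),
            class = "utility_params")
}

#' Normalise the tradeoff axes
#'
#' Cells with negative NPV are excluded as unviable; over the remaining
#' cells both axes are min-max rescaled to `[0, 1]`. Because of this
#' normalisation, utilities are relative to the study area's own value
#' range and are not comparable across study areas.
#'
#' @param npv `wind_grid` of NPV in $M.
#' @param bird `wind_grid` of bird pixel scores.
#' @return list with `W` (wind profitability, `[0,1]`), `Bsens` (bird
#'   sensitivity, `[0,1]`), and `excluded` (logical matrix: cell dropped
#'   for negative NPV).
#' @export
normalize_axes <- function(npv, bird) {
  check_congruent(npv, bird)
  nv <- npv$values; bv <- bird$values
  valid <- is.finite(nv) & is.finite(bv)
  include <- valid & nv >= 0
  if (sum(include) < 2L)
    stop("no viable sites: fewer than 2 cells with non-negative NPV")
  rescale <- function(x) {
    r <- range(x[include])
    if (diff(r) == 0) stop("axis is constant over included cells")
    out <- matrix(NA_real_, nrow(x), ncol(x))
    out[include] <- (x[include] - r[1L]) / (r[2L] - r[1L])
    out
  }
  W <- npv;  W$values <- rescale(nv)
  B <- bird; B$values <- rescale(bv)
  list(W = W, Bsens = B, excluded = valid & !include)
}

#' Utility of a site under one weighting
#'
#' `u = a * W - (1 - a) * B`: weight `a = 1` cares only about wind
#' profitability, `a = 0` only about bird sensitivity.
#'
#' @param W,Bsens normalised wind profitability and bird sensitivity.
#' @param a weighting in `[0, 1]`.
#' @return utility (vectorised).
#' @export
utility <- function(W, Bsens, a) {
  a * W - (1 - a) * Bsens
}

#' Average utility over the weighting sweep
#'
#' The mean of [utility()] over `a_grid` per cell. For the default
#' symmetric 11-value grid this equals `0.5 * (W - Bsens)` exactly.
#'
#' @param W,Bsens normalised `wind_grid`s from [normalize_axes()].
#' @param params a [utility_params()].
#' @return `wind_grid` of average utility.
#' @export
average_utility <- function(W, Bsens, params = utility_params()) {
  check_congruent(W, Bsens)
  if (length(params$a_grid) == 0L) stop("a_grid is empty")
  acc <- matrix(0, nrow(W$values), ncol(W$values))
  for (a in params$a_grid)
    acc <- acc + utility(W$values, Bsens$values, a)
  out <- W
  out$values <- acc / length(params$a_grid)
  out
}

#' Classify tradeoff quadrants
#'
#' Per the concern-quantile convention: "avoid" if a cell sits in the
#' bottom 20% of profitability *or* the top 20% of bird sensitivity;
#' "preferred" if it clears both 60% exclusions (not among the 60% least
#' profitable nor the 60% most sensitive); otherwise "intermediate".
#' Boundary ties go to the more cautious category.
#'
#' @param W,Bsens normalised `wind_grid`s.
#' @param params a [utility_params()].
#' @return character matrix (`NA` on excluded cells) with values
#'   `"avoid"`, `"intermediate"`, `"preferred"`.
#' @export
quadrant_classify <- function(W, Bsens, params = utility_params()) {
  check_congruent(W, Bsens)
  w <- W$values; b <- Bsens$values
  ok <- is.finite(w) & is.finite(b)
  if (sum(ok) < 5L) stop("need at least 5 points to classify")
  qm <- params$quantile_major; qc <- params$quantile_concern
  w_lo <- stats::quantile(w[ok], qm, type = 7, names = FALSE)
  b_hi <- stats::quantile(b[ok], 1 - qm, type = 7, names = FALSE)
  w_mid <- stats::quantile(w[ok], qc, type = 7, names = FALSE)
  b_mid <- stats::quantile(b[ok], 1 - qc, type = 7, names = FALSE)
  out <- matrix(NA_character_, nrow(w), ncol(w))
  out[ok] <- "intermediate"
  out[ok & w > w_mid & b < b_mid] <- "preferred"
  out[ok & (w <= w_lo | b >= b_hi)] <- "avoid"
  out
}

#' Select and rank candidate sites from the utility surface
#'
#' Extracts the top `quantile_major` cells of average utility, labels their
#' 8-connected regions, and takes the peak-utility cell of each region as
#' that region's site. Plateau ties break deterministically to the
#' northernmost then westernmost cell and are flagged. Ranks are dense
#' ranks of the site's utility among *all* valid cells (rank 1 = best cell
#' anywhere), so a site's rank tells how many distinct utility values beat
#' it study-wide.
#'
#' @param u_bar `wind_grid` of average utility.
#' @param params a [utility_params()].
#' @param n_label maximum number of sites to keep (by utility).
#' @return tibble: `label`, `row`, `col`, `lon`, `lat`, `average_utility`,
#'   `rank`, `region`, `region_cells`, `tie`.
#' @export
select_sites <- function(u_bar, params = utility_params(), n_label = 26L) {
  qc <- quantile_classify(u_bar, probs = params$quantile_major,
                          direction = "upper_tail")
  top <- u_bar
  top$values <- ifelse(!is.na(qc$categories) & qc$categories == 1L, 1, 0)
  if (!any(top$values == 1, na.rm = TRUE)) stop("empty top-quantile mask")
  cr <- connected_regions(top)
  lab <- cr$labels$values
  u <- u_bar$values
  u_all <- sort(unique(u[is.finite(u)]), decreasing = TRUE)
  rows <- integer(0); cols <- integer(0); uu <- numeric(0)
  regs <- integer(0); ncells <- integer(0); ties <- logical(0)
  for (r in cr$regions$region) {
    cells <- which(lab == r, arr.ind = TRUE)
    vals <- u[cells]
    peak <- max(vals)
    at <- cells[vals == peak, , drop = FALSE]
    tie <- nrow(at) > 1L
    at <- at[order(at[, 1L], at[, 2L]), , drop = FALSE]  # northern-, westernmost
    rows <- c(rows, unname(at[1L, 1L])); cols <- c(cols, unname(at[1L, 2L]))
    uu <- c(uu, peak); regs <- c(regs, r)
    ncells <- c(ncells, nrow(cells)); ties <- c(ties, tie)
  }
  keep <- order(uu, decreasing = TRUE)[seq_len(min(n_label, length(uu)))]
  keep <- sort(keep)  # labels A, B, ... in region scan order
  ll <- cell_lonlat(u_bar, rows[keep], cols[keep])
  tibble::tibble(
    label = LETTERS[seq_along(keep)],
    row = rows[keep], col = cols[keep],
    lon = ll$lon, lat = ll$lat,
    average_utility = uu[keep],
    rank = match(uu[keep], u_all),
    region = regs[keep], region_cells = ncells[keep],
    tie = ties[keep]
  )
}

#' Complete site records with values and temporal profiles
#'
#' Attaches the unnormalised NPV ($M, as reported), the normalised bird
#' sensitivity, and the 12-month cetacean profile with its minimum month to
#' each selected site. Sites on masked cetacean cells keep their spatial
#' record with a missing profile.
#'
#' @param sites tibble from [select_sites()].
#' @param aggregate aggregate `monthly_stack` from [cetacean_score_map()]
#'   (optional).
#' @param npv `wind_grid` of NPV in $M (optional).
#' @param Bsens normalised bird sensitivity `wind_grid` (optional).
#' @return the sites tibble with added columns `wind_profitability`,
#'   `bird_sensitivity`, `monthly_profile` (list of length-12 vectors),
#'   `best_month`, `best_month_tie`.
#' @export
site_report <- function(sites, aggregate = NULL, npv = NULL, Bsens = NULL) {
  n <- nrow(sites)
  sites$wind_profitability <- if (is.null(npv)) NA_real_ else
    npv$values[cbind(sites$row, sites$col)]
  sites$bird_sensitivity <- if (is.null(Bsens)) NA_real_ else
    Bsens$values[cbind(sites$row, sites$col)]
  profiles <- vector("list", n)
  bm <- rep(NA_integer_, n); bt <- rep(NA, n)
  if (!is.null(aggregate)) {
    for (i in seq_len(n)) {
      p <- tryCatch(monthly_profile(aggregate, sites$row[i], sites$col[i]),
                    error = function(e) NULL)
      if (is.null(p)) {
        warning(sprintf("site %s lies on a masked cetacean cell; profile missing",
                        sites$label[i]))
        next
      }
      profiles[[i]] <- p
      b <- best_month(p)
      bm[i] <- b; bt[i] <- attr(b, "tie")
    }
  }
  sites$monthly_profile <- profiles
  sites$best_month <- bm
  sites$best_month_tie <- bt
  sites
}

#' Write site records as CSV and GeoJSON
#'
#' @param sites completed tibble from [site_report()].
#' @param csv_path,geojson_path output paths (`NULL` to skip either).
#' @return invisibly the flat data frame written.
#' @export
write_sites <- function(sites, csv_path = NULL, geojson_path = NULL) {
  flat <- sites[, setdiff(names(sites), "monthly_profile")]
  if (!is.null(sites$monthly_profile)) {
    pm <- t(vapply(sites$monthly_profile, function(p) {
      if (is.null(p)) rep(NA_real_, 12L) else p
    }, numeric(12L)))
    colnames(pm) <- sprintf("cet_m%02d", 1:12)
    flat <- cbind(flat, as.data.frame(pm))
  }
  if (!is.null(csv_path))
    utils::write.csv(flat, csv_path, row.names = FALSE)
  if (!is.null(geojson_path)) {
    feats <- lapply(seq_len(nrow(flat)), function(i) {
      props <- as.list(flat[i, setdiff(names(flat), c("lon", "lat"))])
      list(type = "Feature", properties = props,
           geometry = list(type = "Point",
                           coordinates = c(flat$lon[i], flat$lat[i])))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         geojson_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(flat)
}
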