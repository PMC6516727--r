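#' Seabird vulnerability table for offshore wind
#'
#' The bundled species-level OWED sensitivity table (21 Atlantic species):
#' the dominant impact channel (collision, displacement or both), its rank
#' and the integer sensitivity value 1-5 used as the weighting in the
#' cumulative surface.
#'
#' @return tibble with columns `common`, `scientific`, `channel`, `rank`,
#'   `value`.
#' @export
owed_bird_table <- function() {
  path <- system.file("extdata", "bird_owed_sensitivity.csv",
                      package = "tradewind", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Species available in the bundled density catalog listing
#'
#' The 27 species with density surfaces in the Atlantic annual-abundance
#' catalog; 6 of these have no OWED sensitivity entry and drop out when
#' matched against [owed_bird_table()].
#'
#' @return tibble with columns `common`, `scientific`.
#' @export
bird_catalog_species <- function() {
  path <- system.file("extdata", "bird_catalog_species.csv",
                      package = "tradewind", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Collision risk score from flight traits
#'
#' `a * (m + t + n) / 3` where `a` is flight altitude, `m` flight
#' maneuverability, `t` percentage of time flying and `n` nocturnal flight
#' activity, each on its expert-elicited source scale.
#'
#' @param traits data frame or list with columns/elements `a`, `m`, `t`, `n`.
#' @return numeric vector of collision risk scores.
#' @export
collision_risk_score <- function(traits) {
  need <- c("a", "m", "t", "n")
  miss <- setdiff(need, names(traits))
  if (length(miss)) stop("missing trait(s): ", paste(miss, collapse = ", "))
  with(traits, a * (m + t + n) / 3)
}

#' Displacement score from disturbance traits
#'
#' `(d * h * c) / 10` where `d` is disturbance by structures and traffic,
#' `h` habitat specialisation and `c` conservation importance.
#'
#' @param traits data frame or list with columns/elements `d`, `h`, `c`.
#' @return numeric vector of displacement scores.
#' @export
displacement_score <- function(traits) {
  need <- c("d", "h", "c")
  miss <- setdiff(need, names(traits))
  if (length(miss)) stop("missing trait(s): ", paste(miss, collapse = ", "))
  (traits[["d"]] * traits[["h"]] * traits[["c"]]) / 10
}

#' Overall species sensitivity
#'
#' The maximum of the collision risk and displacement scores: a species is
#' as sensitive as its worst impact channel.
#'
#' @param collision,displacement numeric vectors.
#' @return elementwise maximum.
#' @export
overall_sensitivity <- function(collision, displacement) {
  if (any(!is.finite(collision)) || any(!is.finite(displacement)))
    stop("scores must be finite")
  pmax(collision, displacement)
}

#' Match density-catalog species against the sensitivity table
#'
#' Name-keyed, case-insensitive; scientific names are preferred and common
#' names used as fallback. Catalog species without a sensitivity entry are
#' dropped (with a reason) rather than silently retained.
#'
#' @param catalog data frame with columns `common` and/or `scientific`
#'   (e.g. [bird_catalog_species()]), or a character vector of names.
#' @param table sensitivity table (default [owed_bird_table()]).
#' @return list with `matched` (catalog rows joined with `value`) and
#'   `dropped` (catalog rows with a `reason` column).
#' @export
match_species <- function(catalog, table = owed_bird_table()) {
  if (is.character(catalog))
    catalog <- tibble::tibble(common = catalog, scientific = catalog)
  catalog <- tibble::as_tibble(catalog)
  if (nrow(catalog) == 0L || nrow(table) == 0L) stop("empty species input")
  key <- function(x) tolower(trimws(as.character(x)))
  for (df_name in c("catalog", "table")) {
    df <- get(df_name)
    for (colnm in intersect(c("common", "scientific"), names(df))) {
      k <- key(df[[colnm]])
      if (anyDuplicated(k))
        stop(sprintf("duplicate %s names in %s: %s", colnm, df_name,
                     paste(unique(df[[colnm]][duplicated(k)]), collapse = ", ")))
    }
  }
  sci_t <- if ("scientific" %in% names(table)) key(table$scientific) else character(0)
  com_t <- if ("common" %in% names(table)) key(table$common) else character(0)
  idx <- rep(NA_integer_, nrow(catalog))
  if ("scientific" %in% names(catalog) && length(sci_t))
    idx <- match(key(catalog$scientific), sci_t)
  if ("common" %in% names(catalog) && length(com_t)) {
    fb <- match(key(catalog$common), com_t)
    idx[is.na(idx)] <- fb[is.na(idx)]
  }
  matched <- catalog[!is.na(idx), , drop = FALSE]
  matched$value <- table$value[idx[!is.na(idx)]]
  dropped <- catalog[is.na(idx), , drop = FALSE]
  if (nrow(dropped)) dropped$reason <- "no sensitivity entry"
  if (nrow(matched) == 0L)
    warning("no catalog species matched the sensitivity table")
  list(matched = matched, dropped = dropped)
}

#' Cumulative bird sensitivity surface
#'
#' Per cell, the mean over species of `log(density + 1) * value`: the
#' log-transformed density of each species weighted by its OWED sensitivity
#' value, averaged across species.
#'
#' @param layers named list of congruent `wind_grid` annual density
#'   surfaces, one per species.
#' @param values named numeric vector of sensitivity values, names matching
#'   `layers`.
#' @param species_mean `"available"` (default) divides by the number of
#'   species with data in each cell; `"strict"` propagates nodata whenever
#'   any species is nodata.
#' @param log_base base of the log transform (default natural).
#' @return a `wind_grid` of bird pixel scores.
#' @export
bird_pixel_score <- function(layers, values,
                             species_mean = c("available", "strict"),
                             log_base = exp(1)) {
  species_mean <- match.arg(species_mean)
  if (length(layers) < 1L) stop("need at least one species layer")
  if (is.null(names(layers)) || !all(names(layers) %in% names(values)))
    stop("every layer needs a matching named sensitivity value")
  do.call(check_congruent, unname(layers))
  ref <- layers[[1L]]
  acc <- matrix(0, nrow(ref$values), ncol(ref$values))
  nsp <- matrix(0L, nrow(ref$values), ncol(ref$values))
  for (sp in names(layers)) {
    d <- layers[[sp]]$values
    if (any(is.finite(d) & d < 0)) stop("negative density in species ", sp)
    ok <- is.finite(d)
    if (species_mean == "strict" && !all(ok)) {
      acc[!ok] <- NA_real_
    }
    contrib <- log(d[ok] + 1, base = log_base) * values[[sp]]
    acc[ok] <- acc[ok] + contrib
    nsp[ok] <- nsp[ok] + 1L
  }
  out <- acc / ifelse(nsp > 0L, nsp, NA_real_)
  out[nsp == 0L] <- NA_real_
  res <- ref
  res$values <- out
  res
}
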