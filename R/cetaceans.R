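#' NatureServe rank to conservation score lookup table
#'
#' Scores scale 1-100 from G1 (critically imperiled, 100) to G5 (secure, 1),
#' with intermediate two-rank codes between the anchors.
#'
#' @return tibble with columns `rank`, `description`, `score`.
#' @export
natureserve_table <- function() {
  path <- system.file("extdata", "natureserve_scores.csv",
                      package = "tradewind", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                    na.strings = ""))
}

#' Cetacean conservation-status table
#'
#' Bundled species table: taxonomic group, IUCN and ESA listings, the
#' NatureServe rank used for scoring, and guild membership for the three
#' guilds (beaked whales, Kogia whales, pilot whales) whose members are
#' scored as a guild average.
#'
#' @return tibble with columns `common`, `scientific`, `group`, `iucn`,
#'   `esa`, `natureserve`, `guild` (`NA` for species scored individually).
#' @export
cetacean_status_table <- function() {
  path <- system.file("extdata", "cetacean_status.csv",
                      package = "tradewind", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                    na.strings = ""))
}

# single-rank anchors G1..G5
.ns_anchor_scores <- c(G1 = 100, G2 = 75, G3 = 51, G4 = 26, G5 = 1)

#' Conservation score for a NatureServe rank
#'
#' Single ranks (G1-G5) are looked up directly. Intermediate two-rank codes
#' (e.g. `G3G4`) take the floor of the midpoint of the flanking single-rank
#' scores, which reproduces all bundled intermediate values (87, 63, 38,
#' 13) from the anchors alone.
#'
#' @param rank character vector of NatureServe codes.
#' @param table optional full lookup table (columns `rank`, `score`)
#'   overriding the rule; defaults to the single-rank anchors plus the
#'   midpoint rule.
#' @return numeric score(s) 1-100.
#' @export
status_score <- function(rank, table = NULL) {
  rank <- toupper(trimws(rank))
  if (!is.null(table)) {
    idx <- match(rank, table$rank)
    if (anyNA(idx))
      stop("unknown NatureServe code(s): ",
           paste(rank[is.na(idx)], collapse = ", "))
    return(as.numeric(table$score[idx]))
  }
  one <- function(r) {
    if (r %in% names(.ns_anchor_scores)) return(unname(.ns_anchor_scores[r]))
    m <- regmatches(r, regexec("^G([1-5])G([1-5])$", r))[[1L]]
    if (length(m) == 3L) {
      lo <- .ns_anchor_scores[paste0("G", m[2L])]
      hi <- .ns_anchor_scores[paste0("G", m[3L])]
      return(floor((unname(lo) + unname(hi)) / 2))
    }
    stop("unknown NatureServe code: ", r)
  }
  vapply(rank, one, numeric(1), USE.NAMES = FALSE)
}

#' Guild conservation score
#'
#' The arithmetic mean of the member species' scores: a guild modelled as a
#' single density surface inherits the average status of its members.
#'
#' @param member_scores numeric vector of member scores.
#' @return the mean score.
#' @export
guild_score <- function(member_scores) {
  if (length(member_scores) < 1L) stop("guild has no member scores")
  mean(member_scores)
}

#' Collapse the species table to analysis units
#'
#' Species outside any guild keep their own score; each guild becomes one
#' unit whose score is the [guild_score()] of its members.
#'
#' @param table a [cetacean_status_table()]-shaped tibble.
#' @return tibble with columns `unit`, `score`, `n_members`.
#' @export
cetacean_unit_scores <- function(table = cetacean_status_table()) {
  table$score <- status_score(table$natureserve)
  solo <- table[is.na(table$guild), ]
  units <- tibble::tibble(unit = solo$common, score = solo$score,
                          n_members = 1L)
  for (g in unique(stats::na.omit(table$guild))) {
    members <- table$score[!is.na(table$guild) & table$guild == g]
    units <- rbind(units,
                   tibble::tibble(unit = g, score = guild_score(members),
                                  n_members = length(members)))
  }
  units
}

#' Monthly density stack for one species
#'
#' @param grids list of 12 congruent `wind_grid`s in month order (Jan-Dec).
#' @param species species or guild name.
#' @param nonnegative enforce the density invariant (values >= 0); disabled
#'   for derived score stacks, which may be negative before rescaling.
#' @return object of class `monthly_stack`.
#' @export
monthly_stack <- function(grids, species = "unnamed", nonnegative = TRUE) {
  if (length(grids) != 12L) stop("a monthly stack needs exactly 12 grids")
  do.call(check_congruent, unname(grids))
  if (nonnegative) for (g in grids) {
    if (any(is.finite(g$values) & g$values < 0))
      stop("densities must be non-negative")
  }
  structure(list(months = grids, species = species), class = "monthly_stack")
}

#' @export
print.monthly_stack <- function(x, ...) {
  cat(sprintf("<monthly_stack> %s: 12 x %d x %d cells\n", x$species,
              nrow(x$months[[1L]]$values), ncol(x$months[[1L]]$values)))
  invisible(x)
}

stack_array <- function(stack) {
  vapply(stack$months, function(g) g$values,
         matrix(0, nrow(stack$months[[1L]]$values),
                ncol(stack$months[[1L]]$values)))
}

#' Mask cells holding the lowest fraction of total cetacean density
#'
#' Total density per cell is summed over all species and months; cells
#' strictly below the `pct` percentile of these totals are masked. Ties at
#' the threshold are kept, so a uniform surface masks nothing.
#'
#' @param stacks list of `monthly_stack`s (all species).
#' @param pct percentile to mask below (default 0.01, the lowest 1%).
#' @return a `wind_grid` validity mask (1 = keep, `NA` = masked or nodata).
#' @export
mask_low_density <- function(stacks, pct = 0.01) {
  if (length(stacks) < 1L) stop("need at least one species stack")
  do.call(check_congruent, lapply(stacks, function(s) s$months[[1L]]))
  ref <- stacks[[1L]]$months[[1L]]
  tot <- matrix(0, nrow(ref$values), ncol(ref$values))
  valid <- matrix(TRUE, nrow(ref$values), ncol(ref$values))
  for (s in stacks) for (g in s$months) {
    v <- g$values
    valid <- valid & is.finite(v)
    tot <- tot + ifelse(is.finite(v), v, 0)
  }
  thr <- stats::quantile(tot[valid], pct, type = 7, names = FALSE)
  keep <- valid & tot >= thr
  out <- ref
  out$values <- ifelse(keep, 1, NA_real_)
  out
}

#' Aggregate monthly cetacean sensitivity surfaces
#'
#' Per species, densities are z-scored over the species' full
#' spatiotemporal stack (all valid cells x 12 months, so months remain
#' comparable), multiplied by the species' conservation score, and averaged
#' across species; the 12-month aggregate is finally min-max rescaled to
#' `[0, 1]` over the whole stack.
#'
#' @param stacks named list of `monthly_stack`s.
#' @param scores named numeric vector of conservation scores (1-100), names
#'   matching `stacks`.
#' @param mask validity mask `wind_grid` from [mask_low_density()]
#'   (optional).
#' @param sd_type `"population"` (divide by N, default) or `"sample"`.
#' @param rescale min-max rescale the aggregate to `[0, 1]` (default TRUE).
#' @return a `monthly_stack` of aggregate scores.
#' @export
cetacean_score_map <- function(stacks, scores, mask = NULL,
                               sd_type = c("population", "sample"),
                               rescale = TRUE) {
  sd_type <- match.arg(sd_type)
  if (length(stacks) < 1L) stop("need at least one species stack")
  if (is.null(names(stacks)) || !all(names(stacks) %in% names(scores)))
    stop("every stack needs a matching named conservation score")
  ref <- stacks[[1L]]$months[[1L]]
  if (!is.null(mask)) check_congruent(ref, mask)
  keep <- if (is.null(mask)) matrix(TRUE, nrow(ref$values), ncol(ref$values))
          else is.finite(mask$values)
  S <- length(stacks)
  agg <- array(0, dim = c(nrow(ref$values), ncol(ref$values), 12L))
  for (sp in names(stacks)) {
    arr <- stack_array(stacks[[sp]])
    sel <- array(rep(keep, 12L), dim = dim(arr)) & is.finite(arr)
    vals <- arr[sel]
    mu <- mean(vals)
    n <- length(vals)
    sdv <- if (sd_type == "population") sqrt(sum((vals - mu)^2) / n)
           else stats::sd(vals)
    if (!is.finite(sdv) || sdv == 0) {
      warning(sprintf("species '%s' has zero density variance; contributes 0",
                      sp))
      next
    }
    z <- array(NA_real_, dim = dim(arr))
    z[sel] <- (arr[sel] - mu) / sdv * scores[[sp]]
    agg <- agg + z / S
  }
  agg[array(rep(!keep, 12L), dim = dim(agg))] <- NA_real_
  if (rescale) {
    rng <- range(agg, na.rm = TRUE)
    if (diff(rng) == 0) stop("aggregate stack is constant; cannot rescale")
    agg <- (agg - rng[1L]) / (rng[2L] - rng[1L])
  }
  months <- lapply(seq_len(12L), function(m) {
    g <- ref
    g$values <- agg[, , m]
    g
  })
  monthly_stack(months, species = "aggregate cetacean score",
                nonnegative = FALSE)
}

#' Monthly sensitivity profile at one cell
#'
#' @param stack a `monthly_stack` (typically the aggregate score).
#' @param row,col cell indices.
#' @return numeric vector of 12 values in month order.
#' @export
monthly_profile <- function(stack, row, col) {
  stopifnot(inherits(stack, "monthly_stack"))
  p <- vapply(stack$months, function(g) g$values[row, col], numeric(1))
  if (any(!is.finite(p)))
    stop(sprintf("cell (%d, %d) is masked or nodata", row, col))
  p
}

#' Month of minimum sensitivity
#'
#' The recommended window for acoustically harmful pre-operational work
#' (pile driving, seismic surveying): the calendar month minimising the
#' aggregate cetacean score at a site. Ties break to the earliest month and
#' are flagged via the `"tie"` attribute.
#'
#' @param profile numeric vector of 12 monthly scores.
#' @return integer month (1-12) with attribute `tie` (logical).
#' @export
best_month <- function(profile) {
  if (length(profile) != 12L || any(!is.finite(profile)))
    stop("profile must be 12 finite values")
  m <- which.min(profile)   # earliest index on ties
  tie <- sum(profile == profile[m]) > 1L
  structure(as.integer(m), tie = tie)
}
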