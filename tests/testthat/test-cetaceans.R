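test_that("status scores reproduce the lookup anchors and midpoint rule", {
  expect_equal(status_score("G1"), 100)
  expect_equal(status_score("G2"), 75)
  expect_equal(status_score("G3"), 51)
  expect_equal(status_score("G4"), 26)
  expect_equal(status_score("G5"), 1)
  # floor-midpoint reproduces every bundled intermediate value
  expect_equal(status_score(c("G1G2", "G2G3", "G3G4", "G4G5")),
               c(87, 63, 38, 13))
  tab <- natureserve_table()
  expect_equal(status_score(tab$rank), tab$score)
  # an explicit table overrides the rule
  expect_equal(status_score("G3G4", table = data.frame(rank = "G3G4",
                                                      score = 40)), 40)
  expect_error(status_score("G9"), "unknown NatureServe code")
  expect_error(status_score("GX"), "unknown NatureServe code")
})

test_that("guild scores average member species", {
  expect_equal(guild_score(c(26, 26, 51, 51, 51)), 41)  # beaked whales
  expect_equal(guild_score(c(26, 26)), 26)              # Kogia whales
  expect_equal(guild_score(c(1, 1)), 1)                 # pilot whales
  expect_error(guild_score(numeric(0)), "no member")

  units <- cetacean_unit_scores()
  expect_equal(units$score[units$unit == "Beaked whales"], 41)
  expect_equal(units$score[units$unit == "Kogia whales"], 26)
  expect_equal(units$score[units$unit == "Pilot whales"], 1)
  expect_equal(units$n_members[units$unit == "Beaked whales"], 5L)
  expect_equal(units$score[units$unit == "North Atlantic right whale"], 100)
})

test_that("low-density masking drops the sparse tail and keeps ties", {
  set.seed(12)
  base <- matrix(runif(100, 5, 10), 10, 10)
  base[4, 7] <- 1e-6   # one near-empty cell
  stacks <- list(a = const_stack(base))
  mask <- mask_low_density(stacks)
  expect_true(is.na(mask$values[4, 7]))
  expect_equal(sum(is.na(mask$values)), 1)

  # uniform totals: threshold ties are kept, nothing masked
  u <- mask_low_density(list(a = const_stack(matrix(2, 6, 6))))
  expect_false(anyNA(u$values))

  # sort-and-threshold oracle on random totals
  tot <- matrix(runif(400), 20, 20)
  m2 <- mask_low_density(list(a = const_stack(tot)))
  thr <- quantile(as.vector(tot) * 12, 0.01, type = 7)
  expect_identical(is.na(m2$values), tot * 12 < thr)
})

test_that("aggregate score map matches a brute-force z-score loop", {
  set.seed(21)
  nr <- 7; nc <- 5
  stacks <- list(); scores <- c(s1 = 100, s2 = 41, s3 = 13)
  for (nm in names(scores)) {
    grids <- lapply(1:12, function(m) random_grid(nr, nc, min = 0, max = 20))
    stacks[[nm]] <- monthly_stack(grids, nm)
  }
  agg <- cetacean_score_map(stacks, scores, rescale = FALSE)
  for (m in sample(1:12, 4)) for (r in seq_len(nr)) for (cl in seq_len(nc)) {
    terms <- vapply(names(scores), function(nm) {
      vals <- unlist(lapply(stacks[[nm]]$months, function(g) g$values))
      d <- stacks[[nm]]$months[[m]]$values[r, cl]
      (d - mean(vals)) / sqrt(mean((vals - mean(vals))^2)) * scores[nm]
    }, numeric(1))
    expect_equal(agg$months[[m]]$values[r, cl], mean(terms),
                 tolerance = 1e-12)
  }
})

test_that("rescaled aggregate attains 0 and 1 and respects invariances", {
  set.seed(22)
  mk <- function() monthly_stack(lapply(1:12, function(m)
    random_grid(6, 6, min = 0, max = 10)), "x")
  s1 <- mk()
  agg1 <- cetacean_score_map(list(a = s1), c(a = 55))
  vals <- unlist(lapply(agg1$months, function(g) g$values))
  expect_equal(min(vals), 0)
  expect_equal(max(vals), 1)

  # single species: monotone transforms collapse to min-max of the stack
  raw <- unlist(lapply(s1$months, function(g) g$values))
  expect_equal(vals, (raw - min(raw)) / (max(raw) - min(raw)),
               tolerance = 1e-12)

  # duplicated species with equal scores change nothing
  agg2 <- cetacean_score_map(list(a = s1, b = s1), c(a = 55, b = 55))
  expect_equal(unlist(lapply(agg2$months, function(g) g$values)), vals,
               tolerance = 1e-12)

  # z-scoring is invariant to positive rescaling and shifts of one species
  s2 <- mk()
  two <- list(a = s1, b = s2)
  sc <- c(a = 100, b = 26)
  base <- cetacean_score_map(two, sc, rescale = FALSE)
  s2b <- monthly_stack(lapply(s2$months, function(g) {
    g$values <- g$values * 3.7 + 2; g
  }), "x")
  alt <- cetacean_score_map(list(a = s1, b = s2b), sc, rescale = FALSE)
  expect_equal(unlist(lapply(alt$months, function(g) g$values)),
               unlist(lapply(base$months, function(g) g$values)),
               tolerance = 1e-10)
})

test_that("guild averaging equals a pseudo-species with the mean score", {
  set.seed(23)
  s <- monthly_stack(lapply(1:12, function(m) random_grid(5, 5, min = 0,
                                                          max = 8)), "g")
  direct <- cetacean_score_map(list(g = s), c(g = guild_score(c(26, 51))),
                               rescale = FALSE)
  asguild <- cetacean_score_map(list(g = s), c(g = 38.5), rescale = FALSE)
  expect_equal(unlist(lapply(direct$months, function(x) x$values)),
               unlist(lapply(asguild$months, function(x) x$values)))
})

test_that("raising a concentrated species' score lifts its month", {
  set.seed(24)
  flat <- matrix(5, 6, 6)
  months <- rep(list(grid_of(flat)), 12)
  hot <- flat; hot[3, 3] <- 50
  months[[4]] <- grid_of(hot)   # concentrated in April at one hotspot
  conc <- monthly_stack(months, "migrant")
  other <- const_stack(matrix(runif(36, 1, 4), 6, 6))
  rel_april <- function(c_mig) {
    agg <- cetacean_score_map(list(m = conc, o = other),
                              c(m = c_mig, o = 26), rescale = FALSE)
    agg$months[[4]]$values[3, 3] - agg$months[[1]]$values[3, 3]
  }
  expect_gt(rel_april(100), rel_april(10))
})

test_that("zero-variance species contribute nothing, with a warning", {
  set.seed(25)
  s1 <- monthly_stack(lapply(1:12, function(m) random_grid(4, 4, min = 0,
                                                           max = 5)), "a")
  s2 <- const_stack(matrix(3, 4, 4))
  expect_warning(
    agg <- cetacean_score_map(list(a = s1, b = s2), c(a = 50, b = 99),
                              rescale = FALSE),
    "zero density variance")
  solo <- cetacean_score_map(list(a = s1), c(a = 50), rescale = FALSE)
  # b contributes 0 but still counts in the species mean (S = 2)
  expect_equal(unlist(lapply(agg$months, function(g) g$values)),
               unlist(lapply(solo$months, function(g) g$values)) / 2,
               tolerance = 1e-12)
})

test_that("monthly profiles index the aggregate stack", {
  set.seed(26)
  grids <- lapply(1:12, function(m) grid_of(matrix(m / 12, 4, 4)))
  stack <- monthly_stack(grids, "agg")
  p <- monthly_profile(stack, 2, 3)
  expect_equal(p, (1:12) / 12)
  # direct-indexing oracle on a random stack
  rnd <- monthly_stack(lapply(1:12, function(m) random_grid(4, 4)), "r")
  expect_equal(monthly_profile(rnd, 3, 1),
               vapply(1:12, function(m) rnd$months[[m]]$values[3, 1],
                      numeric(1)))
  # masked cell errors
  rnd$months[[5]]$values[1, 1] <- NA
  expect_error(monthly_profile(rnd, 1, 1), "masked")
  # constant stack gives a flat profile
  expect_equal(monthly_profile(const_stack(matrix(0.4, 4, 4)), 1, 1),
               rep(0.4, 12))
})

test_that("best month is the argmin with earliest-month tie breaking", {
  p <- rep(0.5, 12); p[5] <- 0.1
  bm <- best_month(p)
  expect_equal(as.integer(bm), 5)
  expect_false(attr(bm, "tie"))
  bmc <- best_month(rep(0.3, 12))
  expect_equal(as.integer(bmc), 1)
  expect_true(attr(bmc, "tie"))
  expect_error(best_month(c(rep(0.1, 11), NA)), "finite")
  expect_error(best_month(1:5), "12")
})

test_that("migration scenario plants a mid-summer trough at mid-coast", {
  b <- make_scenario(small_scenario_config(seed = 9))
  mask <- mask_low_density(b$cetaceans$stacks)
  agg <- cetacean_score_map(b$cetaceans$stacks, b$cetaceans$scores,
                            mask = mask)
  # nearshore mid-coast cell: month of minimum matches the generator's
  # own geometric ground truth
  nr <- b$config$nrow
  r <- round(nr * 2 / 3); cl <- 3   # mid-coast latfrac ~ 1/3, nearshore
  p <- monthly_profile(agg, r, cl)
  expect_equal(as.integer(best_month(p)),
               b$truth$trough_month_midcoast)
  # the profile is two-peaked: both migration passages exceed the trough
  expect_gt(p[3], min(p))
  expect_gt(p[11], min(p))
})
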