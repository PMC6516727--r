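test_that("Weibull fitting recovers generating parameters", {
  set.seed(2024)
  x <- rweibull(50000, shape = 2, scale = 8)
  w <- fit_weibull(x)
  expect_lt(abs(w$shape - 2) / 2, 0.02)
  expect_lt(abs(w$scale - 8) / 8, 0.02)

  # exponential special case: scale estimate ~ sample mean (Gamma(2) = 1)
  y <- rweibull(50000, shape = 1, scale = 5)
  w1 <- fit_weibull(y)
  expect_lt(abs(w1$scale - mean(y)) / mean(y), 0.02)

  # moments fallback agrees with MLE to a few percent
  wm <- fit_weibull(x, method = "moments")
  expect_lt(abs(wm$shape - w$shape) / w$shape, 0.05)
  expect_lt(abs(wm$scale - w$scale) / w$scale, 0.05)

  expect_error(fit_weibull(rep(7, 100)), "zero variance")
  expect_error(fit_weibull(c(-1, x[1:100])), "positive")
  expect_error(fit_weibull(x[1:10]), "at least 30")
})

test_that("hub-height extrapolation scales only the Weibull scale", {
  w <- weibull_params(2, 7, reference_height = 10)
  expect_equal(scale_to_hub(w, 10)$scale, 7)              # identity
  h <- scale_to_hub(w, 90, shear_alpha = 1 / 7)
  expect_equal(h$scale, 7 * 9^(1 / 7), tolerance = 1e-12)
  expect_equal(h$scale / 7, 1.3687, tolerance = 1e-4)
  expect_equal(h$reference_height, 90)
  for (alpha in c(0, 0.1, 0.5)) {
    expect_equal(scale_to_hub(w, 120, alpha)$shape, w$shape)
  }
  expect_error(scale_to_hub(w, -5), "positive")
})

test_that("power curve honours cut-in, rated and cut-out speeds", {
  spec <- turbine_spec()   # 5 MW, 3 / 12.5 / 30 m/s
  expect_equal(power_at_speed(2, spec), 0)
  expect_equal(power_at_speed(12.5, spec), 5)
  expect_equal(power_at_speed(20, spec), 5)
  expect_equal(power_at_speed(31, spec), 0)
  expect_equal(power_at_speed(30, spec), 0)   # cut-out itself stops the rotor
  # cubic partial-load region evaluated by hand
  v <- 8
  expect_equal(power_at_speed(v, spec),
               5 * (v^3 - 3^3) / (12.5^3 - 3^3))
  expect_error(turbine_spec(cut_in = 15), "cut_in < rated_speed")
})

test_that("annual energy matches constant-power and zero-wind limits", {
  farm <- farm_spec()
  # near-constant power: tiny cut-in/rated, huge cut-out -> P ~ rated always
  spec <- turbine_spec(rated_power = 5, cut_in = 1e-6, rated_speed = 2e-6,
                       cut_out = 1e4)
  w <- weibull_params(2, 8, 90)
  e <- annual_energy(w, spec, farm)
  expect_equal(e, 80 * 5 * 1000 * 8760 * 0.95, tolerance = 1e-6)
  # vanishing wind resource
  e0 <- annual_energy(weibull_params(2, 0.01, 90), turbine_spec(), farm)
  expect_lt(e0, 1)
})

test_that("annual energy agrees with quadrature and Monte-Carlo oracles", {
  spec <- turbine_spec()
  farm <- farm_spec()
  w <- weibull_params(2.1, 9.5, 90)
  e <- annual_energy(w, spec, farm)
  # independent quadrature oracle
  f <- function(v) power_at_speed(v, spec) * dweibull(v, w$shape, w$scale)
  ep_int <- integrate(f, 0, spec$cut_out, rel.tol = 1e-10)$value
  e_int <- farm$n_turbines * 8760 * (1 - farm$availability_loss) * ep_int * 1000
  expect_equal(e, e_int, tolerance = 1e-8)
  # Monte-Carlo oracle (modest n here; the full-scale check runs in the
  # acceptance suite)
  set.seed(7)
  vs <- rweibull(2e5, w$shape, w$scale)
  e_mc <- farm$n_turbines * 8760 * (1 - farm$availability_loss) *
    mean(power_at_speed(vs, spec)) * 1000
  expect_lt(abs(e - e_mc) / e_mc, 0.01)
})

test_that("annual energy is monotone in the Weibull scale", {
  spec <- turbine_spec(); farm <- farm_spec()
  es <- vapply(seq(4, 14, by = 1),
               function(l) annual_energy(weibull_params(2, l, 90), spec, farm),
               numeric(1))
  expect_true(all(diff(es) > 0))
})

test_that("transmission cost switches coefficient sets exactly at 60 km", {
  econ <- econ_params(ac_coeffs = c(0, 1), dc_coeffs = c(0, 1))
  expect_equal(transmission_cost(400, 37.5, econ), 37.5)  # coefficient isolation
  econ2 <- econ_params(ac_coeffs = c(0.5, 2), dc_coeffs = c(3, 10))
  expect_equal(transmission_cost(400, 59.9, econ2), 0.5 * 400 + 2 * 59.9)
  expect_equal(transmission_cost(400, 60, econ2), 3 * 400 + 10 * 60)
  expect_equal(transmission_cost(400, 80, econ2), 3 * 400 + 10 * 80)
  expect_error(transmission_cost(400, -1, econ2), "negative")
  expect_error(transmission_cost(0, 10, econ2), "positive")
})

test_that("npv matches the geometric-series closed form", {
  expect_equal(npv(5, 5, 0, 0.08, 20), 0)                  # zero net flow
  expect_equal(npv(12, 2, 0, 0, 2), 20)                    # undiscounted
  expect_equal(npv(1, 0, 0, 0.05, 20),
               (1 - 1.05^-20) / 0.05, tolerance = 1e-12)
  expect_equal(npv(1, 0, 0, 0.05, 20), 12.4622, tolerance = 1e-4)
  # explicit year-by-year sum oracle
  i <- 0.07; T <- 15; net <- 3.2; capex <- 11
  expect_equal(npv(net + 1, 1, capex, i, T),
               -capex + sum(net / (1 + i)^(1:T)), tolerance = 1e-12)
  # capex timing convention
  expect_equal(npv(1, 0, 10, 0.05, 20, capex_timing = "year1"),
               npv(1, 0, 10 / 1.05, 0.05, 20))
  expect_error(npv(1, 0, 0, -1.5, 20), "exceed -1")
})

test_that("NPV responds monotonically to price, discount rate and cable", {
  spec <- turbine_spec(); econ <- econ_params()
  w <- weibull_params(2, 8, 10)
  cell_npv <- function(price, disc, cable) {
    farm <- farm_spec(price_per_kwh = price)
    e <- annual_energy(scale_to_hub(w, spec$hub_height), spec, farm)
    tc <- transmission_cost(400, cable, econ_params(discount_rate = disc))
    capex <- 80 * 12 + tc
    npv(price * e / 1e6, 0.035 * capex, capex, disc, 20)
  }
  prices <- vapply(c(0.1, 0.15, 0.2, 0.25), cell_npv, numeric(1),
                   disc = 0.05, cable = 30)
  expect_true(all(diff(prices) > 0))
  discs <- vapply(c(0.02, 0.05, 0.08), function(d) cell_npv(0.2, d, 30),
                  numeric(1))
  expect_true(all(diff(discs) < 0))
  cables <- vapply(c(10, 30, 50), function(cb) cell_npv(0.2, 0.05, cb),
                   numeric(1))
  expect_true(all(diff(cables) < 0))
})

test_that("valuation map equals the scalar pipeline applied per cell", {
  set.seed(31)
  nr <- 6; nc <- 5
  kg <- grid_of(matrix(2, nr, nc))
  lg <- grid_of(matrix(runif(nr * nc, 5, 10), nr, nc))
  lg$values[2, 2] <- NA
  dg <- grid_of(matrix(runif(nr * nc, 5, 120), nr, nc))
  spec <- turbine_spec(); farm <- farm_spec(); econ <- econ_params()
  vm <- valuation_map(kg, lg, dg, spec, farm, econ)
  for (cell in which(is.finite(lg$values))) {
    w <- scale_to_hub(weibull_params(2, lg$values[cell], 10),
                      spec$hub_height)
    cable <- dg$values[cell] + farm$extra_cable_km
    tc <- transmission_cost(farm$n_turbines * spec$rated_power, cable, econ,
                            farm$acdc_switch_km)
    capex <- farm$n_turbines *
      (farm$turbine_unit_cost + farm$install_cost_per_turbine) + tc
    rev <- farm$price_per_kwh * annual_energy(w, spec, farm) / 1e6
    expect_equal(vm$values[cell],
                 npv(rev, farm$om_fraction * capex, capex,
                     econ$discount_rate, farm$lifetime),
                 tolerance = 1e-10)
  }
  expect_true(is.na(vm$values[2, 2]))
})

test_that("NPV is negative when the resource sits below cut-in", {
  kg <- grid_of(matrix(2, 4, 4))
  lg <- grid_of(matrix(0.3, 4, 4))   # hub-height winds almost never > 3 m/s
  dg <- grid_of(matrix(20, 4, 4))
  vm <- valuation_map(kg, lg, dg, turbine_spec(), farm_spec(), econ_params())
  expect_true(all(vm$values < 0))
})

test_that("monotone distance with uniform wind gives NPV decreasing offshore", {
  kg <- grid_of(matrix(2, 5, 8))
  lg <- grid_of(matrix(8, 5, 8))
  dg <- grid_of(matrix(rep(seq(10, 150, length.out = 8), each = 5), 5, 8))
  vm <- valuation_map(kg, lg, dg, turbine_spec(), farm_spec(), econ_params())
  expect_true(all(diff(vm$values[3, ]) < 0))
})
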