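#' Turbine specification
#'
#' Defaults describe the 5 MW reference turbine used throughout: cut-in
#' 3 m/s, rated 12.5 m/s, cut-out 30 m/s, 116 m rotor, 90 m hub. The power
#' curve between cut-in and rated speed is polynomial in `v^x` with
#' exponent `x` (default cubic, the physically motivated choice).
#'
#' @param rated_power rated power, MW.
#' @param cut_in,rated_speed,cut_out curve speeds, m/s.
#' @param rotor_diameter rotor diameter, m.
#' @param hub_height hub height, m.
#' @param power_exponent polynomial exponent of the partial-load curve.
#' @return object of class `turbine_spec`.
#' @export
turbine_spec <- function(rated_power = 5, cut_in = 3, rated_speed = 12.5,
                         cut_out = 30, rotor_diameter = 116, hub_height = 90,
                         power_exponent = 3) {
  if (!(0 < cut_in && cut_in < rated_speed && rated_speed < cut_out))
    stop("need 0 < cut_in < rated_speed < cut_out")
  if (rated_power <= 0) stop("rated_power must be positive")
  structure(list(rated_power = rated_power, cut_in = cut_in,
                 rated_speed = rated_speed, cut_out = cut_out,
                 rotor_diameter = rotor_diameter, hub_height = hub_height,
                 power_exponent = power_exponent),
            class = "turbine_spec")
}

#' Farm and cost configuration
#'
#' Defaults mirror the 400 MW reference farm: 80 turbines over a 20 year
#' lifetime, $2M installation per turbine, O&M at 3.5% of capital
#' expenditure per year, 4 km of extra cable from shore to grid, and an
#' AC-to-DC transmission switch at 60 km of total cable. The turbine unit
#' cost, electricity price and availability loss are not dictated by the
#' valuation model itself and are configurable; defaults follow the InVEST
#' offshore wind documentation lineage this valuation reimplements.
#'
#' @param n_turbines number of turbines.
#' @param lifetime farm lifetime, years.
#' @param extra_cable_km cable from shore to grid connection, km.
#' @param acdc_switch_km total cable length at/above which DC coefficients
#'   apply.
#' @param install_cost_per_turbine $M per turbine (flat; depth-dependent
#'   foundation cost deliberately not modelled).
#' @param turbine_unit_cost $M per turbine.
#' @param om_fraction annual O&M as a fraction of capex.
#' @param price_per_kwh $ per kWh.
#' @param availability_loss fraction of gross production lost.
#' @return object of class `farm_spec`.
#' @export
farm_spec <- function(n_turbines = 80, lifetime = 20, extra_cable_km = 4,
                      acdc_switch_km = 60, install_cost_per_turbine = 2,
                      turbine_unit_cost = 10, om_fraction = 0.035,
                      price_per_kwh = 0.2, availability_loss = 0.05) {
  if (om_fraction < 0 || om_fraction >= 1) stop("om_fraction must be in [0, 1)")
  if (lifetime < 1) stop("lifetime must be at least 1 year")
  structure(list(n_turbines = n_turbines, lifetime = lifetime,
                 extra_cable_km = extra_cable_km,
                 acdc_switch_km = acdc_switch_km,
                 install_cost_per_turbine = install_cost_per_turbine,
                 turbine_unit_cost = turbine_unit_cost,
                 om_fraction = om_fraction, price_per_kwh = price_per_kwh,
                 availability_loss = availability_loss),
            class = "farm_spec")
}

#' Economic parameters
#'
#' @param discount_rate annual discount rate (weighted average cost of
#'   capital); default 5%.
#' @param ac_coeffs,dc_coeffs transmission-cost coefficients `c(beta0, beta1)`
#'   in $M/MW and $M/km for the AC (< switch distance) and DC regimes.
#' @return object of class `econ_params`.
#' @export
econ_params <- function(discount_rate = 0.05,
                        ac_coeffs = c(beta0 = 0.81, beta1 = 1.36),
                        dc_coeffs = c(beta0 = 1.09, beta1 = 0.89)) {
  if (discount_rate <= -1) stop("discount_rate must exceed -1")
  if (any(c(ac_coeffs, dc_coeffs) < 0)) stop("coefficients must be >= 0")
  structure(list(discount_rate = discount_rate,
                 ac_coeffs = unname(ac_coeffs), dc_coeffs = unname(dc_coeffs)),
            class = "econ_params")
}

#' Weibull wind-resource parameters
#'
#' @param shape shape parameter k (dimensionless).
#' @param scale scale parameter lambda (m/s).
#' @param reference_height height the parameters refer to, m.
#' @return object of class `weibull_params`.
#' @export
weibull_params <- function(shape, scale, reference_height = 10) {
  if (shape <= 0 || scale <= 0) stop("shape and scale must be positive")
  structure(list(shape = shape, scale = scale,
                 reference_height = reference_height),
            class = "weibull_params")
}

#' Fit a Weibull distribution to wind-speed samples
#'
#' Maximum likelihood by default (via \pkg{fitdistrplus}); a
#' method-of-moments fallback solves the coefficient-of-variation identity
#' for the shape parameter.
#'
#' @param speeds numeric vector of wind speeds, m/s (> 0).
#' @param method `"mle"` or `"moments"`.
#' @param reference_height height the samples refer to, m.
#' @return a [weibull_params()].
#' @export
fit_weibull <- function(speeds, method = c("mle", "moments"),
                        reference_height = 10) {
  method <- match.arg(method)
  speeds <- as.numeric(speeds)
  if (length(speeds) < 30L) stop("need at least 30 wind-speed samples")
  if (any(!is.finite(speeds)) || any(speeds <= 0))
    stop("wind-speed samples must be positive and finite")
  if (stats::sd(speeds) == 0)
    stop("zero variance: cannot fit a Weibull to constant samples")
  if (method == "mle") {
    fit <- fitdistrplus::fitdist(speeds, "weibull")
    est <- fit$estimate
    return(weibull_params(est[["shape"]], est[["scale"]], reference_height))
  }
  # moments: CV(k) = sqrt(G(1+2/k)/G(1+1/k)^2 - 1) is decreasing in k
  cv <- stats::sd(speeds) / mean(speeds)
  f <- function(k) sqrt(gamma(1 + 2 / k) / gamma(1 + 1 / k)^2 - 1) - cv
  k <- stats::uniroot(f, c(0.1, 50), tol = 1e-10)$root
  lambda <- mean(speeds) / gamma(1 + 1 / k)
  weibull_params(k, lambda, reference_height)
}

#' Extrapolate Weibull scale to hub height by the power law
#'
#' The scale parameter is multiplied by `(hub / reference)^alpha`; the shape
#' is unchanged (wind-shear power law applied to the speed scale).
#'
#' @param w a [weibull_params()].
#' @param hub_height target height, m.
#' @param shear_alpha shear exponent (default 1/7, the neutral open-water
#'   convention).
#' @return a [weibull_params()] at `hub_height`.
#' @export
scale_to_hub <- function(w, hub_height, shear_alpha = 1 / 7) {
  stopifnot(inherits(w, "weibull_params"))
  if (hub_height <= 0 || w$reference_height <= 0)
    stop("heights must be positive")
  weibull_params(w$shape,
                 w$scale * (hub_height / w$reference_height)^shear_alpha,
                 hub_height)
}

#' Turbine power at a given wind speed
#'
#' Zero below cut-in and at/above cut-out, rated power between rated speed
#' and cut-out, and the polynomial partial-load curve
#' `rated * (v^x - cut_in^x) / (rated_speed^x - cut_in^x)` between cut-in
#' and rated speed.
#'
#' @param v wind speed(s), m/s.
#' @param spec a [turbine_spec()].
#' @return power in MW (vectorised over `v`).
#' @export
power_at_speed <- function(v, spec) {
  stopifnot(inherits(spec, "turbine_spec"))
  x <- spec$power_exponent
  denom <- spec$rated_speed^x - spec$cut_in^x
  p <- ifelse(
    v < spec$cut_in | v >= spec$cut_out, 0,
    ifelse(v >= spec$rated_speed, spec$rated_power,
           spec$rated_power * (v^x - spec$cut_in^x) / denom)
  )
  pmax(p, 0)
}

# Regularised lower incomplete-gamma evaluation of
# integral_a^b v^x dWeibull(v; k, lambda): exact partial moments.
weibull_partial_moment <- function(x, k, lambda, a, b) {
  s <- 1 + x / k
  lambda^x * gamma(s) * (stats::pgamma((b / lambda)^k, s) -
                         stats::pgamma((a / lambda)^k, s))
}

#' Expected annual farm energy production
#'
#' Expected single-turbine power is the integral of the power curve against
#' the hub-height Weibull density over `[0, cut_out]`, evaluated exactly via
#' incomplete-gamma partial moments; annual farm energy multiplies by hours
#' per year, the turbine count and one minus the availability loss.
#'
#' @param w hub-height [weibull_params()].
#' @param spec a [turbine_spec()].
#' @param farm a [farm_spec()].
#' @return kWh per year.
#' @export
annual_energy <- function(w, spec, farm) {
  stopifnot(inherits(w, "weibull_params"))
  ep <- expected_power(w$shape, w$scale, spec)
  farm$n_turbines * 8760 * (1 - farm$availability_loss) * ep * 1000
}

# Expected power (MW) of one turbine; vectorised over shape/scale.
expected_power <- function(k, lambda, spec) {
  x <- spec$power_exponent
  ci <- spec$cut_in; rs <- spec$rated_speed; co <- spec$cut_out
  denom <- rs^x - ci^x
  part <- weibull_partial_moment(x, k, lambda, ci, rs)
  F <- function(v) stats::pweibull(v, shape = k, scale = lambda)
  partial <- spec$rated_power * (part - ci^x * (F(rs) - F(ci))) / denom
  rated <- spec$rated_power * (F(co) - F(rs))
  partial + rated
}

#' Transmission cost of connecting a farm to the grid
#'
#' `TransCost = beta0 * MW + beta1 * TotCable`, with separate coefficient
#' sets for AC cable below the switch distance and DC at or beyond it.
#'
#' @param mw farm capacity, MW.
#' @param total_cable_km total cable laid, km (distance to shore plus the
#'   extra shore-to-grid run).
#' @param econ an [econ_params()].
#' @param acdc_switch_km switch distance, km.
#' @return cost in $M (vectorised over `total_cable_km`).
#' @export
transmission_cost <- function(mw, total_cable_km, econ, acdc_switch_km = 60) {
  stopifnot(inherits(econ, "econ_params"))
  if (mw <= 0) stop("mw must be positive")
  if (any(total_cable_km < 0)) stop("cable length cannot be negative")
  b <- ifelse(total_cable_km >= acdc_switch_km,
              TRUE, FALSE)
  b0 <- ifelse(b, econ$dc_coeffs[1L], econ$ac_coeffs[1L])
  b1 <- ifelse(b, econ$dc_coeffs[2L], econ$ac_coeffs[2L])
  b0 * mw + b1 * total_cable_km
}

#' Net present value of constant annual net flows
#'
#' `NPV = -capex + sum_{t=1..T} (R - C) (1 + i)^-t` with constant annual
#' revenue `R` and recurring cost `C`. By default capital expenditure is
#' incurred at `t = 0` undiscounted; `capex_timing = "year1"` instead
#' discounts it one period, for sensitivity to the alternative convention.
#'
#' @param annual_revenue,annual_cost constant flows, $M/yr.
#' @param capex capital expenditure, $M.
#' @param i discount rate.
#' @param T lifetime, years.
#' @param capex_timing `"upfront"` (default) or `"year1"`.
#' @return NPV, $M (vectorised over the flow arguments).
#' @export
npv <- function(annual_revenue, annual_cost, capex, i, T,
                capex_timing = c("upfront", "year1")) {
  capex_timing <- match.arg(capex_timing)
  if (i <= -1) stop("discount rate must exceed -1")
  if (T < 1) stop("lifetime T must be at least 1")
  annuity <- if (i == 0) T else (1 - (1 + i)^(-T)) / i
  cap <- if (capex_timing == "upfront") capex else capex / (1 + i)
  (annual_revenue - annual_cost) * annuity - cap
}

#' Per-cell net present value of the candidate wind farm
#'
#' Applies the full valuation per cell: total cable = distance to shore +
#' the extra shore-to-grid run; capex = turbines (unit + installation) +
#' transmission; annual O&M = `om_fraction * capex`; revenue =
#' `price_per_kwh * annual energy` from the cell's hub-height Weibull
#' resource. Negative values are retained (coastal cells can be
#' unprofitable).
#'
#' @param shape_grid,scale_grid `wind_grid`s of Weibull shape and scale at
#'   the reference height.
#' @param dist_grid `wind_grid` of distance to shore, km.
#' @param spec a [turbine_spec()].
#' @param farm a [farm_spec()].
#' @param econ an [econ_params()].
#' @param reference_height height of the wind product, m.
#' @param shear_alpha power-law shear exponent used to reach hub height.
#' @param at_hub set `TRUE` if `scale_grid` is already at hub height.
#' @return a `wind_grid` of NPV in $M.
#' @export
valuation_map <- function(shape_grid, scale_grid, dist_grid, spec, farm, econ,
                          reference_height = 10, shear_alpha = 1 / 7,
                          at_hub = FALSE) {
  check_congruent(shape_grid, scale_grid, dist_grid)
  k <- shape_grid$values
  lam <- scale_grid$values
  if (!at_hub) lam <- lam * (spec$hub_height / reference_height)^shear_alpha
  d <- dist_grid$values
  ok <- is.finite(k) & is.finite(lam) & is.finite(d)
  out <- matrix(NA_real_, nrow(k), ncol(k))
  if (any(ok)) {
    mw <- farm$n_turbines * spec$rated_power
    cable <- d[ok] + farm$extra_cable_km
    tc <- transmission_cost(mw, cable, econ, farm$acdc_switch_km)
    capex <- farm$n_turbines *
      (farm$turbine_unit_cost + farm$install_cost_per_turbine) + tc
    ep <- expected_power(k[ok], lam[ok], spec)
    energy_kwh <- farm$n_turbines * 8760 * (1 - farm$availability_loss) *
      ep * 1000
    revenue <- farm$price_per_kwh * energy_kwh / 1e6   # $M/yr
    om <- farm$om_fraction * capex
    out[ok] <- npv(revenue, om, capex, econ$discount_rate, farm$lifetime)
  }
  res <- shape_grid
  res$values <- out
  res
}
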