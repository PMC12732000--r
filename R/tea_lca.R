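# Techno-economic scaling / payback arithmetic and emission-factor carbon
# accounting for the assisted-operation scenario.

#' Economic scenario
#'
#' @param electricity_price USD/kWh (typical range 0.08-0.12).
#' @param feedstock_cost USD/t (25-35).
#' @param lifetime equipment lifetime, years.
#' @param discount_rate annual discount rate in (0, 1).
#' @param capacity plant capacity, t/d.
#' @param reference_capacity reference plant capacity, t/d.
#' @param capacity_index exponent alpha of the cost-capacity scaling law.
#' @param capex capital cost, USD (plant-specific; required for payback).
#' @param operating_saving operating-cost saving, USD/t.
#' @return Object of class `econ_scenario`.
#' @export
econ_scenario <- function(electricity_price = 0.10, feedstock_cost = 30,
                          lifetime = 10, discount_rate = 0.08,
                          capacity = 100, reference_capacity = 30,
                          capacity_index = 0.65, capex = NULL,
                          operating_saving = 13.5) {
  stopifnot(electricity_price > 0, feedstock_cost > 0, lifetime > 0,
            discount_rate > 0, discount_rate < 1, capacity > 0,
            reference_capacity > 0, capacity_index > 0,
            operating_saving > 0)
  structure(as.list(environment()), class = "econ_scenario")
}

#' Emission scenario
#'
#' Regional grid emission factor and energy-savings assumptions. Bundled
#' presets follow typical regional grid factors: China 0.65, EU 0.35,
#' USA 0.45 kg CO2/kWh with 8/9/10% energy-savings rates.
#'
#' @param region label.
#' @param grid_factor kg CO2 per kWh (> 0).
#' @param energy_savings_rate fraction of baseline energy use saved, [0, 1].
#' @param baseline_energy_intensity kWh per t of feed (plant-specific).
#' @return Object of class `emission_scenario`.
#' @export
emission_scenario <- function(region = "China", grid_factor = 0.65,
                              energy_savings_rate = 0.08,
                              baseline_energy_intensity = 100) {
  stopifnot(grid_factor > 0, energy_savings_rate >= 0,
            energy_savings_rate <= 1, baseline_energy_intensity > 0)
  structure(list(region = region, grid_factor = grid_factor,
                 energy_savings_rate = energy_savings_rate,
                 baseline_energy_intensity = baseline_energy_intensity),
            class = "emission_scenario")
}

#' Regional emission presets
#'
#' @param baseline_energy_intensity kWh/t applied to every preset.
#' @return list of [emission_scenario()] objects for China, EU and USA.
#' @export
emission_presets <- function(baseline_energy_intensity = 100) {
  list(
    China = emission_scenario("China", 0.65, 0.08,
                              baseline_energy_intensity),
    EU = emission_scenario("EU", 0.35, 0.09, baseline_energy_intensity),
    USA = emission_scenario("USA", 0.45, 0.10, baseline_energy_intensity)
  )
}

#' Capacity cost scaling
#'
#' `cost = reference_cost * (capacity / reference_capacity)^alpha`; with
#' `alpha < 1` costs scale sub-linearly (economies of scale).
#'
#' @param reference_cost cost at the reference capacity (USD).
#' @param reference_capacity,capacity capacities (t/d).
#' @param alpha capacity index (default 0.65).
#' @return Scaled cost (USD).
#' @export
scale_cost <- function(reference_cost, reference_capacity, capacity,
                       alpha = 0.65) {
  stopifnot(reference_cost > 0, reference_capacity > 0, capacity > 0,
            alpha > 0)
  reference_cost * (capacity / reference_capacity)^alpha
}

#' Discounted payback period
#'
#' Smallest `t` (years) at which the cumulative discounted annual saving
#' reaches the capital cost, with linear interpolation inside the crossing
#' year; `NA` if the capex is not recovered within the lifetime.
#'
#' @param capex capital cost (USD, > 0).
#' @param annual_saving annual saving (USD/yr, > 0).
#' @param discount_rate annual discount rate (>= 0).
#' @param lifetime horizon in years.
#' @return Payback period in years, or `NA`.
#' @export
discounted_payback <- function(capex, annual_saving, discount_rate = 0.08,
                               lifetime = 10) {
  stopifnot(capex > 0, annual_saving > 0, discount_rate >= 0, lifetime >= 1)
  disc <- annual_saving / (1 + discount_rate)^(seq_len(lifetime))
  cum <- cumsum(disc)
  if (cum[lifetime] < capex) return(NA_real_)
  t_hit <- which(cum >= capex)[1]
  prev <- if (t_hit == 1) 0 else cum[t_hit - 1]
  (t_hit - 1) + (capex - prev) / disc[t_hit]
}

#' Annual operating saving
#'
#' @param operating_saving saving per ton of feed (USD/t, > 0).
#' @param capacity plant capacity (t/d, >= 0).
#' @param uptime_days operating days per year.
#' @return USD per year.
#' @export
annual_saving <- function(operating_saving, capacity, uptime_days = 330) {
  stopifnot(operating_saving > 0, capacity >= 0, uptime_days > 0)
  operating_saving * capacity * uptime_days
}

#' Avoided energy and carbon under an emission scenario
#'
#' `energy_saved = intensity * throughput * savings_rate` and
#' `co2_avoided = energy_saved * grid_factor`.
#'
#' @param scenario an [emission_scenario()].
#' @param throughput annual feed throughput (t/yr).
#' @return list with `energy_saved` (kWh/yr) and `co2_avoided` (kg/yr).
#' @export
carbon_reduction <- function(scenario, throughput) {
  stopifnot(inherits(scenario, "emission_scenario"), throughput >= 0)
  energy_saved <- scenario$baseline_energy_intensity * throughput *
    scenario$energy_savings_rate
  list(energy_saved = energy_saved,
       co2_avoided = energy_saved * scenario$grid_factor)
}

#' Payback sensitivity sweep
#'
#' Tabulates the discounted payback over a grid of electricity prices and
#' feedstock costs. The per-ton operating saving is modelled as a base
#' saving plus sensitivities to both prices:
#' `saving = base + e_sens * (electricity_price - 0.10) * intensity +
#' f_sens * (feedstock_cost - 30)`.
#'
#' @param scenario an [econ_scenario()] with `capex` set.
#' @param electricity_prices,feedstock_costs grid vectors (USD/kWh, USD/t).
#' @param energy_intensity kWh/t (electricity-cost exposure).
#' @param e_sens fraction of the energy bill saved (links price to saving).
#' @param f_sens additional saving per USD/t of feedstock cost (better
#'   conversion reduces effective feedstock spend).
#' @param uptime_days operating days per year.
#' @return data.frame: electricity_price, feedstock_cost, operating_saving,
#'   annual_saving, payback_years.
#' @export
payback_sensitivity <- function(scenario,
                                electricity_prices = c(0.08, 0.10, 0.12),
                                feedstock_costs = c(25, 30, 35),
                                energy_intensity = 100, e_sens = 0.09,
                                f_sens = 0.05, uptime_days = 330) {
  stopifnot(inherits(scenario, "econ_scenario"))
  if (is.null(scenario$capex))
    stop("payback sweep requires capex in the scenario")
  grid <- expand.grid(electricity_price = electricity_prices,
                      feedstock_cost = feedstock_costs)
  grid$operating_saving <- scenario$operating_saving +
    e_sens * (grid$electricity_price - 0.10) * energy_intensity +
    f_sens * (grid$feedstock_cost - 30)
  grid$annual_saving <- annual_saving(1, scenario$capacity, uptime_days) *
    grid$operating_saving
  grid$payback_years <- vapply(grid$annual_saving, function(a)
    discounted_payback(scenario$capex, a, scenario$discount_rate,
                       scenario$lifetime), numeric(1))
  grid
}
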