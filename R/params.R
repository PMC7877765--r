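#' Default model parameters
#'
#' Returns the full list of model parameters with their default values:
#' the landscape (grid size, plot productivities, agroecology multiples),
#' the agents (household count, diets, labour requirements), climate response
#' rates, and the price/credit system. Monetary food prices are in cents/kg;
#' wages, asset prices and incomes are in dollars.
#'
#' @return A named list of class `fs_params`.
#' @details Key defaults: a 21x21 grid of 1-ha plots with maximum orphan
#'   productivity Uniform(800, 1200) kg/yr; agroecology yield multiples
#'   truncated-Normal(4, 1.5) on \[2, 7\] reached after a 3-year transition;
#'   250 four-person households each needing a 700 kg/yr basic diet; full
#'   production on 1 ha of orphan agriculture requires one full-time worker
#'   (150 ten-hour days) eating an extra 2900 kcal/day; warming costs 4% of
#'   yield per degree C (10% less under agroecology) and drought losses are
#'   reduced by 20% under agroecology; a low-skilled wage is 180% of the cost
#'   of a basic diet, drifting +2%/yr; necessary inputs cost 15% of a wage per
#'   ha at full production (doubled under agroecology); fertilizer costs 10x
#'   the food price per kg, lifts a plot up to 10x its base yield, and
#'   saturates at 500 kg/ha.
#' @export
default_params <- function() {
  p <- list(
    grid_side = 21L,
    n_households = 250L,
    years = 50L,
    base_plot_yield_mean = 1000,
    base_plot_yield_halfwidth = 0.20,
    agro_multiple_mean = 4,
    agro_multiple_sd = 1.5,
    agro_multiple_bounds = c(2, 7),
    agro_transition_years = 3L,
    agro_labour_multiple = 2,
    basic_diet = 700,
    labour_full_kcal = 5100,
    labour_extra_kcal = 2900,
    labour_days_full = 150,
    cereal_kcal_per_kg = 2200 * 365 / 200,   # 4015 kcal/kg
    warming_loss_per_degC = 0.04,
    agro_warming_loss_reduction = 0.10,
    agro_drought_loss_reduction = 0.20,
    drought_risk_base = 0.05,
    yield_noise_halfwidth = 0.15,
    expectation_noise_halfwidth = 0.05,
    abandonment_diet_fraction = 0.5,
    plot_yield_cap = 10000,
    orphan_yield_increment_peasant = 0.015,
    orphan_yield_increment_other = 0.010,
    agro_yield_increment_peasant = 0.030,
    agro_yield_increment_other = 0.015,
    initial_local_price = 40,
    initial_global_price = 40,
    wage_markup = 1.8,
    wage_drift = 0.02,
    necessary_input_share = 0.15,
    orphan_input_share = 0.5,
    fertilizer_price_multiple = 10,
    fertilizer_drift = 0.01,
    fertilizer_max_kg = 500,
    fertilizer_max_multiple = 10,
    animal_capacity_ha = 5,
    tractor_capacity_ha = 16,
    animal_price_years = 30,
    tractor_price_years = 150,
    land_price_tonnes = 30,
    interest_short = 0.20,
    interest_mid = 0.15,
    interest_long = 0.10,
    loan_term_short = 1L,
    loan_term_mid = 5L,     # midpoint of the 3-6 year range
    loan_term_long = 8L,
    agro_max_ha = 10,
    agro_max_animal_teams = 2L,
    entre_land_per_year = 1L,
    agro_expansion_min_years_per_ha = 3L,
    family_workers = 2,
    workers_manual_ha = 1,
    oscillator_amplitude = 1.5,
    oscillator_period = 10,
    global_trend_sd_multiple = 1,       # sd of annual decline = multiple x mean rate
    entre_ask_markup = 1.2,
    peasant_ask_markup = 1.0,
    entre_ask_discount = 0.995,
    entre_expansion_income_share = 0.10, # expansion goal: net income >= 10% of asset value
    spend_fraction = 0.20,               # 'spend' saving style consumes this share of cash gains
    price_floor = 1
  )
  class(p) <- c("fs_params", "list")
  p
}

#' Extra labour diet per full-time worker-year
#'
#' Cereal (kg/yr) needed to feed one full-time farm worker beyond the basic
#' family diet: 2900 kcal/day over 150 working days at 4015 kcal/kg, about
#' 108 kg of cereal equivalents.
#' @param params parameter list from [default_params()]
#' @return kg of cereal equivalents per FTE-year
#' @export
labour_diet_per_fte <- function(params) {
  params$labour_extra_kcal * params$labour_days_full / params$cereal_kcal_per_kg
}

#' Validate a parameter list
#'
#' Checks positivity/range invariants: fractions in \[0,1\], prices, yields
#' and counts strictly positive, agroecology multiple bounds within
#' (1, fertilizer_max_multiple\].
#' @param params parameter list
#' @return `params`, invisibly; stops with the offending field name otherwise
#' @export
validate_params <- function(params) {
  chk_pos <- c("grid_side", "n_households", "years", "base_plot_yield_mean",
               "basic_diet", "plot_yield_cap", "initial_local_price",
               "initial_global_price", "wage_markup", "fertilizer_price_multiple",
               "fertilizer_max_kg", "animal_capacity_ha", "tractor_capacity_ha",
               "land_price_tonnes", "cereal_kcal_per_kg")
  for (f in chk_pos) {
    if (!is.numeric(params[[f]]) || any(params[[f]] <= 0))
      stop("configuration error: '", f, "' must be strictly positive", call. = FALSE)
  }
  chk_frac <- c("base_plot_yield_halfwidth", "warming_loss_per_degC",
                "agro_warming_loss_reduction", "agro_drought_loss_reduction",
                "drought_risk_base", "yield_noise_halfwidth",
                "expectation_noise_halfwidth", "abandonment_diet_fraction",
                "necessary_input_share", "wage_drift", "fertilizer_drift",
                "interest_short", "interest_mid", "interest_long",
                "spend_fraction")
  for (f in chk_frac) {
    v <- params[[f]]
    if (!is.numeric(v) || any(v < 0) || any(v > 1))
      stop("configuration error: '", f, "' must lie in [0, 1]", call. = FALSE)
  }
  b <- params$agro_multiple_bounds
  if (length(b) != 2 || b[1] <= 1 || b[2] > params$fertilizer_max_multiple || b[1] > b[2])
    stop("configuration error: 'agro_multiple_bounds' must lie within (1, fertilizer_max_multiple]",
         call. = FALSE)
  invisible(params)
}

#' Agricultural policy scenarios
#'
#' The four policy scenarios and their settings: the proportion of orphan
#' households preferring to develop via agroecology, the global price
#' transmission elasticity, and the policy instruments (fertilizer subsidy and
#' halved interest rates under the entrepreneurial policies, raised peasant
#' yield increments under the peasant policy; the eroding variant phases its
#' support out linearly over the run).
#'
#' @param name one of `"entrepreneurial"`, `"entrepreneurial_eroding"`,
#'   `"peasant"`, `"none"`
#' @return A named list of class `fs_policy`.
#' @export
policy_scenario <- function(name = c("none", "entrepreneurial",
                                     "entrepreneurial_eroding", "peasant")) {
  name <- match.arg(name)
  defs <- list(
    entrepreneurial = list(prop_pref_agro = 0.25, transmission = 0.75,
                           fertilizer_subsidy = 0.5, interest_halved = TRUE,
                           eroding = FALSE, yield_increment_profile = "other"),
    entrepreneurial_eroding = list(prop_pref_agro = 0.25, transmission = 0.75,
                                   fertilizer_subsidy = 0.5, interest_halved = TRUE,
                                   eroding = TRUE, yield_increment_profile = "other"),
    peasant = list(prop_pref_agro = 0.75, transmission = 0.25,
                   fertilizer_subsidy = 0, interest_halved = FALSE,
                   eroding = FALSE, yield_increment_profile = "peasant"),
    none = list(prop_pref_agro = 0.5, transmission = 0.5,
                fertilizer_subsidy = 0, interest_halved = FALSE,
                eroding = FALSE, yield_increment_profile = "other")
  )
  pol <- c(list(name = name), defs[[name]])
  class(pol) <- c("fs_policy", "list")
  pol
}

#' Climate change scenarios
#'
#' The three climate scenarios: total warming over 50 years, the drought-risk
#' multiplier reached at year 50 (risk interpolates linearly from the 5%/yr
#' baseline), the mean and maximum local drought yield loss, the mean annual
#' decline rate of the global food price, and the range of the global price
#' bump following a global drought.
#'
#' @param name one of `"no"`, `"low"`, `"high"`
#' @return A named list of class `fs_climate_scenario`.
#' @export
climate_scenario <- function(name = c("no", "low", "high")) {
  name <- match.arg(name)
  defs <- list(
    no   = list(warming_total_degC = 0, drought_risk_multiplier_at_50yr = 1,
                local_drought_loss_mean = 0.075, local_drought_loss_max = 0.20,
                global_trend_decline = 0.015, global_drought_bump = c(0.05, 0.075)),
    low  = list(warming_total_degC = 1, drought_risk_multiplier_at_50yr = 1.5,
                local_drought_loss_mean = 0.10, local_drought_loss_max = 0.25,
                global_trend_decline = 0.0125, global_drought_bump = c(0.075, 0.125)),
    high = list(warming_total_degC = 2, drought_risk_multiplier_at_50yr = 2,
                local_drought_loss_mean = 0.15, local_drought_loss_max = 0.30,
                global_trend_decline = 0.010, global_drought_bump = c(0.10, 0.175))
  )
  cl <- c(list(name = name), defs[[name]])
  class(cl) <- c("fs_climate_scenario", "list")
  cl
}

#' Build a fully-resolved scenario configuration
#'
#' Combines a policy scenario, a climate scenario and the model parameters
#' into one validated configuration. Overrides may adjust any declared
#' parameter or scenario field (e.g. `prop_pref_agro` and `transmission` for
#' style-preference sweeps) and may switch on sensitivity mode via
#' `sens_yield_ratio` (fixed agroecology:entrepreneurial yield ratio, no
#' agroecology yield growth) and `sens_agro_climate` (agroecology climate
#' sensitivity relative to entrepreneurial: 0.9, 1.0 or 1.1).
#'
#' @param policy_name policy scenario name (see [policy_scenario()])
#' @param climate_name climate scenario name (see [climate_scenario()])
#' @param overrides named list of overrides; unknown names are an error
#' @return A list of class `fs_config` with elements `params`, `policy`,
#'   `climate` and `sens` (NULL unless sensitivity mode is requested).
#' @examples
#' cfg <- build_scenario("peasant", "no")
#' cfg$policy$prop_pref_agro   # 0.75
#' cfg$policy$transmission     # 0.25
#' @export
build_scenario <- function(policy_name = "none", climate_name = "no",
                           overrides = list()) {
  params <- default_params()
  policy <- policy_scenario(policy_name)
  climate <- climate_scenario(climate_name)
  sens <- NULL

  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("configuration error: overrides must be named", call. = FALSE)
    for (nm in names(overrides)) {
      val <- overrides[[nm]]
      if (nm == "sens_yield_ratio") {
        if (!is.numeric(val) || val <= 0 || val > 1)
          stop("configuration error: 'sens_yield_ratio' must lie in (0, 1]", call. = FALSE)
        sens <- c(sens, list(yield_ratio = val))
      } else if (nm == "sens_agro_climate") {
        if (!is.numeric(val) || val < 0.5 || val > 1.5)
          stop("configuration error: 'sens_agro_climate' out of range", call. = FALSE)
        sens <- c(sens, list(agro_climate = val))
      } else if (nm %in% c("prop_pref_agro", "transmission")) {
        if (!is.numeric(val) || val < 0 || val > 1)
          stop("configuration error: '", nm, "' must lie in [0, 1]", call. = FALSE)
        policy[[nm]] <- val
      } else if (nm %in% c("fertilizer_subsidy", "interest_halved", "eroding",
                           "yield_increment_profile")) {
        policy[[nm]] <- val
      } else if (nm %in% setdiff(names(climate), "name")) {
        climate[[nm]] <- val
      } else if (nm %in% names(params)) {
        params[[nm]] <- val
      } else {
        stop("configuration error: unknown field '", nm, "'", call. = FALSE)
      }
    }
  }
  if (!is.null(sens) && is.null(sens$agro_climate))
    sens$agro_climate <- 1 - params$agro_warming_loss_reduction
  validate_params(params)
  cfg <- list(params = params, policy = policy, climate = climate, sens = sens)
  class(cfg) <- c("fs_config", "list")
  cfg
}

#' Linear erosion of a policy value over the run
#'
#' Linearly interpolates a policy setting (a subsidy or interest rate) between
#' its initial value at year 0 and its final value at the horizon. Years past
#' the horizon clamp to the final value.
#'
#' @param initial value at year 0
#' @param final value at `horizon`
#' @param year current year (0-based)
#' @param horizon years over which the value erodes
#' @return interpolated value
#' @examples
#' eroded_value(0.5, 0, 25, 50)  # 0.25
#' @export
eroded_value <- function(initial, final, year, horizon) {
  if (year < 0) stop("configuration error: year must be >= 0", call. = FALSE)
  if (year > horizon) year <- horizon
  initial + (final - initial) * year / horizon
}

#' Write and read a scenario configuration file
#'
#' Serializes a resolved configuration to a flat YAML document (one key per
#' parameter/scenario field) and reads it back. Round-tripping reproduces the
#' identical resolved configuration.
#'
#' @param config an `fs_config` from [build_scenario()]
#' @param path file path
#' @return `read_config` returns an `fs_config`.
#' @export
write_config <- function(config, path) {
  flat <- c(
    list(policy = config$policy$name, climate = config$climate$name),
    config$policy[setdiff(names(config$policy), "name")],
    config$climate[setdiff(names(config$climate), "name")],
    config$params
  )
  if (!is.null(config$sens)) {
    flat$sens_yield_ratio <- config$sens$yield_ratio
    flat$sens_agro_climate <- config$sens$agro_climate
  }
  attributes(flat) <- list(names = names(flat))
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  flat <- yaml::read_yaml(path)
  policy_name <- flat$policy
  climate_name <- flat$climate
  flat$policy <- NULL
  flat$climate <- NULL
  cfg <- build_scenario(policy_name, climate_name, overrides = flat)
  cfg
}
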