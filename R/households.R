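#' Initialize the household population
#'
#' Creates 250 four-person households, all initially practicing orphan
#' agriculture on one 1-ha plot, with no savings and production at their
#' plot's maximum yield. Each household holds a fixed preference for its
#' development style (agroecology with probability `prop_pref_agro`, else
#' entrepreneurial), a rationing preference (production vs family nutrition)
#' and a saving style (hoard vs spend), the latter two assigned 50/50.
#'
#' @param params parameter list
#' @param policy policy scenario (supplies `prop_pref_agro`)
#' @param landscape an `fs_landscape` with owners placed
#' @return list of class `fs_households` of parallel vectors over households
#' @export
init_households <- function(params, policy, landscape) {
  n <- params$n_households
  pref <- ifelse(stats::runif(n) < policy$prop_pref_agro,
                 "agroecology", "entrepreneurial")
  ration <- ifelse(stats::runif(n) < 0.5, "production", "nutrition")
  saving <- ifelse(stats::runif(n) < 0.5, "hoard", "spend")
  own_plot <- match(seq_len(n), landscape$owner)
  base <- landscape$base_max_yield[own_plot]
  p0 <- params$initial_local_price / 100
  # at initialization every household produces at its plot maximum; net income
  # is the surplus after the family basic diet, the labour diet, and the
  # orphan-level necessary inputs
  wage0 <- params$wage_markup * params$basic_diet * p0
  nec0 <- params$orphan_input_share * params$necessary_input_share * wage0
  ni0 <- (base - params$basic_diet - labour_diet_per_fte(params)) * p0 - nec0
  H <- list(
    id = seq_len(n),
    active = rep(TRUE, n),
    style = rep("orphan", n),
    pref = pref,
    ration_pref = ration,
    save_style = saving,
    savings = numeric(n),
    teams = integer(n),
    tractors = integer(n),
    converted_year = rep(NA_integer_, n),
    abandoned_year = rep(NA_integer_, n),
    last_land_year = rep(-10L, n),
    last_production = base,
    net_income = ni0,
    last_niha = ni0,
    gross_value = base * p0,
    purch_inputs = rep(nec0, n),
    diet_frac = rep(1, n),
    fte_used = rep(1, n),
    hired_fte = numeric(n),
    optimized = rep(TRUE, n)
  )
  H
}

#' Attainable maximum production of a farm
#'
#' The binding minimum of area capacity and summed plot potential. Area
#' capacity comes from workers and their tools: a manual worker farms 1 ha, a
#' worker with a team of working animals 5 ha, with a small tractor 16 ha.
#' Peasant farms are limited to 2 family workers; entrepreneurial farms hire
#' manual workers freely so their land is the binding constraint. Plot
#' potential is the current maximum yield for orphan/agroecology plots and
#' `fertilizer_max_multiple x base` for entrepreneurial plots.
#'
#' @param area plots owned (ha), vectorized
#' @param plot_sum summed plot potential (kg/yr)
#' @param style style vector
#' @param teams,tractors equipment counts
#' @param params parameter list
#' @return list with `A` (attainable kg/yr), `fte_full` (FTE at full
#'   production) and `cap_ha` (area capacity)
#' @export
attainable_max <- function(area, plot_sum, style, teams, tractors, params) {
  fam <- params$family_workers
  teams_used <- pmin(teams, fam)
  cap_peasant <- params$animal_capacity_ha * teams_used + (fam - teams_used)
  cap_ha <- ifelse(style == "entrepreneurial", Inf, cap_peasant)
  ratio <- ifelse(area > 0, pmin(1, cap_ha / area), 0)
  A <- plot_sum * ratio

  area_eff <- pmin(area, cap_ha)
  # greedy assignment of best tools first
  tr_ha <- pmin(area_eff, params$tractor_capacity_ha * tractors)
  an_ha <- pmin(area_eff - tr_ha, params$animal_capacity_ha * teams)
  man_ha <- area_eff - tr_ha - an_ha
  fte <- tr_ha / params$tractor_capacity_ha + an_ha / params$animal_capacity_ha + man_ha
  list(A = A, fte_full = fte, cap_ha = cap_ha)
}

#' Input requirements at an output fraction
#'
#' Production shows diminishing returns to the variable inputs: producing an
#' output fraction `q` of the attainable maximum requires the input fraction
#' `x = q^2` of the full-production requirement on each variable channel
#' (labour effort and its diet, necessary inputs, fertilizer). Labour-diet and
#' necessary-input intensity double under agroecology (per transitioned ha);
#' fertilizer (500 kg/ha at full production) applies only to entrepreneurial
#' farms.
#'
#' @param q output fraction in \[0, 1\], vectorized
#' @param fte_full FTE at full production
#' @param area farm size (ha)
#' @param intensity agroecology intensity factor (1 for orphan/entrepreneurial;
#'   between 1 and 2 for agroecology farms, by share of transitioned plots)
#' @param style style vector
#' @param wage low-skilled wage ($/FTE-yr)
#' @param params parameter list
#' @return list with `fte` (labour FTE), `labour_diet_kg`,
#'   `necessary_cost` ($), `fertilizer_kg`
#' @export
input_requirements <- function(q, fte_full, area, intensity, style, wage, params) {
  x <- q^2
  ld_fte <- labour_diet_per_fte(params)
  peasant <- style != "entrepreneurial"
  list(
    fte = x * fte_full,
    labour_diet_kg = ifelse(peasant, x * ld_fte * fte_full * intensity, 0),
    necessary_cost = x * params$necessary_input_share * wage * area * intensity,
    fertilizer_kg = ifelse(peasant, 0, x * params$fertilizer_max_kg * area)
  )
}

#' Realize production from a target
#'
#' Actual yield is the target scaled by the warming loss factor, the per-farm
#' drought loss factor, and random variation of +/-15%, floored at zero.
#'
#' @param target target production (kg), vectorized
#' @param warming_factor from [warming_loss_factor()]
#' @param drought_factor from [drought_loss_factor()]
#' @param noise per-farm multiplicative noise (e.g. Uniform(0.85, 1.15));
#'   pass 1 to disable
#' @return realized yield (kg)
#' @export
realize_production <- function(target, warming_factor, drought_factor, noise = 1) {
  pmax(0, target * warming_factor * drought_factor * noise)
}

#' Expected price for the coming year
#'
#' Current local price plus one year of the mean annual change over the
#' previous five years, times multiplicative Uniform(1-h, 1+h) noise
#' representing unmodelled influences on expectations.
#'
#' @param local_history local price series (cents/kg), most recent last
#' @param noise per-household noise vector (pass 1 to disable)
#' @param floor minimum price (cents/kg)
#' @return expected price vector (cents/kg)
#' @export
expected_price <- function(local_history, noise = 1, floor = 1) {
  k <- length(local_history)
  cur <- local_history[k]
  span <- min(5, k - 1)
  trend <- if (span >= 1) (cur - local_history[k - span]) / span else 0
  pmax(floor, (cur + trend) * noise)
}
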