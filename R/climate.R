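#' Initialize climate state
#'
#' @param scenario climate scenario from [climate_scenario()]
#' @param params parameter list
#' @return list of class `fs_climate` with warming, drought risk and this
#'   year's drought outcomes (all zero/none at year 0)
#' @export
init_climate <- function(scenario, params) {
  cl <- list(
    scenario = scenario, year = 0L, warming = 0,
    local_drought_risk = params$drought_risk_base,
    local_drought = FALSE, community_loss = 0,
    global_drought = FALSE, global_bump = 0
  )
  cl
}

#' Advance the climate by one year
#'
#' Warming rises linearly to the scenario total over the 50-year horizon, and
#' drought risk rises linearly from its 5%/yr baseline by the scenario's
#' risk multiplier. Local and global drought events are drawn independently at
#' the current risk. If a local drought occurs, a community-level mean yield
#' loss is drawn Uniform(0, 2 x scenario mean), truncated at the scenario
#' maximum, so its expectation equals the scenario mean. If a global drought
#' occurs, the global price bump is drawn uniformly from the scenario range.
#'
#' @param climate an `fs_climate`
#' @param params parameter list
#' @param horizon years over which warming/risk trends complete (default 50)
#' @return the advanced `fs_climate`
#' @export
step_climate <- function(climate, params, horizon = 50) {
  sc <- climate$scenario
  yr <- climate$year + 1L
  climate$year <- yr
  climate$warming <- sc$warming_total_degC * yr / horizon
  mult <- 1 + (sc$drought_risk_multiplier_at_50yr - 1) * yr / horizon
  climate$local_drought_risk <- params$drought_risk_base * mult

  climate$local_drought <- stats::runif(1) < climate$local_drought_risk
  loss_draw <- stats::runif(1, 0, 2 * sc$local_drought_loss_mean)
  climate$community_loss <- if (climate$local_drought)
    min(loss_draw, sc$local_drought_loss_max) else 0

  climate$global_drought <- stats::runif(1) < climate$local_drought_risk
  bump_draw <- stats::runif(1, sc$global_drought_bump[1], sc$global_drought_bump[2])
  climate$global_bump <- if (climate$global_drought) bump_draw else 0
  climate
}

#' Warming-related yield loss factor
#'
#' Multiplicative factor applied to target yield: `1 - rate * warming`,
#' floored at 0, where the rate is 4%/degC for orphan and entrepreneurial
#' farming and 10% lower (3.6%/degC) under agroecology. In sensitivity mode
#' the agroecology rate is `rate * agro_sensitivity` instead.
#'
#' @param warming degrees C of warming
#' @param style `"orphan"`, `"agroecology"` or `"entrepreneurial"` (vectorized)
#' @param params parameter list
#' @param agro_sensitivity agroecology loss rate relative to entrepreneurial
#'   (default `1 - agro_warming_loss_reduction` = 0.9)
#' @return multiplicative yield factor in \[0, 1\]
#' @export
warming_loss_factor <- function(warming, style, params = default_params(),
                                agro_sensitivity = NULL) {
  if (is.null(agro_sensitivity))
    agro_sensitivity <- 1 - params$agro_warming_loss_reduction
  rate <- ifelse(style == "agroecology",
                 params$warming_loss_per_degC * agro_sensitivity,
                 params$warming_loss_per_degC)
  pmax(0, 1 - rate * warming)
}

#' Per-farm drought yield loss factor
#'
#' When a local drought has occurred with community-level mean loss
#' `base_loss`, each farm's loss varies multiplicatively around it
#' (Uniform(0.75, 1.25) noise), is clamped to \[0, max loss\], and is reduced
#' by 20% under agroecology (or scaled by `agro_sensitivity` in sensitivity
#' mode). Returns `1 - loss`, clamped to \[0, 1\].
#'
#' @param base_loss community mean loss fraction this year (0 if no drought)
#' @param style style vector (as in [warming_loss_factor()])
#' @param noise per-farm multiplicative noise (same length as `style`);
#'   pass 1 to disable
#' @param params parameter list
#' @param loss_max scenario maximum loss fraction
#' @param agro_sensitivity agroecology loss relative to entrepreneurial
#'   (default `1 - agro_drought_loss_reduction` = 0.8)
#' @return multiplicative yield factor in \[0, 1\]
#' @export
drought_loss_factor <- function(base_loss, style, noise = 1,
                                params = default_params(), loss_max = 1,
                                agro_sensitivity = NULL) {
  if (base_loss <= 0) return(rep(1, length(style)))
  if (is.null(agro_sensitivity))
    agro_sensitivity <- 1 - params$agro_drought_loss_reduction
  loss <- pmin(pmax(base_loss * noise, 0), loss_max)
  loss <- ifelse(style == "agroecology", loss * agro_sensitivity, loss)
  pmin(pmax(1 - loss, 0), 1)
}
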