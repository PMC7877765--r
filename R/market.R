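#' Initialize market state
#'
#' Local and global food prices start at 40 cents/kg; input prices (wage,
#' necessary inputs, fertilizer, land, working animals, tractor) and credit
#' terms are derived from food price at year 0.
#'
#' @param params parameter list
#' @param policy policy scenario
#' @return list of class `fs_market`
#' @export
init_market <- function(params, policy) {
  M <- list(
    local_price = params$initial_local_price,
    global_price = params$initial_global_price,
    global_trend = params$initial_global_price,
    local_history = params$initial_local_price,
    global_history = params$initial_global_price,
    global_change_pct = 0
  )
  update_input_prices(M, params, policy, year = 0)
}

#' Advance the exogenous global food price
#'
#' The underlying trend declines multiplicatively by a random annual rate
#' drawn Normal(mean = scenario decline rate, sd = rate), truncated to
#' \[-2 x rate, 4 x rate\] (so price rises are possible). An additive sinusoid
#' of amplitude 1.5 cents and period 10 years is superimposed, and a global
#' drought multiplies the realized price by (1 + bump). Price is floored at
#' 1 cent/kg.
#'
#' @param market an `fs_market`
#' @param climate an `fs_climate` (provides year and drought bump)
#' @param params parameter list
#' @return the updated market, with `global_change_pct` the year-on-year
#'   percent change of the global price
#' @export
step_global_price <- function(market, climate, params) {
  rate <- climate$scenario$global_trend_decline
  sd <- rate * params$global_trend_sd_multiple
  d <- if (rate > 0) {
    repeat {
      d <- stats::rnorm(1, rate, sd)
      if (d >= -2 * rate && d <= 4 * rate) break
    }
    d
  } else { stats::rnorm(1, 0, 0); 0 }   # draw kept for stream alignment
  market$global_trend <- market$global_trend * (1 - d)
  osc <- params$oscillator_amplitude *
    sin(2 * pi * climate$year / params$oscillator_period)
  price <- (market$global_trend + osc) * (1 + climate$global_bump)
  price <- max(price, params$price_floor)
  prev <- market$global_price
  market$global_change_pct <- 100 * (price - prev) / prev
  market$global_price <- price
  market$global_history <- c(market$global_history, price)
  market
}

#' Form the local food price
#'
#' The initial aggregate price is the production-weighted average of household
#' asking prices; it is then adjusted for the global price according to the
#' scenario's transmission elasticity: a +5% global change with transmission
#' 0.5 raises the local price by 2.5%.
#'
#' @param asking_prices cents/kg asks of producing households
#' @param productions production weights (kg)
#' @param global_change_pct year-on-year percent change of the global price
#' @param transmission transmission elasticity in \[0, 1\]
#' @param last_price carried forward if total production is zero
#' @return local price, cents/kg
#' @export
form_local_price <- function(asking_prices, productions, global_change_pct,
                             transmission, last_price = NULL) {
  keep <- is.finite(asking_prices) & is.finite(productions) & productions > 0
  if (!any(keep)) {
    if (is.null(last_price)) stop("no producers and no previous price", call. = FALSE)
    return(last_price)
  }
  p0 <- sum(asking_prices[keep] * productions[keep]) / sum(productions[keep])
  p0 * (1 + transmission * global_change_pct / 100)
}

#' Derive input prices and credit terms for the year
#'
#' All input prices are tied to food prices: the low-skilled wage is 180% of
#' the cost of a basic diet at the 5-year mean local price, with an additional
#' 2%/yr drift; necessary inputs cost 15% of a wage per ha at full production;
#' fertilizer costs 10x the current local price per kg (+1%/yr drift, less any
#' policy subsidy); land costs 30 tonnes of cereal per ha; working animals and
#' tractors cost 30 and 150 years of average orphan net income. Interest rates
#' are halved under the entrepreneurial policies; under the eroding policy the
#' subsidy and rate reductions phase out linearly over the run.
#'
#' @param market an `fs_market`
#' @param params parameter list
#' @param policy policy scenario
#' @param year current year (0-based; year 0 uses initial prices)
#' @return the market with `wage`, `necessary_cost_ha`, `fertilizer_price`,
#'   `land_price`, `animal_price`, `tractor_price`, `fertilizer_subsidy` and
#'   `interest` (short/mid/long) set
#' @export
update_input_prices <- function(market, params, policy, year) {
  horizon <- params$years
  p5 <- mean(utils::tail(market$local_history, 5)) / 100   # $/kg
  market$wage <- params$wage_markup * params$basic_diet * p5 *
    (1 + params$wage_drift)^year
  market$necessary_cost_ha <- params$necessary_input_share * market$wage

  subsidy <- policy$fertilizer_subsidy
  if (policy$eroding && subsidy > 0)
    subsidy <- eroded_value(subsidy, 0, year, horizon)
  market$fertilizer_subsidy <- subsidy
  market$fertilizer_price <- params$fertilizer_price_multiple *
    (market$local_price / 100) * (1 + params$fertilizer_drift)^year * (1 - subsidy)

  market$land_price <- params$land_price_tonnes * 1000 * p5

  orphan_net <- (params$base_plot_yield_mean - params$basic_diet -
                   labour_diet_per_fte(params)) * p5
  market$animal_price <- params$animal_price_years * orphan_net
  market$tractor_price <- params$tractor_price_years * orphan_net

  full <- c(short = params$interest_short, mid = params$interest_mid,
            long = params$interest_long)
  rates <- if (policy$interest_halved) {
    if (policy$eroding) {
      vapply(full, function(r) eroded_value(r / 2, r, year, horizon), numeric(1))
    } else full / 2
  } else full
  market$interest <- rates
  market
}

#' Level annuity payment
#'
#' Annual payment amortizing a loan of `principal` at annual rate `rate` over
#' `term` years.
#' @param principal loan principal ($)
#' @param rate annual interest rate (fraction)
#' @param term years
#' @return annual payment ($)
#' @examples
#' annuity_payment(1000, 0.10, 8)  # about 187.44
#' @export
annuity_payment <- function(principal, rate, term) {
  if (any(term < 1)) stop("loan term must be >= 1 year", call. = FALSE)
  ifelse(rate == 0, principal / term,
         principal * rate / (1 - (1 + rate)^(-term)))
}

# empty loan book: parallel vectors
empty_loans <- function() {
  list(hh = integer(0), balance = numeric(0), rate = numeric(0),
       payment = numeric(0), remaining = integer(0))
}

add_loan <- function(loans, hh, principal, rate, term) {
  loans$hh <- c(loans$hh, hh)
  loans$balance <- c(loans$balance, principal)
  loans$rate <- c(loans$rate, rate)
  loans$payment <- c(loans$payment, annuity_payment(principal, rate, term))
  loans$remaining <- c(loans$remaining, as.integer(term))
  loans
}

#' Annual debt service on a loan book
#'
#' Each loan pays its level annuity at its contracted rate; the balance
#' amortizes and fully repaid loans are removed. A single-year loan of $100 at
#' 20% pays $120 and closes.
#'
#' @param loans loan book (internal list of parallel vectors `hh`, `balance`,
#'   `rate`, `payment`, `remaining`)
#' @param n_households number of households (length of the returned due vector)
#' @return list with `due` ($ due per household, a vector), `interest`
#'   (interest portion per household) and the updated `loans`
#' @export
annual_debt_service <- function(loans, n_households) {
  due <- numeric(n_households)
  interest <- numeric(n_households)
  if (length(loans$hh)) {
    int <- loans$balance * loans$rate
    pay <- pmin(loans$payment, loans$balance + int)   # final payment settles exactly
    loans$balance <- loans$balance + int - pay
    loans$remaining <- loans$remaining - 1L
    due <- as.numeric(rowsum_vec(pay, loans$hh, n_households))
    interest <- as.numeric(rowsum_vec(int, loans$hh, n_households))
    keep <- loans$balance > 1e-9 & loans$remaining > 0L
    loans <- lapply(loans, `[`, keep)
  }
  list(due = due, interest = interest, loans = loans)
}

# scheduled payments due next year, per household (for planning)
debt_due_next <- function(loans, n_households) {
  if (!length(loans$hh)) return(numeric(n_households))
  int <- loans$balance * loans$rate
  pay <- pmin(loans$payment, loans$balance + int)
  as.numeric(rowsum_vec(pay, loans$hh, n_households))
}

rowsum_vec <- function(x, group, n) {
  out <- numeric(n)
  s <- rowsum(x, group)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# outstanding balance per household
debt_balance <- function(loans, n_households) {
  if (!length(loans$hh)) return(numeric(n_households))
  as.numeric(rowsum_vec(loans$balance, loans$hh, n_households))
}
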