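test_that("year-0 input prices follow the food-price formulas", {
  p <- default_params()
  M <- init_market(p, policy_scenario("none"))
  expect_equal(M$wage, 1.8 * 700 * 0.40)                # $504
  expect_equal(M$necessary_cost_ha, 0.15 * 504)         # $75.60
  expect_equal(M$land_price, 30000 * 0.40)              # $12,000/ha
  expect_equal(M$fertilizer_price, 10 * 0.40)           # $4.00/kg, no subsidy
  expect_equal(unname(M$interest), c(0.20, 0.15, 0.10))

  Ms <- init_market(p, policy_scenario("entrepreneurial"))
  expect_equal(Ms$fertilizer_price, 2.00)               # 50% subsidy
  expect_equal(unname(Ms$interest), c(0.10, 0.075, 0.05))

  # asset prices: 30 and 150 years of average orphan net income (~190 kg x price)
  orphan_net <- (1000 - 700 - labour_diet_per_fte(p)) * 0.40
  expect_equal(M$animal_price, 30 * orphan_net)
  expect_equal(M$tractor_price, 150 * orphan_net)
  expect_lt(abs(orphan_net - 80), 8)   # the reference "about $80 per year"
})

test_that("eroding policy support returns linearly to baseline over the run", {
  p <- default_params()
  pol <- policy_scenario("entrepreneurial_eroding")
  M <- init_market(p, pol)
  M25 <- update_input_prices(M, p, pol, year = 25)
  expect_equal(M25$fertilizer_subsidy, 0.25)
  expect_equal(unname(M25$interest), c(0.15, 0.1125, 0.075))
  M50 <- update_input_prices(M, p, pol, year = 50)
  expect_equal(M50$fertilizer_subsidy, 0)
  expect_equal(unname(M50$interest), c(0.20, 0.15, 0.10))
})

test_that("local price formation matches the transmission worked example", {
  # +5% global change at transmission 0.5 raises the local price by exactly 2.5%
  expect_equal(form_local_price(40, 1000, 5, 0.5), 40 * 1.025)
  expect_equal(form_local_price(c(40, 60), c(100, 300), 0, 0.5), 55)
  expect_equal(form_local_price(c(40, 60), c(100, 300), 8, 0), 55)
  expect_equal(form_local_price(numeric(0), numeric(0), 5, 0.5, last_price = 33), 33)
  expect_error(form_local_price(numeric(0), numeric(0), 5, 0.5), "no producers")
})

test_that("loan annuities amortize at the contracted rate", {
  expect_equal(annuity_payment(100, 0.20, 1), 120)
  expect_equal(annuity_payment(1000, 0.10, 8), 1000 * 0.1 / (1 - 1.1^-8))
  expect_equal(annuity_payment(1000, 0.10, 8), 187.44, tolerance = 1e-4)

  loans <- farmstyles:::add_loan(farmstyles:::empty_loans(), hh = 3L,
                                 principal = 100, rate = 0.20, term = 1)
  svc <- annual_debt_service(loans, n_households = 5)
  expect_equal(svc$due, c(0, 0, 120, 0, 0))
  expect_equal(svc$interest[3], 20)
  expect_equal(length(svc$loans$hh), 0)   # fully repaid, removed

  # an 8-year loan pays the level annuity each year and ends at zero balance
  loans <- farmstyles:::add_loan(farmstyles:::empty_loans(), 1L, 1000, 0.10, 8)
  total <- 0
  for (k in 1:8) {
    svc <- annual_debt_service(loans, 1)
    total <- total + svc$due[1]
    loans <- svc$loans
  }
  expect_equal(length(loans$hh), 0)
  expect_equal(total, 8 * annuity_payment(1000, 0.10, 8), tolerance = 1e-9)
  expect_equal(annual_debt_service(farmstyles:::empty_loans(), 4)$due, rep(0, 4))
})

test_that("the global price trends down, oscillates, and responds to drought", {
  p <- default_params()
  # deterministic trend: sd off, no drought
  cfgp <- build_scenario("none", "no",
                         list(global_trend_sd_multiple = 0, drought_risk_base = 0))$params
  M <- init_market(cfgp, policy_scenario("none"))
  cl <- init_climate(climate_scenario("no"), cfgp)
  set.seed(2)
  for (k in 1:10) {
    cl <- step_climate(cl, cfgp)
    M <- step_global_price(M, cl, cfgp)
    expected <- 40 * 0.985^k + 1.5 * sin(2 * pi * k / 10)
    expect_equal(M$global_price, expected, tolerance = 1e-9)
  }
  # a drought year multiplies the price by (1 + bump)
  cl$global_drought <- TRUE
  cl$global_bump <- 0.10
  cl$year <- cl$year + 1L
  M2 <- step_global_price(M, cl, cfgp)
  base <- 40 * 0.985^11 + 1.5 * sin(2 * pi * 11 / 10)
  expect_equal(M2$global_price, base * 1.10, tolerance = 1e-9)

  # decline 1.5 vs 1.0 %/yr: year-50 mean under no-CC is below high-CC
  mean_at_50 <- function(nm, seeds) {
    vapply(seeds, function(s) {
      set.seed(s)
      pp <- build_scenario("none", nm, list(drought_risk_base = 0))$params
      M <- init_market(pp, policy_scenario("none"))
      cl <- init_climate(climate_scenario(nm), pp)
      for (k in 1:50) {
        cl <- step_climate(cl, pp)
        M <- step_global_price(M, cl, pp)
      }
      M$global_price
    }, numeric(1))
  }
  expect_lt(mean(mean_at_50("no", 1:100)), mean(mean_at_50("high", 1:100)))
})

test_that("wage and land prices track the five-year mean local price", {
  p <- default_params()
  M <- init_market(p, policy_scenario("none"))
  M$local_history <- c(40, 50, 60, 50, 40, 50)   # last five mean = 50
  M$local_price <- 50
  M2 <- update_input_prices(M, p, policy_scenario("none"), year = 0)
  expect_equal(M2$wage, 1.8 * 700 * 0.50)
  expect_equal(M2$land_price, 30000 * 0.50)
  # wage drift compounds at 2%/yr on top of the food-price link
  M3 <- update_input_prices(M, p, policy_scenario("none"), year = 10)
  expect_equal(M3$wage, 1.8 * 700 * 0.50 * 1.02^10)
})
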