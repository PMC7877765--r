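# shared scenario builders for the test suite

# all stochastic elements off: fixed prices, no climate events, no drift
quiet_overrides <- function(...) {
  c(list(
    yield_noise_halfwidth = 0,
    expectation_noise_halfwidth = 0,
    drought_risk_base = 0,
    wage_drift = 0,
    fertilizer_drift = 0,
    global_trend_sd_multiple = 0,
    global_trend_decline = 0,
    oscillator_amplitude = 0,
    spend_fraction = 0
  ), list(...))
}

# a solitary orphan household in an otherwise frozen world
solitary_orphan_config <- function(...) {
  build_scenario("none", "no", quiet_overrides(n_households = 1L, ...))
}

# brute-force Gini oracle: explicit double loop over all pairs
gini_bruteforce <- function(x) {
  if (any(x < 0)) x <- x - min(x)
  n <- length(x)
  if (mean(x) == 0) return(0)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + abs(x[i] - x[j])
  s / (2 * n^2 * mean(x))
}

# closed-form OLS slope oracle
slope_bruteforce <- function(y) {
  t <- seq_along(y)
  unname(stats::coef(stats::lm(y ~ t))[2])
}
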