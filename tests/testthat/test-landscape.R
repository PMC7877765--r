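test_that("the landscape initializes 441 plots with the reference distributions", {
  set.seed(42)
  p <- default_params()
  L <- init_landscape(p)
  n <- length(L$base_max_yield)
  expect_equal(n, 441)
  expect_true(all(L$base_max_yield >= 800 & L$base_max_yield <= 1200))
  # Uniform(800, 1200): mean 1000, SE = (400/sqrt(12))/sqrt(441) ~ 5.5
  expect_lt(abs(mean(L$base_max_yield) - 1000), 3 * 400 / sqrt(12) / sqrt(n))
  expect_true(all(L$agro_multiple >= 2 & L$agro_multiple <= 7))
  # truncated-normal mode near 4
  expect_lt(abs(mean(L$agro_multiple) - 4), 0.3)
  expect_true(all(is.na(L$owner)))
})

test_that("household placement leaves ~40% of plots unoccupied", {
  set.seed(7)
  L <- init_landscape(default_params())
  L <- place_households(L, 250)
  expect_equal(sum(is.na(L$owner)), 441 - 250)
  expect_equal(sum(is.na(L$owner)) / 441, 0.433, tolerance = 0.01)
  expect_equal(sort(unique(L$owner[!is.na(L$owner)])), 1:250)
  expect_error(place_households(init_landscape(
    build_scenario("none", "no", list(grid_side = 3L))$params), 250),
    "more households")
})

test_that("land purchases pick the best contiguous unoccupied plot deterministically", {
  set.seed(1)
  p <- build_scenario("none", "no", list(grid_side = 3L))$params
  L <- init_landscape(p)
  # centre plot (index 5) owned by household 1
  L$owner[5] <- 1L
  pot <- rep(1, 9)
  pot[c(2, 4, 6, 8)] <- c(900, 1100, 1100, 950)
  expect_equal(best_contiguous_plot(L, 1, pot), 4L)  # max, tie broken low index
  pot[4] <- 1000
  expect_equal(best_contiguous_plot(L, 1, pot), 6L)  # unique argmax
  L$owner[c(2, 4, 6, 8)] <- 9L                       # enclosed farm
  expect_true(is.na(best_contiguous_plot(L, 1, pot)))
  # diagonal neighbours never qualify (4-neighbour adjacency)
  L2 <- init_landscape(p)
  L2$owner[5] <- 1L
  L2$owner[c(2, 4, 6, 8)] <- 2L
  expect_true(is.na(best_contiguous_plot(L2, 1, rep(1, 9))))
})

test_that("agroecology transitions interpolate to the full multiple and cap", {
  p <- default_params()
  L <- init_landscape(p)
  L$base_max_yield[1] <- 1000
  L$agro_multiple[1] <- 4
  L$base_max_yield[2] <- 2000
  L$agro_multiple[2] <- 7
  L$transition_progress[1:2] <- 0L
  agro_full <- pmin(p$plot_yield_cap, L$base_max_yield * L$agro_multiple)
  cur <- numeric(0)
  for (k in 1:3) {
    L <- advance_transitions(L, p, agro_full)
    cur <- c(cur, L$current_max_yield[1])
  }
  expect_equal(cur, c(2000, 3000, 4000))   # linear rise from 1000 to 4000
  expect_true(L$transitioned[1])
  expect_equal(L$transition_progress[1], 3L)
  expect_equal(L$current_max_yield[2], 10000)   # 14000 capped
})

test_that("slow yield increments follow the policy profile and cap", {
  p <- default_params()
  L <- init_landscape(p)
  L$current_max_yield[1:3] <- c(1000, 4000, 10000)
  L2 <- apply_yield_increments(L, orphan_idx = 1, agro_idx = 2:3,
                               policy = policy_scenario("peasant"), params = p)
  expect_equal(L2$current_max_yield[1:3], c(1015, 4120, 10000))
  L3 <- apply_yield_increments(L, orphan_idx = 1, agro_idx = 2:3,
                               policy = policy_scenario("none"), params = p)
  expect_equal(L3$current_max_yield[1:3], c(1010, 4060, 10000))
  expect_equal(L2$base_max_yield, L$base_max_yield)   # base never changes
})

test_that("plot count and base yields are immutable over a full simulation", {
  cfg <- build_scenario("peasant", "high")
  res <- run_simulation(cfg, seed = 5, years = 12)
  w <- attr(res, "world")
  set.seed(5)
  L0 <- place_households(init_landscape(cfg$params), cfg$params$n_households)
  expect_equal(w$landscape$base_max_yield, L0$base_max_yield)
  expect_equal(w$landscape$agro_multiple, L0$agro_multiple)
  expect_equal(length(w$landscape$owner), 441)
  # no plot has two owners by construction; ownership ids are valid
  ow <- w$landscape$owner
  expect_true(all(is.na(ow) | (ow >= 1 & ow <= 250)))
})
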