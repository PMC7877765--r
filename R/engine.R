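#' Initialize a simulation world
#'
#' Builds the landscape, places the households, and initializes climate and
#' market state for a resolved scenario configuration. Consumes random draws
#' from the current RNG stream; use [run_simulation()] for seeded runs.
#'
#' @param config an `fs_config` from [build_scenario()]
#' @return list of class `fs_world`
#' @export
init_world <- function(config) {
  params <- config$params
  L <- init_landscape(params)
  L <- place_households(L, params$n_households)
  H <- init_households(params, config$policy, L)
  M <- init_market(params, config$policy)
  C <- init_climate(config$climate, params)
  cap <- params$plot_yield_cap
  agro_full <- if (!is.null(config$sens)) {
    pmin(cap, config$sens$yield_ratio * params$fertilizer_max_multiple * L$base_max_yield)
  } else {
    pmin(cap, L$base_max_yield * L$agro_multiple)
  }
  w <- list(
    config = config, params = params, policy = config$policy,
    sens = config$sens, year = 0L,
    landscape = L, households = H, market = M, climate = C,
    loans = empty_loans(), agro_full = agro_full,
    out = NULL, style_income = NULL
  )
  class(w) <- c("fs_world", "list")
  w
}

# deactivate a household's plots on abandonment: the land leaves production
free_plots <- function(L, ids) {
  idx <- which(!is.na(L$owner) & L$owner %in% ids)
  if (length(idx)) {
    L$owner[idx] <- NA_integer_
    L$retired[idx] <- TRUE
    L$transitioned[idx] <- FALSE
    L$transition_progress[idx] <- NA_integer_
    L$current_max_yield[idx] <- L$base_max_yield[idx]
  }
  L
}

# reset one plot to unoccupied base state
reset_plot <- function(L, j) {
  L$owner[j] <- NA_integer_
  L$transitioned[j] <- FALSE
  L$transition_progress[j] <- NA_integer_
  L$current_max_yield[j] <- L$base_max_yield[j]
  L
}

#' Advance the world by one year
#'
#' Executes the annual cycle in order: climate step, global price step, orphan
#' conversions, entrepreneurial solvency check, farm expansions, price
#' expectations and style-specific production optimization, pre-production
#' rationing, production realization, asking prices and local price formation,
#' accounting with distress handling (asset sales, abandonment), slow yield
#' increments, agroecology transition progress, and the annual outcome
#' snapshot.
#'
#' @param world an `fs_world`
#' @return the advanced world
#' @export
step_year <- function(world) {
  params <- world$params
  policy <- world$policy
  sens <- world$sens
  L <- world$landscape
  H <- world$households
  M <- world$market
  loans <- world$loans
  n <- params$n_households
  t <- world$year + 1L
  basic <- params$basic_diet
  fam <- params$family_workers
  ld_fte <- labour_diet_per_fte(params)

  agro_ws <- if (!is.null(sens)) sens$agro_climate else 1 - params$agro_warming_loss_reduction
  agro_ds <- if (!is.null(sens)) sens$agro_climate else 1 - params$agro_drought_loss_reduction

  ## 1-3: climate, global price, input prices -------------------------------
  C <- step_climate(world$climate, params, horizon = params$years)
  M <- step_global_price(M, C, params)
  M <- update_input_prices(M, params, policy, year = t)
  p_cur <- M$local_price / 100

  ## 4: conversions ----------------------------------------------------------
  orphan <- H$active & H$style == "orphan"
  trans_cost <- params$agro_transition_years *
    (ld_fte * p_cur + (1 - params$orphan_input_share) * M$necessary_cost_ha)
  conv_a <- orphan & H$pref == "agroecology" & H$savings >= trans_cost
  if (any(conv_a)) {
    H$savings[conv_a] <- H$savings[conv_a] - trans_cost
    H$style[conv_a] <- "agroecology"
    H$last_land_year[conv_a] <- t
    idx <- which(!is.na(L$owner) & L$owner %in% H$id[conv_a])
    L$transition_progress[idx] <- 0L
  }
  conv_e <- orphan & H$pref == "entrepreneurial" &
    (H$net_income + H$savings) >= M$wage
  if (any(conv_e)) {
    H$style[conv_e] <- "entrepreneurial"
    H$converted_year[conv_e] <- t
    idx <- which(!is.na(L$owner) & L$owner %in% H$id[conv_e])
    L$current_max_yield[idx] <- L$base_max_yield[idx]   # fertilizer becomes the yield channel
  }

  ## 5: entrepreneurial solvency pre-check ----------------------------------
  due_plan <- debt_due_next(loans, n)
  entre <- H$active & H$style == "entrepreneurial"
  # net income is already diet-net, so resources include half the diet back
  shaky <- which(entre & (H$savings + H$net_income + 0.5 * basic * p_cur) < due_plan)
  for (i in shaky) {
    need <- due_plan[i] - 0.5 * basic * p_cur - H$net_income[i]
    res <- sell_assets_until(L, H, M, i, H$savings[i], need)
    L <- res$L; H <- res$H; H$savings[i] <- res$cash
    if (H$savings[i] < need) {
      H$active[i] <- FALSE
      H$abandoned_year[i] <- t
      H$diet_frac[i] <- 0
      L <- free_plots(L, i)
      keep <- loans$hh != i
      loans <- lapply(loans, `[`, keep)
    }
  }

  ## 6: expansions -----------------------------------------------------------
  order <- sample.int(n)   # annual shuffle (fixed-length draw)
  own0 <- which(!is.na(L$owner))
  area_now <- tabulate(L$owner[own0], n)
  mine_list <- vector("list", n)
  mine_list[sort(unique(L$owner[own0]))] <- split(own0, L$owner[own0])
  entre_pot <- params$fertilizer_max_multiple * L$base_max_yield
  developed <- H$active & H$style != "orphan"
  sv <- H$savings; tm <- H$teams; trc <- H$tractors
  niv <- H$net_income; lly <- H$last_land_year; cyv <- H$converted_year
  is_agro_hh <- H$style == "agroecology"
  for (i in order[developed[order]]) {
    if (is_agro_hh[i]) {
      mine <- mine_list[[i]]
      if (!length(mine) || !all(L$transitioned[mine])) next
      area <- length(mine)
      teams_used <- min(tm[i], fam)
      cap_ha <- params$animal_capacity_ha * teams_used + (fam - teams_used)
      if (area >= cap_ha && tm[i] < params$agro_max_animal_teams &&
          sv[i] >= M$animal_price) {
        tm[i] <- tm[i] + 1L
        sv[i] <- sv[i] - M$animal_price
      } else if (area < params$agro_max_ha &&
                 (t - lly[i]) >= params$agro_expansion_min_years_per_ha &&
                 sv[i] >= M$land_price + trans_cost) {
        j <- best_contiguous_plot(L, i, world$agro_full, owned = mine)
        if (!is.na(j)) {
          sv[i] <- sv[i] - M$land_price - trans_cost
          L$owner[j] <- i
          L$transition_progress[j] <- 0L
          lly[i] <- t
          mine_list[[i]] <- c(mine, j)
        }
      }
    } else if (is.na(cyv[i]) || cyv[i] < t) {
      resources <- niv[i] + sv[i]
      if (resources >= 0.5 * M$land_price) {
        j <- best_contiguous_plot(L, i, entre_pot, owned = mine_list[[i]])
        if (!is.na(j)) {
          cash_pay <- min(sv[i], M$land_price)
          fin <- M$land_price - cash_pay
          sv[i] <- sv[i] - cash_pay
          if (fin > 0)
            loans <- add_loan(loans, i, fin, M$interest[["long"]], params$loan_term_long)
          L$owner[j] <- i
          L$current_max_yield[j] <- L$base_max_yield[j]
          area_now[i] <- area_now[i] + 1L
          mine_list[[i]] <- c(mine_list[[i]], j)
        }
      }
      mech_cap <- params$tractor_capacity_ha * trc[i] +
        params$animal_capacity_ha * tm[i]
      if (area_now[i] > mech_cap) {
        if (area_now[i] >= 8 && resources >= 0.5 * M$tractor_price) {
          cash_pay <- min(sv[i], M$tractor_price)
          sv[i] <- sv[i] - cash_pay
          fin <- M$tractor_price - cash_pay
          if (fin > 0)
            loans <- add_loan(loans, i, fin, M$interest[["mid"]], params$loan_term_mid)
          trc[i] <- trc[i] + 1L
        } else if (area_now[i] >= 3 && resources >= 0.5 * M$animal_price) {
          cash_pay <- min(sv[i], M$animal_price)
          sv[i] <- sv[i] - cash_pay
          fin <- M$animal_price - cash_pay
          if (fin > 0)
            loans <- add_loan(loans, i, fin, M$interest[["mid"]], params$loan_term_mid)
          tm[i] <- tm[i] + 1L
        }
      }
    }
  }
  H$savings <- sv; H$teams <- tm; H$tractors <- trc; H$last_land_year <- lly

  ## 7: expectations and optimization ---------------------------------------
  hw <- params$expectation_noise_halfwidth
  e_noise <- stats::runif(n, 1 - hw, 1 + hw)
  p_exp <- expected_price(M$local_history, e_noise, floor = params$price_floor)
  p <- p_exp / 100

  own <- !is.na(L$owner)
  area <- tabulate(L$owner[own], n)
  ow1 <- L$owner
  ow1[!own] <- 1L
  is_entre_plot <- own & H$style[ow1] == "entrepreneurial"
  pot <- L$current_max_yield
  pot[is_entre_plot] <- params$fertilizer_max_multiple *
    L$base_max_yield[is_entre_plot]
  plot_sum <- rowsum_vec(pot[own], L$owner[own], n)
  n_trans <- rowsum_vec(as.numeric(L$transitioned[own]), L$owner[own], n)

  att <- attainable_max(area, plot_sum, H$style, H$teams, H$tractors, params)
  A <- att$A
  A[!H$active] <- 0
  fte_full <- att$fte_full
  peasant <- H$style != "entrepreneurial"
  entre_hh <- !peasant
  intensity <- rep(1, n)
  agw <- H$style == "agroecology" & area > 0
  intensity[agw] <- 1 + n_trans[agw] / area[agw]

  # orphan farming uses very limited purchased inputs (half the developed-farm
  # rate); developed farming pays the base rate, transitioned agroecology
  # double (in proportion to labour)
  nec_int <- intensity
  nec_int[H$style == "orphan"] <- params$orphan_input_share
  nec_full <- params$necessary_input_share * M$wage * area * nec_int
  ld_full <- ld_fte * fte_full * intensity
  ld_full[entre_hh] <- 0
  fert_full_cost <- numeric(n)
  fert_full_cost[entre_hh] <- params$fertilizer_max_kg * area[entre_hh] *
    M$fertilizer_price
  wage_full <- numeric(n)
  wage_full[entre_hh] <- fte_full[entre_hh] * M$wage
  debt_due <- debt_due_next(loans, n)
  assets_val <- H$teams * M$animal_price + H$tractors * M$tractor_price +
    area * M$land_price

  # expected climate-related losses enter the revenue side of planning:
  # warming at this year's level plus the drought risk-weighted mean loss
  wf_exp <- warming_loss_factor(C$warming, H$style, params, agro_sensitivity = agro_ws)
  d_style <- ifelse(H$style == "agroecology", agro_ds, 1)
  exp_clim <- wf_exp * (1 - C$local_drought_risk *
                          C$scenario$local_drought_loss_mean * d_style)

  nq <- 101L
  Q <- seq(0, 1, length.out = nq)
  Q2 <- Q^2
  qcols <- seq_len(nq)
  a1 <- A * p * exp_clim

  col_opt <- integer(n)
  pe <- which(peasant & H$active & area > 0)
  en <- which(!peasant & H$active & area > 0)
  # peasant objective: returns to labour (labour time not costed; labour diet in kind)
  if (length(pe)) {
    objP <- a1[pe] %o% Q - (nec_full[pe] + ld_full[pe] * p[pe]) %o% Q2
    col_opt[pe] <- max.col(objP, "first")
  }
  # entrepreneurial: return on investment; family diet + debt are the fixed stake
  if (length(en)) {
    d_fix <- debt_due[en] + basic * p[en]
    value <- a1[en] %o% Q
    cvar <- (nec_full[en] + fert_full_cost[en] + wage_full[en]) %o% Q2
    profit <- value - cvar - d_fix
    roi <- value / (cvar + d_fix)
    col_roi <- max.col(roi, "first")
    col_pi <- max.col(profit, "first")
    pr_at_roi <- profit[cbind(seq_along(en), col_roi)]
    goal <- params$entre_expansion_income_share * assets_val[en]
    colv <- col_roi
    loss <- pr_at_roi < 0
    colv[loss] <- col_pi[loss]
    low <- which(!loss & pr_at_roi < goal)
    if (length(low)) {
      cix <- matrix(qcols, length(low), nq, byrow = TRUE)
      mask <- profit[low, , drop = FALSE] >= goal[low] & cix >= col_roi[low]
      hit <- rowSums(mask) > 0
      first <- max.col(mask, "first")
      # expansion-driven: if the income goal is out of reach, produce at the
      # largest scale that remains viable (non-negative expected profit)
      mask0 <- profit[low, , drop = FALSE] >= 0
      last0 <- max.col(mask0 * cix, "first")
      any0 <- rowSums(mask0) > 0
      colv[low][hit] <- first[hit]
      colv[low][!hit & any0] <- pmax(last0[!hit & any0], col_roi[low][!hit & any0])
      colv[low][!hit & !any0] <- col_pi[low][!hit & !any0]
    }
    col_opt[en] <- colv
  }
  # peasant autonomy goal: raise net income per hectare, escalating if needed
  if (length(pe)) {
    G <- H$last_niha[pe] * pmax(area[pe], 1) + basic * p[pe]
    at <- objP[cbind(seq_along(pe), col_opt[pe])]
    unmet <- which(at <= G)
    if (length(unmet)) {
      cix <- matrix(qcols, length(unmet), nq, byrow = TRUE)
      mask <- objP[unmet, , drop = FALSE] > G[unmet] & cix >= col_opt[pe][unmet]
      hit <- rowSums(mask) > 0
      first <- max.col(mask, "first")
      newcol <- ifelse(hit, first, nq)
      col_opt[pe][unmet] <- pmax(col_opt[pe][unmet], newcol)
    }
  }
  col_pre <- col_opt

  ## 8: pre-production rationing (peasants: cash feasibility) ----------------
  rationed <- rep(FALSE, n)
  if (length(pe)) {
    qsel <- Q[col_pre[pe]]
    cash_at <- H$savings[pe] - basic * p[pe] + a1[pe] * qsel -
      (ld_full[pe] * p[pe] + nec_full[pe]) * qsel^2
    bad <- which(cash_at < 0)
    for (k in bad) {
      i <- pe[k]
      cashv <- H$savings[i] - basic * p[i] + a1[i] * Q -
        (ld_full[i] * p[i] + nec_full[i]) * Q2
      cash05v <- cashv + (1 - params$abandonment_diet_fraction) * basic * p[i]
      if (H$ration_pref[i] == "nutrition") {
        feas <- which(cashv >= 0 & qcols <= col_pre[i])
        if (length(feas)) {
          col_opt[i] <- max(feas)
        } else {
          feas05 <- which(cash05v >= 0 & qcols <= col_pre[i])
          col_opt[i] <- if (length(feas05)) max(feas05) else which.max(cash05v)
        }
      } else {
        if (cash05v[col_pre[i]] < 0) {
          feas05 <- which(cash05v >= 0 & qcols <= col_pre[i])
          col_opt[i] <- if (length(feas05)) max(feas05) else which.max(cash05v)
        }
      }
      # any pre-production shortfall means resources were rationed between
      # consumption and production, whichever margin gave way
      rationed[i] <- TRUE
    }
  }

  q <- (col_opt - 1) / (nq - 1)
  q[!H$active | area == 0] <- 0
  x <- q^2
  fte_q <- x * fte_full
  ld_q <- x * ld_full
  nec_q <- x * nec_full
  fert_cost_q <- x * fert_full_cost
  hired <- ifelse(peasant, 0, pmax(0, fte_q - fam))
  hired_cost <- hired * M$wage
  target <- q * A

  ## 9: production realization ------------------------------------------------
  wf <- wf_exp
  dnz <- stats::runif(n, 0.75, 1.25)
  df <- drought_loss_factor(C$community_loss, H$style, dnz, params,
                            loss_max = C$scenario$local_drought_loss_max,
                            agro_sensitivity = agro_ds)
  yh <- params$yield_noise_halfwidth
  ynz <- stats::runif(n, 1 - yh, 1 + yh)
  Y <- realize_production(target, wf, df, ynz)

  ## 10: asking prices and local price ---------------------------------------
  # asks: a common damped-expectation anchor plus style-specific floors.
  # Peasants will not sell below cash-cost recovery on their marketed surplus
  # (autonomy: the next production cycle must be financed without the market);
  # entrepreneurs, pursuing expansion and market share, undersell the anchor
  # slightly but hold a return-on-investment floor over unit cash cost.
  avail <- pmax(0, Y - ld_q)
  marketable <- ifelse(peasant, pmax(0, avail - basic), Y)
  k <- length(M$local_history)
  span <- min(5, k - 1)
  trend <- if (span >= 1) (M$local_price - M$local_history[k - span]) / span else 0
  anchor <- max(params$price_floor, M$local_price + 0.5 * trend)
  cash_cost <- ifelse(peasant, nec_q, nec_q + fert_cost_q + hired_cost)
  ask_floor <- ifelse(peasant,
                      ifelse(marketable > basic, 100 * nec_q / pmax(marketable, 1), 0),
                      100 * params$entre_ask_markup * cash_cost / pmax(Y, 1))
  style_anchor <- anchor * ifelse(peasant, 1, params$entre_ask_discount)
  ask <- pmin(pmax(ask_floor, style_anchor), 3 * anchor)
  contrib <- H$active & marketable > 0 & Y > 0
  new_local <- form_local_price(ask[contrib], marketable[contrib], M$global_change_pct,
                                policy$transmission, last_price = M$local_price)
  M$local_price <- new_local
  M$local_history <- c(M$local_history, new_local)
  pr <- new_local / 100

  ## 11: settlement, distress, abandonment ------------------------------------
  svc <- annual_debt_service(loans, n)
  loans <- svc$loans
  old_savings <- H$savings
  nec_paid <- nec_q
  diet <- numeric(n)
  cash <- numeric(n)
  revenue <- numeric(n)
  food_spent <- numeric(n)
  fail <- rep(FALSE, n)

  ld_cons <- pmin(Y, ld_q)
  availr <- Y - ld_cons
  # committed inputs claim harvest revenue before family consumption; a
  # household whose remaining diet falls below half the basic diet gives up
  shortfall_kg <- pmax(0, nec_q - H$savings) / pr
  must_sell <- pmin(shortfall_kg, availr)
  fam_own <- pmin(pmax(availr - must_sell, 0), basic)
  marketed <- availr - fam_own

  pw <- which(H$active & peasant)
  if (length(pw)) {
    revenue[pw] <- marketed[pw] * pr
    cash[pw] <- H$savings[pw] + revenue[pw] - nec_q[pw]
    for (i in pw[cash[pw] < 0]) {
      res <- sell_assets_until(L, H, M, i, cash[i], 0)
      L <- res$L; H <- res$H; cash[i] <- res$cash
      if (cash[i] < 0) {              # inputs partly unaffordable: scale back
        nec_paid[i] <- nec_q[i] + cash[i]
        cash[i] <- 0
        fail[i] <- TRUE
      }
    }
    buy <- pmin(pmax(basic - fam_own[pw], 0), pmax(cash[pw], 0) / pr)
    cash[pw] <- cash[pw] - buy * pr
    food_spent[pw] <- buy * pr
    diet[pw] <- (fam_own[pw] + buy) / basic
    short <- pw[diet[pw] < params$abandonment_diet_fraction]
    for (i in short) {   # last resort: liquidate assets to buy food
      need <- pmax(basic - (diet[i] * basic), 0) * pr
      res <- sell_assets_until(L, H, M, i, cash[i], need)
      L <- res$L; H <- res$H; cash[i] <- res$cash
      extra <- min(pmax(basic * (1 - diet[i]), 0), pmax(cash[i], 0) / pr)
      cash[i] <- cash[i] - extra * pr
      food_spent[i] <- food_spent[i] + extra * pr
      diet[i] <- diet[i] + extra / basic
    }
  }

  ew <- which(H$active & !peasant)
  if (length(ew)) {
    revenue[ew] <- Y[ew] * pr
    outflow <- nec_q[ew] + fert_cost_q[ew] + hired_cost[ew] + svc$due[ew] + basic * pr
    cash[ew] <- H$savings[ew] + revenue[ew] - outflow
    diet[ew] <- 1
    food_spent[ew] <- basic * pr
    for (k in seq_along(ew)) {
      i <- ew[k]
      if (cash[i] >= 0) next
      st <- min(-cash[i], fert_cost_q[i])      # bridge fertilizer bill with short credit
      if (st > 0) {
        loans <- add_loan(loans, i, st, M$interest[["short"]], params$loan_term_short)
        cash[i] <- cash[i] + st
      }
      if (cash[i] < 0) {
        res <- sell_assets_until(L, H, M, i, cash[i], 0)
        L <- res$L; H <- res$H; cash[i] <- res$cash
      }
      if (cash[i] < 0) {
        release <- min(-cash[i], (1 - params$abandonment_diet_fraction) * basic * pr)
        cash[i] <- cash[i] + release
        diet[i] <- 1 - release / (basic * pr)
        food_spent[i] <- food_spent[i] - release
        fail[i] <- TRUE
      }
    }
  }

  # abandonment: below half a basic diet, or debts that cannot be met
  give_up <- H$active & (diet < params$abandonment_diet_fraction | cash < -1e-9)
  if (any(give_up)) {
    ids <- H$id[give_up]
    H$active[give_up] <- FALSE
    H$abandoned_year[give_up] <- t
    L <- free_plots(L, ids)
    keep <- !(loans$hh %in% ids)
    loans <- lapply(loans, `[`, keep)
    cash[give_up] <- 0
  }

  cash <- pmax(cash, 0)
  gain <- pmax(0, cash - old_savings)
  spendy <- H$save_style == "spend"
  cash[spendy] <- cash[spendy] - params$spend_fraction * gain[spendy]
  H$savings <- cash

  # net income: income after production costs and after feeding the family
  # and its workers (the paper's orphan benchmark: ~190 kg surplus x price)
  gv <- Y * pr
  purch <- nec_paid
  purch[entre_hh] <- nec_paid[entre_hh] + fert_cost_q[entre_hh]
  ni <- revenue - nec_paid - food_spent
  ni[entre_hh] <- (gv - nec_paid - fert_cost_q - hired_cost - svc$interest -
                     food_spent)[entre_hh]
  live <- H$active
  dead <- !live
  Y[dead] <- 0; gv[dead] <- 0; purch[dead] <- 0; ni[dead] <- 0
  H$last_production <- Y
  H$gross_value <- gv
  H$purch_inputs <- purch
  H$net_income <- ni
  ok <- live & area > 0
  H$last_niha[ok] <- ni[ok] / area[ok]
  diet <- pmin(diet, 1)
  diet[dead] <- 0
  H$diet_frac <- diet
  # realized labour: peasant farms supply the intensified labour themselves
  # (agroecology doubles labour per ha), capped by the two family workers;
  # entrepreneurial labour counts family plus hired workers
  fte_metric <- pmin(fam, fte_q * intensity)
  fte_metric[entre_hh] <- fte_q[entre_hh]
  fte_metric[dead] <- 0
  H$fte_used <- fte_metric
  hired[dead] <- 0
  H$hired_fte <- hired
  # a farm counts as having optimized only if it could plan without rationing
  # AND realized its target up to ordinary yield variation: climate shortfalls
  # block the slow fine-tuning gains
  H$optimized <- live & !rationed & !fail & q > 0 &
    Y >= (1 - params$yield_noise_halfwidth) * target

  ## 12: slow yield increments ------------------------------------------------
  own <- !is.na(L$owner)
  owner_ok <- own
  oidx <- which(owner_ok)
  ow <- L$owner[oidx]
  opt <- H$optimized[ow]
  orphan_pl <- oidx[opt & H$style[ow] == "orphan"]
  agro_pl <- if (is.null(sens))
    oidx[opt & H$style[ow] == "agroecology" & L$transitioned[oidx]] else integer(0)
  L <- apply_yield_increments(L, orphan_pl, agro_pl, policy, params)

  ## 13: transition progress ---------------------------------------------------
  L <- advance_transitions(L, params, world$agro_full)
  agro_hh <- which(H$active & H$style == "agroecology" & is.na(H$converted_year))
  for (i in agro_hh) {
    mine <- which(!is.na(L$owner) & L$owner == i)
    if (length(mine) && all(L$transitioned[mine])) H$converted_year[i] <- t
  }

  ## 14: snapshot ---------------------------------------------------------------
  act <- H$active
  tot <- sum(Y[act])
  is_orph <- act & H$style == "orphan"
  sty_mean <- function(s) {
    sel <- act & H$style == s
    if (any(sel)) mean(H$net_income[sel]) else NA_real_
  }
  rlp <- real_land_productivity(H$net_income[act], area[act],
                                H$gross_value[act], H$purch_inputs[act])
  row <- c(
    year = t,
    total_production_t = tot / 1000,
    local_price = M$local_price,
    global_price = M$global_price,
    n_converted = sum(!is.na(H$converted_year)),
    n_abandoned = sum(!H$active),
    orphan_nutrition = orphan_nutrition(H$diet_frac, is_orph),
    labour_fte = sum(H$fte_used[act]),
    income_gini = gini(H$net_income[act]),
    mean_net_income = if (any(act)) mean(H$net_income[act]) else NA_real_,
    income_orphan = sty_mean("orphan"),
    income_agro = sty_mean("agroecology"),
    income_entre = sty_mean("entrepreneurial"),
    mean_rlp = if (any(act)) mean(rlp) else NA_real_,
    households_feedable = households_feedable(tot, basic),
    warming = C$warming,
    local_drought = as.numeric(C$local_drought),
    community_loss = C$community_loss,
    wage = M$wage,
    fertilizer_price = M$fertilizer_price,
    land_price = M$land_price,
    n_orphan = sum(is_orph),
    n_agro = sum(act & H$style == "agroecology"),
    n_entre = sum(act & H$style == "entrepreneurial")
  )
  world$out <- rbind(world$out, row)
  world$year <- t
  world$landscape <- L
  world$households <- H
  world$market <- M
  world$climate <- C
  world$loans <- loans
  world
}

# sell animals, tractor, then land (keeping the home plot), until `cash`
# reaches `need`; assets sell at current market prices
sell_assets_until <- function(L, H, M, i, cash, need) {
  while (cash < need && H$teams[i] > 0) {
    H$teams[i] <- H$teams[i] - 1L
    cash <- cash + M$animal_price
  }
  while (cash < need && H$tractors[i] > 0) {
    H$tractors[i] <- H$tractors[i] - 1L
    cash <- cash + M$tractor_price
  }
  if (cash < need) {
    mine <- which(!is.na(L$owner) & L$owner == i)
    while (cash < need && length(mine) > 1) {
      k <- which.min(L$current_max_yield[mine])
      L <- reset_plot(L, mine[k])
      mine <- mine[-k]
      cash <- cash + M$land_price
    }
  }
  list(L = L, H = H, cash = cash)
}

#' Run a single simulation
#'
#' Deterministic given `(config, seed)`: the seed initializes the run's RNG
#' stream and identical calls reproduce identical outputs.
#'
#' @param config an `fs_config` from [build_scenario()]
#' @param seed integer seed for the run
#' @param years horizon override (default from the configuration)
#' @return a data.frame of per-year tracked outcomes (class `fs_run`), with
#'   the trailing 5-year mean net income and trailing 10-year income slopes by
#'   style appended, and the final world attached as attribute `"world"`
#' @export
run_simulation <- function(config, seed = 1L, years = NULL) {
  if (!is.null(years)) config$params$years <- as.integer(years)
  set.seed(as.integer(seed))
  w <- init_world(config)
  for (t in seq_len(config$params$years)) w <- step_year(w)
  out <- as.data.frame(w$out, row.names = NA)
  if (nrow(out)) {
    out$mean_net_income_5yr <- trail_mean(out$mean_net_income, 5)
    out$income_slope_orphan <- trail_slope(out$income_orphan, 10)
    out$income_slope_agro <- trail_slope(out$income_agro, 10)
    out$income_slope_entre <- trail_slope(out$income_entre, 10)
  }
  class(out) <- c("fs_run", "data.frame")
  attr(out, "world") <- w
  out
}

trail_mean <- function(x, k) {
  vapply(seq_along(x), function(i) {
    v <- x[max(1, i - k + 1):i]; mean(v[is.finite(v)])
  }, numeric(1))
}

trail_slope <- function(x, k) {
  vapply(seq_along(x), function(i) income_slope(x[max(1, i - k + 1):i], k),
         numeric(1))
}

#' Run a seeded batch of replicate simulations
#'
#' Runs `n_runs` independent replicates of one scenario (per-run seeds
#' `base_seed + run index - 1`) and returns across-run mean and SD of every
#' tracked outcome per year.
#'
#' @param config an `fs_config`
#' @param n_runs number of replicates (250 in the reference experiments)
#' @param base_seed integer; run `i` uses seed `base_seed + i - 1`
#' @param keep_runs if TRUE, the individual run data.frames are returned too
#' @return list of class `fs_batch` with `mean` and `sd` data.frames and `n`
#' @export
run_batch <- function(config, n_runs = 250, base_seed = 1L, keep_runs = FALSE) {
  stopifnot(n_runs >= 1)
  runs <- vector("list", n_runs)
  acc <- NULL
  acc2 <- NULL
  for (r in seq_len(n_runs)) {
    res <- run_simulation(config, seed = base_seed + r - 1L)
    m <- as.matrix(as.data.frame(unclass(res)))
    if (is.null(acc)) {
      acc <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
      acc2 <- acc
      cnt <- acc
    }
    fin <- is.finite(m)
    m0 <- ifelse(fin, m, 0)
    acc <- acc + m0
    acc2 <- acc2 + m0^2
    cnt <- cnt + fin
    if (keep_runs) runs[[r]] <- res
  }
  mu <- acc / pmax(cnt, 1)
  va <- pmax(0, acc2 / pmax(cnt, 1) - mu^2)
  mu[cnt == 0] <- NA
  out <- list(mean = as.data.frame(mu), sd = as.data.frame(sqrt(va)),
              n = n_runs, runs = if (keep_runs) runs else NULL)
  class(out) <- c("fs_batch", "list")
  out
}

#' Write a run or batch to CSV
#'
#' @param x an `fs_run` or `fs_batch`
#' @param path output file (batch writes `<path>` for means and
#'   `<stem>_sd.csv` for SDs)
#' @return the path(s), invisibly
#' @export
write_outputs <- function(x, path) {
  if (inherits(x, "fs_batch")) {
    utils::write.csv(x$mean, path, row.names = FALSE)
    sd_path <- sub("\\.csv$", "_sd.csv", path)
    utils::write.csv(x$sd, sd_path, row.names = FALSE)
    return(invisible(c(path, sd_path)))
  }
  utils::write.csv(as.data.frame(unclass(x)), path, row.names = FALSE)
  invisible(path)
}
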