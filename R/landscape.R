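#' Initialize the rural landscape
#'
#' Creates the grid of 1-ha arable plots. Each plot receives an independent
#' maximum productive potential under orphan agriculture, drawn
#' Uniform(800, 1200) kg/yr, and an agroecology yield multiple drawn from a
#' Normal(4, 1.5) truncated (by rejection) to \[2, 7\]. No plot has an owner.
#'
#' @param params parameter list from [default_params()]
#' @return A list of class `fs_landscape` with parallel vectors over plots:
#'   `row`, `col` (0-based coordinates), `base_max_yield`, `agro_multiple`,
#'   `owner` (household id or NA), `transitioned`, `transition_progress`
#'   (NA when no transition is under way), `current_max_yield`, plus the
#'   4-neighbour adjacency index matrix `nbr`.
#' @export
init_landscape <- function(params) {
  side <- params$grid_side
  n <- side * side
  lo <- params$base_plot_yield_mean * (1 - params$base_plot_yield_halfwidth)
  hi <- params$base_plot_yield_mean * (1 + params$base_plot_yield_halfwidth)
  base <- stats::runif(n, lo, hi)
  mult <- rtrunc_norm(n, params$agro_multiple_mean, params$agro_multiple_sd,
                      params$agro_multiple_bounds[1], params$agro_multiple_bounds[2])
  idx <- seq_len(n) - 1L
  L <- list(
    row = idx %/% side,
    col = idx %% side,
    base_max_yield = base,
    agro_multiple = mult,
    owner = rep(NA_integer_, n),
    retired = rep(FALSE, n),   # deactivated by abandonment; out of production
    transitioned = rep(FALSE, n),
    transition_progress = rep(NA_integer_, n),
    current_max_yield = base,
    nbr = grid_neighbours(side)
  )
  L
}

# truncated normal by rejection: exact at this scale
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(n, mean, sd)
    out <- c(out, draw[draw >= lo & draw <= hi])
  }
  out[seq_len(n)]
}

# 4-neighbour (von Neumann) adjacency, no wrap-around; NA where off-grid
grid_neighbours <- function(side) {
  n <- side * side
  idx <- seq_len(n)
  row <- (idx - 1L) %/% side
  col <- (idx - 1L) %% side
  up    <- ifelse(row > 0L,        idx - side, NA_integer_)
  down  <- ifelse(row < side - 1L, idx + side, NA_integer_)
  left  <- ifelse(col > 0L,        idx - 1L,   NA_integer_)
  right <- ifelse(col < side - 1L, idx + 1L,   NA_integer_)
  cbind(up, down, left, right)
}

#' Place households on the landscape
#'
#' Assigns `n` households to `n` distinct, randomly selected plots.
#'
#' @param landscape an `fs_landscape`
#' @param n number of households
#' @return the landscape with `owner` set to household ids `1..n` on the
#'   selected plots
#' @export
place_households <- function(landscape, n) {
  n_plots <- length(landscape$owner)
  if (n > n_plots)
    stop("configuration error: more households (", n, ") than plots (", n_plots, ")",
         call. = FALSE)
  picks <- sample.int(n_plots, n)
  landscape$owner[picks] <- seq_len(n)
  landscape
}

#' Best unoccupied plot contiguous with a household's farm
#'
#' Returns the index of the unoccupied plot adjacent (4-neighbour) to any plot
#' the household owns, with the highest productive potential under the
#' household's farming style. For agroecology buyers the potential is
#' `base_max_yield * agro_multiple` (or the sensitivity-mode equivalent); for
#' other buyers it is the entrepreneurial potential
#' `base_max_yield * fertilizer_max_multiple`. Ties break on the lowest plot
#' index (row-major, i.e. lowest (row, col)).
#'
#' @param landscape an `fs_landscape`
#' @param household_id id of the buying household
#' @param potential numeric vector of per-plot productive potential used for
#'   the argmax
#' @param owned optional precomputed indices of the household's plots
#' @return plot index, or `NA_integer_` if no adjacent unoccupied plot exists
#' @export
best_contiguous_plot <- function(landscape, household_id, potential, owned = NULL) {
  if (is.null(owned))
    owned <- which(!is.na(landscape$owner) & landscape$owner == household_id)
  if (!length(owned)) stop("household owns no plots", call. = FALSE)
  cand <- as.vector(landscape$nbr[owned, , drop = FALSE])
  cand <- cand[!is.na(cand)]
  cand <- cand[is.na(landscape$owner[cand]) & !landscape$retired[cand]]
  if (!length(cand)) return(NA_integer_)
  pot <- potential[cand]
  min(cand[pot == max(pot)])   # ties: lowest (row, col)
}

#' Advance agroecology transitions by one year
#'
#' Plots under transition gain one year of progress. During transition the
#' current maximum yield interpolates linearly from the base yield to the full
#' agroecology potential; on completing the transition period the plot is
#' marked transitioned at its full (capped) potential.
#'
#' @param landscape an `fs_landscape`
#' @param params parameter list
#' @param agro_full per-plot full agroecology potential (kg/yr), e.g.
#'   `base_max_yield * agro_multiple`, already capped
#' @return the updated landscape
#' @export
advance_transitions <- function(landscape, params, agro_full) {
  tr <- which(!is.na(landscape$transition_progress) & !landscape$transitioned)
  if (!length(tr)) return(landscape)
  prog <- landscape$transition_progress[tr] + 1L
  landscape$transition_progress[tr] <- prog
  frac <- pmin(1, prog / params$agro_transition_years)
  base <- landscape$base_max_yield[tr]
  landscape$current_max_yield[tr] <-
    pmin(base + (agro_full[tr] - base) * frac, params$plot_yield_cap)
  done <- prog >= params$agro_transition_years
  landscape$transitioned[tr[done]] <- TRUE
  landscape
}

#' Apply slow annual yield increments to peasant plots
#'
#' Orphan-farmed plots and fully-transitioned agroecology plots whose owner
#' produced at its unconstrained optimum this year gain a slow increase in
#' maximum productivity, at the policy-dependent rate, capped at the plot
#' yield ceiling. Entrepreneurial plots never gain increments.
#'
#' @param landscape an `fs_landscape`
#' @param orphan_idx indices of orphan plots eligible this year
#' @param agro_idx indices of transitioned agroecology plots eligible this year
#' @param policy policy scenario (selects the increment profile)
#' @param params parameter list
#' @return the updated landscape
#' @export
apply_yield_increments <- function(landscape, orphan_idx, agro_idx, policy, params) {
  peasant <- identical(policy$yield_increment_profile, "peasant")
  r_orphan <- if (peasant) params$orphan_yield_increment_peasant else params$orphan_yield_increment_other
  r_agro <- if (peasant) params$agro_yield_increment_peasant else params$agro_yield_increment_other
  if (length(orphan_idx))
    landscape$current_max_yield[orphan_idx] <-
      pmin(landscape$current_max_yield[orphan_idx] * (1 + r_orphan), params$plot_yield_cap)
  if (length(agro_idx))
    landscape$current_max_yield[agro_idx] <-
      pmin(landscape$current_max_yield[agro_idx] * (1 + r_agro), params$plot_yield_cap)
  landscape
}
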