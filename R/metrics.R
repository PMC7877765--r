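#' Gini coefficient of incomes
#'
#' Mean absolute difference form: `G = sum_ij |x_i - x_j| / (2 n^2 xbar)`;
#' 0 when all incomes are equal or the mean is zero. When any income is
#' negative the vector is first shifted by its minimum, keeping G in \[0, 1\].
#'
#' @param incomes numeric vector (at least one value)
#' @return Gini coefficient in \[0, 1\]; `NA` for empty input
#' @examples
#' gini(c(1, 2, 3, 4))   # 0.25
#' gini(c(0, 0, 0, 10))  # 0.75
#' @export
gini <- function(incomes) {
  incomes <- incomes[is.finite(incomes)]
  n <- length(incomes)
  if (n == 0) return(NA_real_)
  if (any(incomes < 0)) incomes <- incomes - min(incomes)
  m <- mean(incomes)
  if (m == 0) return(0)
  x <- sort(incomes)
  # sum_ij |xi - xj| = 2 * sum_i (2i - n - 1) x_(i)
  s <- 2 * sum((2 * seq_len(n) - n - 1) * x)
  s / (2 * n^2 * m)
}

#' Trailing income slope
#'
#' Ordinary least-squares slope ($/yr) of income on year over the trailing
#' window (default ten years; shorter early in a run).
#'
#' @param series income series, most recent last
#' @param window trailing window length in years
#' @return slope in $ per year; 0 when fewer than two points are available
#' @examples
#' income_slope(c(0, 3, 4, 9, 9))  # 2.4
#' @export
income_slope <- function(series, window = 10) {
  series <- utils::tail(series, window)
  series <- series[is.finite(series)]
  n <- length(series)
  if (n < 2) return(0)
  t <- seq_len(n)
  sum((t - mean(t)) * (series - mean(series))) / sum((t - mean(t))^2)
}

#' Real land productivity of a farm
#'
#' Net income per hectare adjusted for 'endogeneity', the share of the gross
#' value product created on the farm:
#' `endogeneity = (GVP - purchased non-labour inputs) / GVP`, and
#' `RLP = (net income / farm size) * endogeneity`. A farm with no purchased
#' non-labour inputs has RLP equal to its net income per hectare; a farm whose
#' purchased inputs equal its gross value product has RLP 0.
#'
#' @param net_income farm net income ($), vectorized
#' @param size farm size (ha)
#' @param gvp gross value of total farm production ($)
#' @param purchased_inputs purchased inputs excluding labour ($)
#' @return real land productivity ($/ha)
#' @examples
#' real_land_productivity(400, 2, 1000, 250)  # 150
#' @export
real_land_productivity <- function(net_income, size, gvp, purchased_inputs) {
  endo <- ifelse(gvp > 0, pmax(0, gvp - purchased_inputs) / gvp, 0)
  ifelse(size > 0 & gvp > 0, net_income / size * endo, 0)
}

#' Mean orphan nutrition
#'
#' Average proportion of a basic diet achieved across remaining (active)
#' orphan households; `NA` when none remain.
#'
#' @param diet_frac diet fractions achieved
#' @param is_orphan logical: active orphan households
#' @return mean diet fraction or `NA`
#' @export
orphan_nutrition <- function(diet_frac, is_orphan) {
  if (!any(is_orphan)) return(NA_real_)
  mean(diet_frac[is_orphan])
}

#' Households feedable from total production
#'
#' `floor(total kg / 700 kg)`: the number of households that could be fed a
#' basic diet from the community's total production.
#'
#' @param total_kg total production (kg of cereal equivalents)
#' @param basic_diet kg per household-year (default 700)
#' @return count of households
#' @export
households_feedable <- function(total_kg, basic_diet = 700) {
  floor(total_kg / basic_diet)
}
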