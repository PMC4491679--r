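#' Patient cost parameters for a course of proton therapy
#'
#' Per-diem unreimbursed cost ranges for a patient travelling to a proton
#' center (US government per-diem rates for representative cities near
#' proton facilities) and the treatment-calendar assumptions.
#'
#' @param meals_per_day `(low, high)` USD/day for meals and incidentals,
#'   default `c(51, 71)`.
#' @param lodging_per_day `(low, high)` USD/day, default `c(80, 185)`.
#' @param wage_per_day USD/day of lost wages, default 200 (a $52,100/year
#'   median household income over ~260 working days).
#' @param planning_days Days for CT simulation and treatment planning,
#'   default 5.
#' @param fractions_per_week Treatment days per week, default 5
#'   (weekday-only delivery).
#' @return Object of class `"cost_parameters"`.
#' @export
cost_parameters <- function(meals_per_day = c(51, 71),
                            lodging_per_day = c(80, 185),
                            wage_per_day = 200,
                            planning_days = 5L,
                            fractions_per_week = 5L) {
  for (rng in list(meals_per_day, lodging_per_day)) {
    if (length(rng) != 2L || any(!is.finite(rng)) || any(rng < 0) || rng[1] > rng[2])
      stop("per-diem ranges must be two non-negative numbers, low <= high",
           call. = FALSE)
  }
  if (wage_per_day < 0) stop("wage_per_day must be >= 0", call. = FALSE)
  if (planning_days < 0) stop("planning_days must be >= 0", call. = FALSE)
  if (fractions_per_week < 1 || fractions_per_week > 7)
    stop("fractions_per_week must be in 1..7", call. = FALSE)
  structure(list(meals_per_day = meals_per_day,
                 lodging_per_day = lodging_per_day,
                 wage_per_day = wage_per_day,
                 planning_days = as.integer(planning_days),
                 fractions_per_week = as.integer(fractions_per_week)),
            class = "cost_parameters")
}

#' Calendar days for a treatment course
#'
#' Delivery span under a Monday-start calendar with `fractions_per_week`
#' treatment days per week and intervening rest days counted inside the
#' span: `span = n + (7 - fpw) * floor((n - 1) / fpw)` (for the default five
#' weekday fractions, `n + 2 * floor((n - 1) / 5)`, i.e. weekends between
#' treatment weeks are included). Total days add the planning days.
#'
#' @param n_fractions Number of fractions, >= 1.
#' @param params A [cost_parameters()].
#' @return List with `delivery_span_days` and `total_days`.
#' @examples
#' treatment_calendar_days(44)$total_days  # 65
#' @export
treatment_calendar_days <- function(n_fractions, params = cost_parameters()) {
  stopifnot(inherits(params, "cost_parameters"))
  if (length(n_fractions) != 1L || !is.finite(n_fractions) || n_fractions < 1 ||
      abs(n_fractions - round(n_fractions)) > 1e-9)
    stop("n_fractions must be a positive whole number", call. = FALSE)
  n <- as.integer(round(n_fractions))
  fpw <- params$fractions_per_week
  span <- n + (7L - fpw) * (n - 1L) %/% fpw
  list(delivery_span_days = span, total_days = span + params$planning_days)
}

#' Unreimbursed cost savings from hypofractionation
#'
#' Days saved are the difference of delivery spans between the standard and
#' hypofractionated courses (planning days are common to both and cancel);
#' each cost component is days saved times its per-diem rate, unrounded.
#'
#' @param n_standard Standard fraction count, default 44.
#' @param n_hypo Hypofractionated count, default 25; must be `< n_standard`.
#' @param params A [cost_parameters()].
#' @return Object of class `"savings_report"`: list with `days_saved`,
#'   `meals_usd` (low, high), `lodging_usd` (low, high), `wages_usd`.
#' @examples
#' savings()  # 27 days; wages 27 * 200 = 5400 USD
#' @export
savings <- function(n_standard = 44, n_hypo = 25, params = cost_parameters()) {
  stopifnot(inherits(params, "cost_parameters"))
  if (n_hypo >= n_standard)
    stop("n_hypo must be smaller than n_standard", call. = FALSE)
  span_std <- treatment_calendar_days(n_standard, params)$delivery_span_days
  span_hyp <- treatment_calendar_days(n_hypo, params)$delivery_span_days
  days <- span_std - span_hyp
  structure(list(days_saved = days,
                 meals_usd = days * params$meals_per_day,
                 lodging_usd = days * params$lodging_per_day,
                 wages_usd = days * params$wage_per_day),
            class = "savings_report")
}

#' @export
print.savings_report <- function(x, ...) {
  cat(sprintf("Days saved: %d\n", x$days_saved))
  cat(sprintf("  Meals & incidentals: $%.0f - $%.0f\n",
              x$meals_usd[1], x$meals_usd[2]))
  cat(sprintf("  Lodging:             $%.0f - $%.0f\n",
              x$lodging_usd[1], x$lodging_usd[2]))
  cat(sprintf("  Lost wages:          $%.0f\n", x$wages_usd))
  invisible(x)
}

#' Convert an annual income to a daily wage
#'
#' @param annual Annual income in USD, >= 0.
#' @param convention `"workday"` (annual / 260.5, the working days in an
#'   average year) or `"calendar"` (annual / 365).
#' @return USD per day.
#' @examples
#' annual_wage_to_daily(52100, "workday")  # ~200
#' @export
annual_wage_to_daily <- function(annual, convention = c("workday", "calendar")) {
  convention <- match.arg(convention)
  if (any(!is.finite(annual)) || any(annual < 0))
    stop("annual income must be non-negative", call. = FALSE)
  annual / switch(convention, workday = 260.5, calendar = 365)
}
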