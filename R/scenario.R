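#' Per-cycle bed-rate targets from a base rate and increments
#'
#' Builds the escalating beds-per-1000 schedule: the target at the end of
#' cycle `i` is `base_rate` plus the cumulative sum of the per-cycle
#' increments through cycle `i`. With base 45 and increments of 3 per cycle
#' this yields the original 48-60 schedule; raising the increment to 4 from
#' cycle 3 yields the smart-community 48, 51, 55, 59, 63 schedule.
#'
#' @param base_rate Beds per 1000 at the start of the horizon.
#' @param increments Non-negative beds-per-1000 added in each cycle
#'   (length = number of cycles).
#' @return Numeric vector of per-cycle targets, in beds per 1000.
#' @examples
#' cycle_rate_targets(45, c(3, 3, 4, 4, 4))
#' @export
cycle_rate_targets <- function(base_rate, increments) {
  if (any(increments < 0)) stop("increments must be non-negative")
  base_rate + cumsum(increments)
}

#' Build the smart-community variant of a planning problem
#'
#' From `switch_cycle` onward, robot-substituted services reduce institution
#' income: the income coefficients are multiplied by `income_factor`
#' (default 0.5 from cycle 3). At the same time demand for beds escalates,
#' so the single end-of-horizon bed floor is replaced by per-cycle floors
#' from `schedule` (beds per 1000, one per cycle), measured against
#' `reference_population`, and the grade-share floors are enforced on the
#' cumulative bed mix at the end of every cycle.
#'
#' @param base A horizon-mode [care_problem()].
#' @param switch_cycle First cycle with reduced income (default 3: the
#'   2 + 3 split of a five-cycle horizon).
#' @param income_factor Multiplier on income coefficients from
#'   `switch_cycle` onward, in `(0, 1]`.
#' @param schedule Per-cycle bed-rate targets in beds per 1000 (length =
#'   number of cycles), e.g. from [cycle_rate_targets()].
#' @param reference_population Population the per-cycle floors are measured
#'   against; scalar (applied to every cycle, as in the printed model) or
#'   one value per cycle.
#' @return A per-cycle-mode [care_problem()].
#' @export
build_smart_problem <- function(base,
                                switch_cycle = 3,
                                income_factor = 0.5,
                                schedule,
                                reference_population) {
  stopifnot(inherits(base, "care_problem"))
  m <- base$cycles
  if (switch_cycle < 1 || switch_cycle > m) {
    config_abort("switch_cycle must lie in 1..cycles")
  }
  if (income_factor <= 0 || income_factor > 1) {
    config_abort("income_factor must lie in (0, 1]")
  }
  if (length(schedule) != m) {
    config_abort("schedule must supply one bed-rate target per cycle")
  }
  factors <- rep(1, m)
  factors[seq(switch_cycle, m)] <- income_factor
  care_problem(
    grades = base$grades,
    initial_beds = base$initial_beds,
    cycles = m,
    cycle_rate_targets = schedule / 1000,
    reference_population = reference_population,
    income_factors = factors,
    upper_bounds = NULL,
    district = paste0(base$district, " (smart)")
  )
}

#' Linear extrapolation of a beds-per-1000 rate
#'
#' Extends the straight line through two observed rates to a target year.
#' Used to project what uninterrupted growth in bed provision would have
#' delivered by the end of the horizon.
#'
#' @param rate_t0,rate_t1 Observed rates (any consistent unit).
#' @param year0,year1 Their years; `year1` must differ from `year0`.
#' @param target_year Year to extrapolate to.
#' @return The extrapolated rate.
#' @examples
#' linear_rate_extrapolation(39, 45, 2018, 2020, 2035)  # 90
#' @export
linear_rate_extrapolation <- function(rate_t0, rate_t1, year0, year1,
                                      target_year) {
  if (year1 == year0) stop("year0 and year1 must differ")
  rate_t0 + (target_year - year0) * (rate_t1 - rate_t0) / (year1 - year0)
}
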