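#' Nanjing fixture tables
#'
#' The package ships the published Nanjing parameterisation as plain-text
#' fixtures: the 2019 census of graded institutions per district, the grade
#' coefficient table (cost, income and bed coefficients, minimum shares),
#' the inferred initial bed stocks per district, and the two per-cycle
#' bed-rate schedules (the original 48-60 beds-per-1000 ramp and the
#' "existing programs" 48-63 ramp used by the smart-community scenario).
#'
#' Citywide scalars used by the fixture problems: the elderly population is
#' projected at 2.56 million in 2035 with a 60-beds-per-1000 floor; the
#' elderly population was 1.581 million at the end of 2020 and grows by
#' roughly 40-50 thousand a year, so the package uses 1.716 million
#' (1.581M + 3 x 45k) as its near-term (2023) reference population for the
#' per-cycle floors. District-level elderly populations were never
#' published, so district fixture problems default to the citywide values;
#' override `horizon_population` / `reference_population` to study a single
#' district against its own population.
#'
#' @name nanjing
NULL

nanjing_path <- function(file) {
  system.file("extdata", file, package = "eldercap", mustWork = TRUE)
}

read_fixture_csv <- function(file) {
  tibble::as_tibble(utils::read.csv(nanjing_path(file), check.names = FALSE))
}

#' @describeIn nanjing Grade parameter table (one row per grade,
#'   highest first).
#' @export
nanjing_grade_parameters <- function() {
  g <- read_fixture_csv("nanjing_grade_parameters.csv")
  grade_params(g$grade, g$cost_coeff, g$income_coeff, g$bed_coeff, g$min_share)
}

#' @describeIn nanjing Institutions per district and grade (2019 census).
#' @export
nanjing_institutions <- function() {
  read_fixture_csv("nanjing_institutions.csv")
}

#' @describeIn nanjing Published initial bed stocks per district and grade.
#' @export
nanjing_initial_beds <- function() {
  read_fixture_csv("nanjing_initial_beds.csv")
}

#' @describeIn nanjing Per-cycle beds-per-1000 schedules; `which` is
#'   `"original"` (48-60) or `"existing"` (48-63).
#' @param which Schedule name.
#' @export
nanjing_bed_rate_schedule <- function(which = c("existing", "original")) {
  which <- match.arg(which)
  s <- read_fixture_csv("nanjing_bed_rate_schedules.csv")
  s <- s[s$schedule == which, ]
  s$beds_per_1000[order(s$cycle)]
}

#' @describeIn nanjing District names in the fixture.
#' @export
nanjing_districts <- function() {
  nanjing_institutions()$district
}

# Citywide scalars of the Nanjing parameterisation.
nanjing_constants <- function() {
  list(
    horizon_population = 2560000,   # projected elderly population, 2035
    bed_rate_target = 0.06,         # 60 beds per 1000 elderly by 2035
    reference_population = 1716000, # 1.581M (end 2020) + 3yr x 45k growth
    cycles = 5L
  )
}

#' Build a Nanjing planning problem
#'
#' Assembles the planning problem for one Nanjing district (or the whole
#' city, `district = "city"`, which sums the district institution counts)
#' from the fixture tables. The baseline scenario enforces the single
#' end-of-horizon floor of 60 beds per 1000 elderly; the smart scenario
#' halves income coefficients from cycle 3 and enforces the escalating
#' per-cycle schedule.
#'
#' @param district District name (see [nanjing_districts()]) or `"city"`.
#' @param scenario `"baseline"` or `"smart"`.
#' @param horizon_population,reference_population Optional population
#'   overrides; defaults are the citywide values (district-level elderly
#'   populations were never published).
#' @param ... Passed on to [care_problem()] (e.g. `upper_bounds`).
#' @return A [care_problem()].
#' @examples
#' p <- nanjing_problem("Qinhuai")
#' p$initial_beds
#' @export
nanjing_problem <- function(district,
                            scenario = c("baseline", "smart"),
                            horizon_population = NULL,
                            reference_population = NULL,
                            ...) {
  scenario <- match.arg(scenario)
  konst <- nanjing_constants()
  inst <- nanjing_institutions()
  grades <- nanjing_grade_parameters()
  if (identical(district, "city")) {
    counts <- colSums(as.matrix(inst[, grades$grade]))
  } else {
    row <- inst[inst$district == district, ]
    if (nrow(row) != 1) {
      config_abort(sprintf(
        "unknown district '%s'; expected one of %s or 'city'",
        district, paste(inst$district, collapse = ", ")
      ))
    }
    counts <- as.numeric(row[, grades$grade])
  }
  base <- care_problem(
    grades = grades,
    counts = counts,
    cycles = konst$cycles,
    horizon_population = horizon_population %||% konst$horizon_population,
    bed_rate_target = konst$bed_rate_target,
    district = district,
    ...
  )
  if (scenario == "baseline") return(base)
  build_smart_problem(
    base,
    switch_cycle = 3,
    income_factor = 0.5,
    schedule = nanjing_bed_rate_schedule("existing"),
    reference_population = reference_population %||% konst$reference_population
  )
}
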