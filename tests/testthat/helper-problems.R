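# Small problem builders shared across the suite.

# Two grades, one cycle, distinct benefit/cost ratios so the Pareto front is
# informative.  Default floor asks for >= 20 new beds.
toy_problem <- function(bed_floor = 20, bounds = 4, min_share = 0,
                        a = c(3, 1), b = c(2, 1), cc = c(10, 10),
                        cycles = 1) {
  g <- grade_params(
    grade = c("hi", "lo"),
    cost_coeff = a, income_coeff = b, bed_coeff = cc,
    min_share = min_share
  )
  care_problem(
    grades = g, initial_beds = c(0, 0), cycles = cycles,
    horizon_population = 1000, bed_rate_target = bed_floor / 1000,
    upper_bounds = bounds, district = "toy"
  )
}

# Equal-ratio variant from the enumeration worked example: a = b so every
# feasible plan is Pareto-optimal.
toy_problem_equal_ratio <- function() {
  toy_problem(a = c(2, 1), b = c(2, 1))
}

# Five-grade, five-cycle problem with Nanjing coefficients but a small
# population so default bounds stay modest.
small_nanjing_like <- function() {
  care_problem(
    grades = nanjing_grade_parameters(),
    counts = c(0, 6, 8, 7, 5),
    cycles = 5,
    horizon_population = 80000,
    bed_rate_target = 0.06,
    district = "small"
  )
}

# Tiny synthetic spec whose instances stay exhaustively enumerable.
tiny_spec <- function(n_grades = 2, n_cycles = 2, bound_cap = 4) {
  synthetic_spec(
    n_grades = n_grades, n_cycles = n_cycles,
    cost_range = c(1, 10), income_range = c(1, 10), bed_range = c(5, 20),
    count_range = c(0, 2), population_range = c(100, 1000),
    rate_range = c(0.2, 0.6), share = 0.1, bound_cap = bound_cap
  )
}

# Objective pairs of an archive tibble as a canonical character key,
# tolerant of floating-point noise.
objective_keys <- function(tbl) {
  sprintf("%.9g|%.9g", tbl$benefit, tbl$cost)
}
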