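#' Grade parameter table
#'
#' Builds and validates the per-grade parameter table of a planning problem.
#' Each row describes one quality grade of elder-care institution (by
#' convention ordered from the highest grade, AAAAA, down to the lowest, A):
#' the construction-cost coefficient `cost_coeff` (area-like units per
#' institution), the income coefficient `income_coeff` (currency-like units
#' per institution), the bed coefficient `bed_coeff` (average beds per
#' institution), and the minimum share `min_share` of total beds that the
#' grade must hold.
#'
#' @param grade Character vector of grade labels (e.g. `"AAAAA"` ... `"A"`).
#' @param cost_coeff,income_coeff Non-negative per-institution coefficients.
#' @param bed_coeff Strictly positive beds per institution.
#' @param min_share Minimum bed-share fractions in `[0, 1]`; their sum must
#'   not exceed 1 or no plan can satisfy all share floors.
#' @return A tibble with one row per grade.
#' @examples
#' grade_params(
#'   grade = c("high", "low"),
#'   cost_coeff = c(10, 1), income_coeff = c(20, 2),
#'   bed_coeff = c(100, 10), min_share = c(0.2, 0.2)
#' )
#' @export
grade_params <- function(grade, cost_coeff, income_coeff, bed_coeff,
                         min_share = 0) {
  n <- length(grade)
  g <- tibble::tibble(
    grade = as.character(grade),
    cost_coeff = as.double(cost_coeff),
    income_coeff = as.double(income_coeff),
    bed_coeff = as.double(bed_coeff),
    min_share = rep_len(as.double(min_share), n)
  )
  if (anyDuplicated(g$grade)) {
    config_abort("grades: labels must be distinct")
  }
  if (any(g$cost_coeff < 0) || any(g$income_coeff < 0)) {
    config_abort("grades: cost_coeff and income_coeff must be >= 0")
  }
  if (any(g$bed_coeff <= 0)) {
    config_abort("grades: bed_coeff must be > 0")
  }
  if (any(g$min_share < 0) || any(g$min_share > 1)) {
    config_abort("grades: min_share must lie in [0, 1]")
  }
  if (sum(g$min_share) > 1 + 1e-12) {
    config_abort(sprintf(
      "grades: min_share sums to %.4f > 1; the share floors are jointly unsatisfiable",
      sum(g$min_share)
    ))
  }
  g
}

config_abort <- function(msg) {
  rlang::abort(msg, class = "eldercap_config_error")
}

#' Derive initial bed stocks from institution counts
#'
#' Converts per-grade institution counts into initial bed stocks using the
#' ceiling of each bed coefficient: `counts * ceiling(bed_coeff)`. The
#' published district bed stocks are integer multiples of the rounded-up
#' coefficients, so the ceiling rule reconstructs them exactly; constraint
#' arithmetic elsewhere in the package keeps the raw (fractional) bed
#' coefficients.
#'
#' @param counts Non-negative integer vector of institutions per grade.
#' @param bed_coeffs Positive beds-per-institution coefficients, same length.
#' @return Integer vector of initial beds per grade.
#' @examples
#' derive_initial_beds(c(0, 6, 8, 7, 5),
#'                     c(777.6, 265.4, 168.1428571, 74.33333333, 35))
#' @export
derive_initial_beds <- function(counts, bed_coeffs) {
  if (length(counts) != length(bed_coeffs)) {
    stop("counts and bed_coeffs must have equal length")
  }
  if (any(counts < 0)) stop("institution counts must be non-negative")
  if (any(bed_coeffs <= 0)) stop("bed coefficients must be positive")
  as.integer(round(counts * ceiling(bed_coeffs)))
}

#' Define a capacity-planning problem
#'
#' Assembles one district's (or one scenario's) planning problem: grade
#' parameters, initial bed stocks, the number of three-year construction
#' cycles, population targets and bed-rate floors, per-cycle income factors,
#' and per-cell upper bounds on the decision variables. The decision variable
#' is an `cycles x n_grades` matrix of non-negative integers: how many
#' institutions of each grade to build in each cycle.
#'
#' Two constraint modes exist. In `"horizon"` mode a single beds-per-capita
#' floor is enforced at the end of the horizon together with grade-share
#' floors on the final bed mix. In `"per_cycle"` mode (used by the
#' smart-community scenario, see [build_smart_problem()]) a beds-per-capita
#' floor is enforced at the end of every cycle against `reference_population`,
#' and the grade-share floors are enforced on the cumulative bed mix of every
#' cycle.
#'
#' @param grades A data frame as returned by [grade_params()].
#' @param counts Optional institutions per grade; initial beds are then
#'   derived with [derive_initial_beds()].
#' @param initial_beds Optional explicit initial beds per grade (overrides
#'   `counts`-based derivation).
#' @param cycles Number of construction cycles M (default 5).
#' @param horizon_population Elderly population at the end of the horizon
#'   (required in horizon mode).
#' @param bed_rate_target Horizon beds-per-capita floor as a fraction
#'   (default 0.06, i.e. 60 beds per 1000 elderly).
#' @param cycle_rate_targets Optional per-cycle beds-per-capita floors
#'   (length `cycles`); supplying them switches the problem to per-cycle mode.
#' @param reference_population Population the per-cycle floors are measured
#'   against. A single number applies one reference population to every
#'   cycle; a vector of length `cycles` gives each cycle its own.
#' @param income_factors Per-cycle multiplier on the income coefficients in
#'   `(0, 1]`; scalar or length `cycles`. All 1 in the baseline model.
#' @param upper_bounds Per-cell maxima for the decision matrix: a scalar, a
#'   length-`n_grades` vector, or a full `cycles x n_grades` matrix. Defaults
#'   to `ceiling(pmax(0, additional beds required) / bed_coeff)` per grade,
#'   the number of institutions of that grade that could on its own close the
#'   largest remaining bed gap.
#' @param district Label used in printing and outputs.
#' @return An object of class `care_problem`.
#' @seealso [evaluate_plan()], [moga()], [build_smart_problem()]
#' @export
care_problem <- function(grades,
                         counts = NULL,
                         initial_beds = NULL,
                         cycles = 5,
                         horizon_population = NULL,
                         bed_rate_target = 0.06,
                         cycle_rate_targets = NULL,
                         reference_population = NULL,
                         income_factors = 1,
                         upper_bounds = NULL,
                         district = "district") {
  grades <- grade_params(grades$grade, grades$cost_coeff, grades$income_coeff,
                         grades$bed_coeff, grades$min_share)
  n <- nrow(grades)
  m <- as.integer(cycles)
  if (is.na(m) || m < 1) config_abort("cycles must be a positive integer")

  if (is.null(initial_beds)) {
    if (is.null(counts)) {
      initial_beds <- rep(0L, n)
    } else {
      if (length(counts) != n) config_abort("counts: one entry per grade required")
      initial_beds <- derive_initial_beds(counts, grades$bed_coeff)
    }
  }
  if (length(initial_beds) != n || any(initial_beds < 0)) {
    config_abort("initial_beds: one non-negative entry per grade required")
  }
  initial_beds <- as.double(initial_beds)

  mode <- if (is.null(cycle_rate_targets)) "horizon" else "per_cycle"
  if (mode == "horizon") {
    if (is.null(horizon_population)) {
      config_abort("horizon mode requires horizon_population")
    }
    if (bed_rate_target < 0) config_abort("bed_rate_target must be >= 0")
    required <- bed_rate_target * horizon_population - sum(initial_beds)
  } else {
    if (length(cycle_rate_targets) != m) {
      config_abort("cycle_rate_targets must have one rate per cycle")
    }
    if (any(cycle_rate_targets < 0)) config_abort("cycle_rate_targets must be >= 0")
    if (is.null(reference_population)) {
      config_abort("per-cycle mode requires reference_population")
    }
    if (!length(reference_population) %in% c(1L, m)) {
      config_abort("reference_population must be a single value or one per cycle")
    }
    reference_population <- rep_len(as.double(reference_population), m)
    required <- max(cycle_rate_targets * reference_population) - sum(initial_beds)
  }

  income_factors <- rep_len(as.double(income_factors), m)
  if (any(income_factors <= 0) || any(income_factors > 1)) {
    config_abort("income_factors must lie in (0, 1]")
  }

  if (is.null(upper_bounds)) {
    per_grade <- ceiling(max(required, 0) / grades$bed_coeff)
    upper_bounds <- matrix(per_grade, nrow = m, ncol = n, byrow = TRUE)
  } else if (is.matrix(upper_bounds)) {
    if (!all(dim(upper_bounds) == c(m, n))) {
      config_abort("upper_bounds matrix must be cycles x n_grades")
    }
  } else if (length(upper_bounds) %in% c(1L, n)) {
    upper_bounds <- matrix(rep_len(as.double(upper_bounds), n),
                           nrow = m, ncol = n, byrow = TRUE)
  } else {
    config_abort("upper_bounds must be a scalar, per-grade vector, or full matrix")
  }
  if (any(upper_bounds < 0)) config_abort("upper_bounds must be >= 0")
  storage.mode(upper_bounds) <- "double"
  dimnames(upper_bounds) <- list(paste0("cycle", seq_len(m)), grades$grade)

  problem <- structure(
    list(
      district = district,
      grades = grades,
      initial_beds = stats::setNames(initial_beds, grades$grade),
      cycles = m,
      n_grades = n,
      mode = mode,
      horizon_population = horizon_population,
      bed_rate_target = bed_rate_target,
      cycle_rate_targets = cycle_rate_targets,
      reference_population = reference_population,
      income_factors = income_factors,
      upper_bounds = upper_bounds
    ),
    class = "care_problem"
  )
  problem$linear <- linearize_problem(problem)
  problem
}

#' @export
print.care_problem <- function(x, ...) {
  cat(sprintf(
    "<care_problem> %s: %d cycles x %d grades, %s mode\n",
    x$district, x$cycles, x$n_grades, x$mode
  ))
  cat(sprintf("  initial beds: %s (total %d)\n",
              paste(x$initial_beds, collapse = ", "), sum(x$initial_beds)))
  if (x$mode == "horizon") {
    cat(sprintf("  horizon floor: %.3f x %s beds\n",
                x$bed_rate_target, format(x$horizon_population, big.mark = ",")))
  } else {
    cat(sprintf("  per-cycle floors: %s per capita\n",
                paste(format(x$cycle_rate_targets), collapse = ", ")))
  }
  cat(sprintf("  income factors: %s\n", paste(x$income_factors, collapse = ", ")))
  invisible(x)
}

# Precompute the linear form of objectives and constraints over the
# column-major flattening of the M x N plan matrix: F1 = w1.x, F2 = w2.x,
# slack = A x - rhs.  Everything in the model is linear, so population-level
# evaluation in the GA reduces to one matrix product.
linearize_problem <- function(p) {
  m <- p$cycles
  n <- p$n_grades
  cyc <- rep(seq_len(m), times = n)   # cycle index of each gene
  grd <- rep(seq_len(n), each = m)    # grade index of each gene
  b <- p$grades$income_coeff
  a <- p$grades$cost_coeff
  cc <- p$grades$bed_coeff
  pk <- p$grades$min_share
  d0 <- unname(p$initial_beds)
  D0 <- sum(d0)

  w1 <- p$income_factors[cyc] * b[grd]
  w2 <- a[grd]

  rows <- list()
  rhs <- c()
  labels <- c()
  if (p$mode == "horizon") {
    rows[[1]] <- cc[grd]
    rhs <- p$bed_rate_target * p$horizon_population - D0
    labels <- "bed_floor_horizon"
    for (k in seq_len(n)) {
      coef <- -pk[k] * cc[grd]
      coef[grd == k] <- coef[grd == k] + cc[k]
      rows[[length(rows) + 1L]] <- coef
      rhs <- c(rhs, pk[k] * D0 - d0[k])
      labels <- c(labels, paste0("share_", p$grades$grade[k]))
    }
  } else {
    for (i in seq_len(m)) {
      coef <- ifelse(cyc <= i, cc[grd], 0)
      rows[[length(rows) + 1L]] <- coef
      rhs <- c(rhs, p$cycle_rate_targets[i] * p$reference_population[i] - D0)
      labels <- c(labels, paste0("bed_floor_cycle", i))
    }
    for (i in seq_len(m)) {
      for (k in seq_len(n)) {
        coef <- ifelse(cyc <= i, -pk[k] * cc[grd], 0)
        sel <- grd == k & cyc <= i
        coef[sel] <- coef[sel] + cc[k]
        rows[[length(rows) + 1L]] <- coef
        rhs <- c(rhs, pk[k] * D0 - d0[k])
        labels <- c(labels, paste0("share_cycle", i, "_", p$grades$grade[k]))
      }
    }
  }
  A <- do.call(rbind, rows)
  list(w1 = w1, w2 = w2, A = A, rhs = rhs, labels = labels)
}

#' Coerce a plan to its matrix form
#'
#' Plans may be given as a `cycles x n_grades` numeric matrix or as a long
#' data frame with columns `cycle`, `grade`, `count`. Entries must be
#' non-negative integers.
#'
#' @param plan Matrix or data frame.
#' @param problem A [care_problem()].
#' @param check_bounds If `TRUE`, additionally require every cell to respect
#'   the problem's upper bounds.
#' @return A `cycles x n_grades` numeric matrix with grade column names.
#' @export
as_plan_matrix <- function(plan, problem, check_bounds = FALSE) {
  m <- problem$cycles
  n <- problem$n_grades
  if (is.data.frame(plan)) {
    required <- c("cycle", "grade", "count")
    if (!all(required %in% names(plan))) {
      stop("plan data frame needs columns cycle, grade, count")
    }
    x <- matrix(0, nrow = m, ncol = n,
                dimnames = list(NULL, problem$grades$grade))
    gi <- match(plan$grade, problem$grades$grade)
    if (anyNA(gi)) stop("plan contains unknown grade labels")
    if (any(plan$cycle < 1 | plan$cycle > m)) stop("plan cycle out of range")
    x[cbind(plan$cycle, gi)] <- plan$count
  } else {
    x <- as.matrix(plan)
    if (!all(dim(x) == c(m, n))) {
      stop(sprintf("plan must be %d x %d for this problem", m, n))
    }
    colnames(x) <- problem$grades$grade
  }
  if (any(x < 0)) stop("plan entries must be non-negative")
  if (any(abs(x - round(x)) > 1e-8)) stop("plan entries must be integers")
  if (check_bounds && any(x > problem$upper_bounds + 1e-8)) {
    stop("plan exceeds the problem's upper bounds")
  }
  x
}

#' Tidy a plan matrix
#'
#' @param x Plan matrix (or long data frame, passed through after validation).
#' @param problem A [care_problem()].
#' @return Tibble with columns `cycle`, `grade`, `count`.
#' @export
plan_tibble <- function(x, problem) {
  x <- as_plan_matrix(x, problem)
  tibble::tibble(
    cycle = rep(seq_len(problem$cycles), times = problem$n_grades),
    grade = rep(problem$grades$grade, each = problem$cycles),
    count = as.integer(round(as.vector(x)))
  )
}

#' Economic benefit of a plan
#'
#' Total income over the horizon: the sum over cycles and grades of
#' `income_factor[cycle] * income_coeff[grade] * count`. With all income
#' factors at 1 this is the baseline benefit objective; the smart-community
#' scenario sets factors below 1 from its switch cycle.
#'
#' @inheritParams as_plan_matrix
#' @return A single number.
#' @export
economic_benefit <- function(plan, problem) {
  x <- as_plan_matrix(plan, problem)
  sum(problem$linear$w1 * as.vector(x))
}

#' Social cost of a plan
#'
#' Total construction cost over the horizon: the sum over cycles and grades
#' of `cost_coeff[grade] * count`.
#'
#' @inheritParams as_plan_matrix
#' @return A single number.
#' @export
social_cost <- function(plan, problem) {
  x <- as_plan_matrix(plan, problem)
  sum(problem$linear$w2 * as.vector(x))
}

#' Horizon beds-per-capita floor
#'
#' Slack of the end-of-horizon bed requirement: total beds (initial plus
#' built, using the raw bed coefficients) minus
#' `bed_rate_target * horizon_population`. Non-negative slack means the floor
#' is met.
#'
#' @inheritParams as_plan_matrix
#' @return A single slack value.
#' @export
horizon_bed_floor <- function(plan, problem) {
  if (problem$mode != "horizon") {
    stop("horizon_bed_floor applies to horizon-mode problems")
  }
  x <- as_plan_matrix(plan, problem)
  built <- sum(sweep(x, 2, problem$grades$bed_coeff, `*`))
  sum(problem$initial_beds) + built -
    problem$bed_rate_target * problem$horizon_population
}

#' Cumulative beds per grade
#'
#' Bed stock of each grade after `through_cycle` cycles of construction:
#' initial beds plus `bed_coeff` times the counts built in cycles
#' `1..through_cycle`. `through_cycle = 0` returns the initial stocks.
#'
#' @inheritParams as_plan_matrix
#' @param through_cycle Integer in `0..cycles`.
#' @return Named numeric vector, one entry per grade.
#' @export
cumulative_beds <- function(plan, problem, through_cycle = problem$cycles) {
  if (through_cycle < 0 || through_cycle > problem$cycles) {
    stop("through_cycle out of range")
  }
  x <- as_plan_matrix(plan, problem)
  built <- if (through_cycle == 0) {
    rep(0, problem$n_grades)
  } else {
    colSums(x[seq_len(through_cycle), , drop = FALSE]) * problem$grades$bed_coeff
  }
  stats::setNames(unname(problem$initial_beds) + built, problem$grades$grade)
}

#' Grade bed-share floors
#'
#' Slack of each grade's minimum-share constraint on the bed mix after
#' `through_cycle` cycles: `beds_k - min_share_k * total_beds`. With
#' `through_cycle = cycles` (the default) this is the end-of-horizon share
#' constraint of the baseline model; per-cycle-mode problems apply it at the
#' end of every cycle.
#'
#' @inheritParams cumulative_beds
#' @return Named numeric slack vector, one entry per grade.
#' @export
grade_share_floors <- function(plan, problem, through_cycle = problem$cycles) {
  beds <- cumulative_beds(plan, problem, through_cycle)
  beds - problem$grades$min_share * sum(beds)
}

#' Per-cycle beds-per-capita floors
#'
#' Slack of the bed requirement at the end of each cycle: total cumulative
#' beds minus `cycle_rate_targets[i] * reference_population[i]`. Only defined
#' for per-cycle-mode problems.
#'
#' @inheritParams as_plan_matrix
#' @return Numeric slack vector, one entry per cycle.
#' @export
per_cycle_bed_floors <- function(plan, problem) {
  if (problem$mode != "per_cycle") {
    stop("per_cycle_bed_floors applies to per-cycle-mode problems")
  }
  vapply(seq_len(problem$cycles), function(i) {
    sum(cumulative_beds(plan, problem, i)) -
      problem$cycle_rate_targets[i] * problem$reference_population[i]
  }, numeric(1))
}

#' Evaluate a plan's objectives and feasibility
#'
#' Computes both objectives and all active constraints of the problem.
#' Objectives are reported in minimisation convention: `neg_benefit`
#' (the negated economic benefit) and `cost` (the social cost), so that
#' smaller is better in both coordinates.
#'
#' @inheritParams as_plan_matrix
#' @return A list with elements `objectives` (named length-2 vector
#'   `c(neg_benefit, cost)`), `benefit`, `cost`, `feasibility` (a tibble of
#'   per-constraint slacks), `total_violation`, and `feasible`.
#' @export
evaluate_plan <- function(plan, problem) {
  x <- as.vector(as_plan_matrix(plan, problem))
  lin <- problem$linear
  f1 <- sum(lin$w1 * x)
  f2 <- sum(lin$w2 * x)
  slack <- as.vector(lin$A %*% x) - lin$rhs
  violation <- sum(pmax(0, -slack))
  list(
    objectives = c(neg_benefit = -f1, cost = f2),
    benefit = f1,
    cost = f2,
    feasibility = tibble::tibble(constraint = lin$labels, slack = slack),
    total_violation = violation,
    feasible = violation == 0
  )
}

# Vectorised evaluation of a genome matrix (rows = individuals, columns =
# column-major plan cells).  Returns minimisation-convention objectives and
# total constraint violations.
evaluate_genomes <- function(G, problem) {
  lin <- problem$linear
  f1 <- as.vector(G %*% lin$w1)
  f2 <- as.vector(G %*% lin$w2)
  slack <- G %*% t(lin$A)
  slack <- sweep(slack, 2, lin$rhs, `-`)
  viol <- rowSums(pmax(-slack, 0))
  list(obj1 = -f1, obj2 = f2, violation = viol)
}
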