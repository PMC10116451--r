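#' Specification for synthetic planning problems
#'
#' Parameter ranges for the synthetic problem generator. Defaults mirror the
#' structure and magnitudes of the Nanjing parameterisation: five grades over
#' five cycles, cost / income / bed coefficients strictly decreasing from the
#' highest grade to the lowest, per-grade minimum shares of 15%, and a
#' beds-per-capita floor around 4-7%. Coefficient ranges are sampled so that
#' benefit/cost ratios differ across grades — with equal ratios the Pareto
#' front collapses to a line and exercises nothing.
#'
#' @param n_grades,n_cycles Problem dimensions.
#' @param cost_range,income_range,bed_range Sampling ranges for the grade
#'   coefficients (positive).
#' @param monotone If `TRUE` (default) sampled coefficients are sorted
#'   strictly decreasing from the highest grade to the lowest.
#' @param count_range Range of initial institution counts per grade.
#' @param population_range Range of the horizon elderly population.
#' @param rate_range Range of the beds-per-capita floor (fraction).
#' @param share Per-grade minimum bed share.
#' @param bound_cap Optional cap on the per-cell upper bounds (keeps small
#'   instances enumerable).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_grades = 5,
                           n_cycles = 5,
                           cost_range = c(300, 12000),
                           income_range = c(700, 8000),
                           bed_range = c(30, 800),
                           monotone = TRUE,
                           count_range = c(0, 8),
                           population_range = c(1e5, 1e6),
                           rate_range = c(0.04, 0.07),
                           share = 0.15,
                           bound_cap = NULL) {
  stopifnot(
    n_grades >= 1, n_cycles >= 1,
    all(cost_range > 0), all(income_range > 0), all(bed_range > 0),
    share >= 0, share * n_grades <= 1
  )
  structure(
    list(
      n_grades = as.integer(n_grades), n_cycles = as.integer(n_cycles),
      cost_range = cost_range, income_range = income_range,
      bed_range = bed_range, monotone = isTRUE(monotone),
      count_range = count_range, population_range = population_range,
      rate_range = rate_range, share = share, bound_cap = bound_cap
    ),
    class = "synthetic_spec"
  )
}

sample_coeffs <- function(n, range, monotone, distinct_ratios = FALSE) {
  x <- stats::runif(n, range[1], range[2])
  if (monotone) x <- sort(x, decreasing = TRUE)
  x
}

#' Generate a random planning problem
#'
#' Draws a problem from the ranges in `spec`, reproducibly under `seed`.
#' Generated problems are guaranteed to admit at least one feasible plan:
#' draws are rejected (up to `max_attempts`) until the all-maximum plan —
#' every cell at its upper bound — satisfies every constraint.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @param max_attempts Rejection-sampling budget.
#' @return A [care_problem()].
#' @export
generate_problem <- function(spec = synthetic_spec(), seed = 1L,
                             max_attempts = 100L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      n <- spec$n_grades
      a <- sample_coeffs(n, spec$cost_range, spec$monotone)
      b <- sample_coeffs(n, spec$income_range, spec$monotone)
      cc <- sample_coeffs(n, spec$bed_range, spec$monotone)
      counts <- sample(seq(spec$count_range[1], spec$count_range[2]),
                       n, replace = TRUE)
      pop <- stats::runif(1, spec$population_range[1], spec$population_range[2])
      rate <- stats::runif(1, spec$rate_range[1], spec$rate_range[2])
      grades <- grade_params(
        grade = paste0("G", rev(seq_len(n))),
        cost_coeff = a, income_coeff = b, bed_coeff = cc,
        min_share = spec$share
      )
      problem <- care_problem(
        grades = grades, counts = counts, cycles = spec$n_cycles,
        horizon_population = pop, bed_rate_target = rate,
        district = sprintf("synthetic-%d", seed)
      )
      if (!is.null(spec$bound_cap)) {
        problem <- care_problem(
          grades = grades, counts = counts, cycles = spec$n_cycles,
          horizon_population = pop, bed_rate_target = rate,
          upper_bounds = pmin(problem$upper_bounds, spec$bound_cap),
          district = problem$district
        )
      }
      all_max <- evaluate_plan(problem$upper_bounds, problem)
      if (all_max$feasible) return(problem)
    }
    stop("could not generate a feasible problem within max_attempts")
  })
}

#' Exact Pareto set by exhaustive enumeration
#'
#' Enumerates every integer plan within the problem's upper bounds, keeps
#' the feasible ones, and returns the exact non-dominated set. Intended as
#' the ground-truth oracle for small instances; refuses instances with more
#' than `max_plans` candidate plans.
#'
#' @param problem A [care_problem()].
#' @param max_plans Enumeration cap (default `1e6`).
#' @return A list of class `pareto_oracle`: `archive` (tibble with flattened
#'   plan cells, `benefit`, `cost`), `plans` (list of matrices), `n_candidates`,
#'   `n_feasible`, and `feasible` (whether any feasible plan exists).
#' @export
brute_force_pareto <- function(problem, max_plans = 1e6) {
  stopifnot(inherits(problem, "care_problem"))
  bounds <- as.vector(problem$upper_bounds)
  n_cand <- prod(bounds + 1)
  if (n_cand > max_plans) {
    stop(sprintf("instance has %.3g candidate plans (> %.3g cap)",
                 n_cand, max_plans))
  }
  G <- as.matrix(expand.grid(lapply(bounds, function(b) 0:b)))
  colnames(G) <- NULL
  ev <- evaluate_genomes(G, problem)
  feas <- ev$violation == 0
  any_feasible <- any(feas)
  if (any_feasible) {
    G <- G[feas, , drop = FALSE]
    o1 <- ev$obj1[feas]
    o2 <- ev$obj2[feas]
  } else {
    o1 <- ev$obj1
    o2 <- ev$obj2
  }
  rnk <- non_dominated_sort(o1, o2)
  keep <- rnk == 1
  G <- G[keep, , drop = FALSE]
  o1 <- o1[keep]
  o2 <- o2[keep]
  ord <- order(-o1, o2)
  G <- G[ord, , drop = FALSE]
  o1 <- o1[ord]
  o2 <- o2[ord]
  plans <- lapply(seq_len(nrow(G)), function(i) {
    matrix(G[i, ], nrow = problem$cycles, ncol = problem$n_grades,
           dimnames = list(NULL, problem$grades$grade))
  })
  cells <- tibble::as_tibble(G, .name_repair = "minimal")
  names(cells) <- paste0(
    "x_c", rep(seq_len(problem$cycles), times = problem$n_grades),
    "_", rep(problem$grades$grade, each = problem$cycles)
  )
  archive <- dplyr::bind_cols(
    tibble::tibble(solution = seq_len(nrow(G))),
    cells,
    tibble::tibble(benefit = -o1, cost = o2)
  )
  structure(
    list(archive = archive, plans = plans,
         n_candidates = n_cand, n_feasible = sum(feas),
         feasible = any_feasible),
    class = "pareto_oracle"
  )
}
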