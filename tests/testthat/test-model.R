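# Core model: bed derivation, objectives, constraints, evaluation.

printed_c <- c(777.6, 265.4, 168.1428571, 74.33333333, 35)

test_that("initial beds derive from counts by the ceiling rule", {
  expect_equal(
    derive_initial_beds(c(0, 6, 8, 7, 5), printed_c),
    c(0L, 1596L, 1352L, 525L, 175L)
  )
  expect_equal(derive_initial_beds(rep(0, 5), printed_c), rep(0L, 5))
  expect_equal(derive_initial_beds(rep(1, 5), printed_c),
               c(778L, 266L, 169L, 75L, 35L))
  expect_error(derive_initial_beds(c(1, 2), printed_c), "equal length")
  expect_error(derive_initial_beds(c(-1, rep(0, 4)), printed_c),
               "non-negative")
})

test_that("every published district bed stock is reconstructed (55/55 cells)", {
  inst <- nanjing_institutions()
  beds <- nanjing_initial_beds()
  g <- nanjing_grade_parameters()
  derived <- t(apply(as.matrix(inst[, g$grade]), 1,
                     derive_initial_beds, bed_coeffs = g$bed_coeff))
  expect_identical(unname(derived),
                   unname(as.matrix(beds[, g$grade])))
})

test_that("economic benefit sums income coefficients with cycle factors", {
  p <- small_nanjing_like()
  plan <- matrix(0, 5, 5)
  plan[1, 1] <- 1  # one AAAAA institution in cycle 1
  expect_equal(economic_benefit(plan, p), 7916)
  expect_equal(economic_benefit(matrix(0, 5, 5), p), 0)

  smart <- care_problem(
    grades = p$grades, initial_beds = p$initial_beds, cycles = 5,
    horizon_population = p$horizon_population,
    income_factors = c(1, 1, 0.5, 0.5, 0.5)
  )
  plan3 <- matrix(0, 5, 5)
  plan3[3, 1] <- 1  # one AAAAA institution in cycle 3, halved income
  expect_equal(economic_benefit(plan3, smart), 3958)
})

test_that("social cost sums construction cost coefficients", {
  p <- small_nanjing_like()
  plan <- matrix(0, 5, 5)
  plan[2, 3] <- 1  # one AAA in any cycle
  expect_equal(social_cost(plan, p), 3600)
  expect_equal(social_cost(matrix(0, 5, 5), p), 0)
  plan2 <- matrix(0, 5, 5)
  plan2[4, ] <- 2  # two of every grade in one cycle
  expect_equal(social_cost(plan2, p), 48600)
})

test_that("horizon bed floor slack uses raw bed coefficients", {
  g <- grade_params(paste0("g", 1:5), cost_coeff = 1, income_coeff = 1,
                    bed_coeff = rep(10, 5), min_share = 0)
  p <- care_problem(g, initial_beds = c(878, 0, 0, 0, 0), cycles = 1,
                    horizon_population = 10000, bed_rate_target = 0.06,
                    upper_bounds = 1)
  zero <- matrix(0, 1, 5)
  expect_equal(horizon_bed_floor(zero, p), 278)

  p0 <- care_problem(g, initial_beds = c(878, 0, 0, 0, 0), cycles = 1,
                     horizon_population = 10000, bed_rate_target = 0,
                     upper_bounds = 1)
  expect_equal(horizon_bed_floor(zero, p0), 878)

  pneg <- care_problem(g, initial_beds = rep(0, 5), cycles = 1,
                       horizon_population = 10000, bed_rate_target = 0.06,
                       upper_bounds = 1)
  expect_equal(horizon_bed_floor(zero, pneg), -600)
})

test_that("grade share floors measure each grade against total beds", {
  g <- grade_params(paste0("g", 1:5), cost_coeff = 1, income_coeff = 1,
                    bed_coeff = rep(10, 5), min_share = 0.15)
  p <- care_problem(g, initial_beds = rep(100, 5), cycles = 1,
                    horizon_population = 1, bed_rate_target = 0,
                    upper_bounds = 3)
  zero <- matrix(0, 1, 5)
  expect_equal(unname(grade_share_floors(zero, p)), rep(25, 5))

  g0 <- grade_params(paste0("g", 1:5), cost_coeff = 1, income_coeff = 1,
                     bed_coeff = rep(10, 5), min_share = 0)
  p0 <- care_problem(g0, initial_beds = c(40, 30, 20, 10, 5), cycles = 1,
                     horizon_population = 1, bed_rate_target = 0,
                     upper_bounds = 3)
  expect_equal(unname(grade_share_floors(zero, p0)), c(40, 30, 20, 10, 5))

  pc <- care_problem(g, initial_beds = c(500, 0, 0, 0, 0), cycles = 1,
                     horizon_population = 1, bed_rate_target = 0,
                     upper_bounds = 3)
  slack <- grade_share_floors(zero, pc)
  expect_equal(unname(slack[2:5]), rep(-0.15 * 500, 4))
})

test_that("cumulative beds track the running construction sum", {
  g <- grade_params("only", cost_coeff = 1, income_coeff = 1,
                    bed_coeff = 10, min_share = 0)
  p <- care_problem(g, initial_beds = 5, cycles = 3,
                    horizon_population = 1, bed_rate_target = 0,
                    upper_bounds = 5)
  x <- matrix(c(1, 2, 0), ncol = 1)
  expect_equal(unname(vapply(1:3, function(i) cumulative_beds(x, p, i),
                             numeric(1))),
               c(15, 35, 35))
  expect_equal(unname(cumulative_beds(matrix(0, 3, 1), p, 0)), 5)
  expect_equal(unname(cumulative_beds(matrix(0, 3, 1), p, 3)), 5)
  expect_error(cumulative_beds(x, p, 4), "out of range")

  q <- nanjing_problem("Qinhuai")
  expect_equal(unname(cumulative_beds(matrix(0, 5, 5), q, 0)),
               c(0, 1596, 1352, 525, 175))
})

test_that("per-cycle bed floors compare cumulative totals to cycle targets", {
  g <- grade_params("only", cost_coeff = 1, income_coeff = 1,
                    bed_coeff = 100, min_share = 0)
  p <- care_problem(g, initial_beds = 400, cycles = 5,
                    cycle_rate_targets = c(0.048, 0.051, 0.055, 0.059, 0.063),
                    reference_population = 10000,
                    upper_bounds = 10)
  plan <- matrix(c(1, 0, 0, 0, 0), ncol = 1)  # 500 beds from cycle 1 on
  slack <- per_cycle_bed_floors(plan, p)
  expect_equal(slack[1], 500 - 480)
  expect_equal(slack, 500 - c(0.048, 0.051, 0.055, 0.059, 0.063) * 10000)

  p0 <- care_problem(g, initial_beds = 400, cycles = 5,
                     cycle_rate_targets = rep(0, 5),
                     reference_population = 10000, upper_bounds = 10)
  expect_equal(per_cycle_bed_floors(plan, p0), rep(500, 5))
})

test_that("evaluate_plan bundles objectives and feasibility", {
  g <- grade_params(c("hi", "lo"), cost_coeff = c(2, 1),
                    income_coeff = c(3, 1), bed_coeff = c(10, 10),
                    min_share = 0.2)
  met <- care_problem(g, initial_beds = c(50, 50), cycles = 2,
                      horizon_population = 1000, bed_rate_target = 0.05,
                      upper_bounds = 3)
  ev <- evaluate_plan(matrix(0, 2, 2), met)
  expect_true(ev$feasible)
  expect_equal(unname(ev$objectives), c(0, 0))
  expect_equal(ev$total_violation, 0)

  unmet <- care_problem(g, initial_beds = c(0, 0), cycles = 2,
                        horizon_population = 1000, bed_rate_target = 0.05,
                        upper_bounds = 3)
  ev2 <- evaluate_plan(matrix(0, 2, 2), unmet)
  expect_false(ev2$feasible)
  expect_gt(ev2$total_violation, 0)

  plan <- matrix(c(1, 2, 3, 0), 2, 2)
  ev3 <- evaluate_plan(plan, met)
  expect_equal(ev3$objectives[["neg_benefit"]], -economic_benefit(plan, met))
  expect_equal(ev3$objectives[["cost"]], social_cost(plan, met))
  expect_equal(ev3$feasibility$slack[1], horizon_bed_floor(plan, met))
  expect_equal(ev3$feasibility$slack[2:3],
               unname(grade_share_floors(plan, met)))
})

test_that("objectives are linear and monotone in the plan", {
  p <- small_nanjing_like()
  withr::with_seed(7, {
    for (rep in 1:20) {
      x <- matrix(sample(0:3, 25, replace = TRUE), 5, 5)
      y <- matrix(sample(0:3, 25, replace = TRUE), 5, 5)
      ex <- evaluate_plan(x, p)$objectives
      ey <- evaluate_plan(y, p)$objectives
      exy <- evaluate_plan(x + y, p)$objectives
      expect_equal(exy, ex + ey)

      # adding one institution of a random grade in a random cycle
      x2 <- x
      i <- sample(5, 1); j <- sample(5, 1)
      x2[i, j] <- x2[i, j] + 1
      expect_gte(economic_benefit(x2, p), economic_benefit(x, p))
      expect_gte(social_cost(x2, p), social_cost(x, p))
      expect_gte(horizon_bed_floor(x2, p), horizon_bed_floor(x, p))
    }
  })
})

test_that("final cumulative beds decompose into initial stock plus built beds", {
  p <- small_nanjing_like()
  withr::with_seed(11, {
    for (rep in 1:10) {
      x <- matrix(sample(0:4, 25, replace = TRUE), 5, 5)
      final <- cumulative_beds(x, p, 5)
      expect_equal(unname(final - p$initial_beds),
                   unname(colSums(x) * p$grades$bed_coeff))
    }
  })
})

test_that("problems with jointly unsatisfiable shares are rejected at load", {
  expect_error(
    grade_params(c("a", "b"), cost_coeff = 1, income_coeff = 1,
                 bed_coeff = 1, min_share = c(0.6, 0.6)),
    "jointly unsatisfiable",
    class = "eldercap_config_error"
  )
})

test_that("plans round-trip between matrix and long tibble form", {
  p <- toy_problem(cycles = 3)
  x <- matrix(c(1, 0, 2, 4, 3, 0), nrow = 3)
  tbl <- plan_tibble(x, p)
  expect_equal(nrow(tbl), 6)
  expect_identical(unname(as_plan_matrix(tbl, p)), unname(x * 1.0))
  expect_error(as_plan_matrix(matrix(-1, 3, 2), p), "non-negative")
  expect_error(as_plan_matrix(matrix(0.5, 3, 2), p), "integers")
  expect_error(as_plan_matrix(matrix(9, 3, 2), p, check_bounds = TRUE),
               "upper bounds")
})
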