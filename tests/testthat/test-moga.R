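# Genetic-algorithm components and the full solver loop.

test_that("initial population is uniform within bounds and reproducible", {
  p0 <- toy_problem(bounds = 0)
  G0 <- initialize_population(p0, moga_config(population_size = 10, seed = 3))
  expect_true(all(G0 == 0))

  p <- toy_problem(bounds = 3, cycles = 2)
  cfg <- moga_config(population_size = 10000, seed = 5)
  G1 <- initialize_population(p, cfg)
  G2 <- initialize_population(p, cfg)
  expect_identical(G1, G2)
  for (j in seq_len(ncol(G1))) {
    freq <- tabulate(G1[, j] + 1, nbins = 4) / nrow(G1)
    expect_true(all(abs(freq - 0.25) < 0.02))
  }
})

test_that("constrained domination prefers feasibility, then objectives", {
  expect_true(dominates(c(1, 1), c(2, 2)))
  expect_false(dominates(c(1, 5), c(5, 1)))
  expect_false(dominates(c(5, 1), c(1, 5)))
  expect_false(dominates(c(1, 1), c(1, 1)))
  # feasible beats infeasible regardless of objectives
  expect_true(dominates(c(9, 9), c(1, 1), viol_u = 0, viol_v = 2))
  expect_false(dominates(c(1, 1), c(9, 9), viol_u = 2, viol_v = 0))
  # infeasibles compare by violation magnitude
  expect_true(dominates(c(9, 9), c(1, 1), viol_u = 1, viol_v = 2))
  expect_false(dominates(c(1, 1), c(9, 9), viol_u = 2, viol_v = 1))
})

test_that("non-dominated sorting matches the pairwise definition", {
  o1 <- c(1, 2, 5, 3)
  o2 <- c(5, 2, 1, 3)
  expect_equal(non_dominated_sort(o1, o2), c(1, 1, 1, 2))
  expect_equal(non_dominated_sort(3, 7), 1)
  expect_equal(non_dominated_sort(c(1, 2, 3), c(1, 2, 3)), c(1, 2, 3))

  # random populations: rank-1 must equal the brute pairwise non-dominated set
  withr::with_seed(9, {
    for (rep in 1:10) {
      a <- sample(1:6, 12, replace = TRUE)
      b <- sample(1:6, 12, replace = TRUE)
      v <- sample(0:1, 12, replace = TRUE) * stats::runif(12)
      rk <- non_dominated_sort(a, b, v)
      for (i in seq_along(a)) {
        dominated <- any(vapply(seq_along(a), function(j) {
          j != i && dominates(c(a[j], b[j]), c(a[i], b[i]), v[j], v[i])
        }, logical(1)))
        expect_identical(rk[i] == 1, !dominated)
      }
    }
  })
})

test_that("crowding distance rewards isolation and survives degeneracy", {
  expect_equal(crowding_distance(cbind(1, 2)), Inf)
  expect_equal(crowding_distance(cbind(c(1, 2), c(2, 1))), c(Inf, Inf))
  d <- crowding_distance(cbind(c(0, 1, 2), c(2, 1, 0)))
  expect_equal(d[2], 2)
  expect_equal(d[c(1, 3)], c(Inf, Inf))
  # duplicated objective values: zero interior gaps, no division error
  dup <- crowding_distance(cbind(c(1, 1, 1, 1), c(5, 5, 5, 5)))
  expect_true(all(is.finite(dup[2:3])) || all(is.infinite(dup)))
  expect_false(anyNA(dup))
})

test_that("roulette selection weights parents by reciprocal rank", {
  withr::with_seed(21, {
    sel_flat <- roulette_select(rep(1L, 4), 40000)
    freq <- tabulate(sel_flat, 4) / 40000
    expect_true(all(abs(freq - 0.25) < 0.01))

    sel <- roulette_select(c(1L, 2L), 1e5)
    expect_true(abs(mean(sel == 1) - 2 / 3) < 0.01)
    expect_true(abs(mean(sel == 2) - 1 / 3) < 0.01)
  })
  expect_error(roulette_select(integer(0), 1), "empty")
})

test_that("variation operators keep genomes integral and within bounds", {
  bounds <- c(0, 1, 3, 7)
  withr::with_seed(33, {
    a <- c(0, 1, 2, 5)
    b <- c(0, 0, 3, 7)
    kids <- eldercap:::crossover_genomes(a, b, rate = 0)
    expect_identical(kids[[1]], a)
    expect_identical(kids[[2]], b)
    expect_identical(eldercap:::mutate_genome(c(0, 0, 0, 0), rep(0, 4), 1),
                     c(0, 0, 0, 0))
    for (rep in 1:10000) {
      kids <- eldercap:::crossover_genomes(a, b, rate = 0.5)
      child <- eldercap:::mutate_genome(kids[[1]], bounds, rate = 0.5)
      expect_true(all(child == round(child)))
      expect_true(all(child >= 0 & child <= bounds))
    }
  })
  expect_identical(integer_repair(c(-0.4, 2.6, 9.2), c(5, 5, 5)), c(0, 3, 5))
})

test_that("2-D hypervolume equals the strip decomposition", {
  expect_equal(hypervolume_2d(cbind(c(1, 2, 5), c(5, 2, 1)), c(6, 6)), 18)
  expect_equal(hypervolume_2d(cbind(7, 7), c(6, 6)), 0)
  # dominated points do not change the volume
  expect_equal(hypervolume_2d(cbind(c(1, 2, 5, 4), c(5, 2, 1, 4)), c(6, 6)), 18)
})

test_that("the GA archive is contained in the exact Pareto set", {
  p <- toy_problem(bed_floor = 20, bounds = 4)
  oracle <- brute_force_pareto(p)
  res <- moga(p, moga_config(population_size = 30, generations = 200,
                             stagnation_window = 60, seed = 101))
  expect_true(res$feasible)
  expect_true(all(objective_keys(res$archive) %in% objective_keys(oracle$archive)))
  # containment also holds plan-by-plan
  okeys <- apply(dplyr::select(oracle$archive, dplyr::starts_with("x_")), 1,
                 paste, collapse = ",")
  akeys <- apply(dplyr::select(res$archive, dplyr::starts_with("x_")), 1,
                 paste, collapse = ",")
  expect_true(all(akeys %in% okeys))
})

test_that("identical problem, settings and seed reproduce the archive exactly", {
  p <- toy_problem(bounds = 3)
  cfg <- moga_config(population_size = 20, generations = 40, seed = 77)
  r1 <- moga(p, cfg)
  r2 <- moga(p, cfg)
  expect_identical(r1$archive, r2$archive)
  expect_identical(r1$history, r2$history)
})

test_that("archive members are mutually non-dominated and feasible", {
  p <- toy_problem(bed_floor = 20, bounds = 4, min_share = 0.2)
  res <- moga(p, moga_config(population_size = 30, generations = 100,
                             seed = 19))
  arc <- res$archive
  expect_gt(nrow(arc), 0)
  for (i in seq_len(nrow(arc))) {
    ev <- evaluate_plan(res$plans[[i]], p)
    expect_true(ev$feasible)
    expect_equal(ev$benefit, arc$benefit[i])
    expect_equal(ev$cost, arc$cost[i])
    for (j in seq_len(nrow(arc))) {
      if (i == j) next
      expect_false(dominates(c(-arc$benefit[j], arc$cost[j]),
                             c(-arc$benefit[i], arc$cost[i])))
    }
  }
})

test_that("archive hypervolume never decreases across generations", {
  p <- toy_problem(bed_floor = 20, bounds = 4)
  res <- moga(p, moga_config(population_size = 20, generations = 80,
                             seed = 5))
  expect_true(all(diff(res$history$hypervolume) >= 0))
})

test_that("a fully bounded-out problem returns the zero plan", {
  g <- grade_params("only", cost_coeff = 1, income_coeff = 1,
                    bed_coeff = 10, min_share = 0)
  p <- care_problem(g, initial_beds = 100, cycles = 1,
                    horizon_population = 100, bed_rate_target = 0.1,
                    upper_bounds = 0)
  res <- moga(p, moga_config(population_size = 10, generations = 5, seed = 1))
  expect_true(res$feasible)
  expect_equal(nrow(res$archive), 1)
  expect_true(all(res$plans[[1]] == 0))
})

test_that("infeasible-only searches are flagged", {
  g <- grade_params("only", cost_coeff = 1, income_coeff = 1,
                    bed_coeff = 1, min_share = 0)
  p <- care_problem(g, initial_beds = 0, cycles = 1,
                    horizon_population = 1000, bed_rate_target = 0.5,
                    upper_bounds = 2)  # needs 500 beds, at most 2 available
  res <- moga(p, moga_config(population_size = 10, generations = 5, seed = 2))
  expect_false(res$feasible)
})

test_that("GA evaluation agrees with the scalar objective functions", {
  p <- small_nanjing_like()
  withr::with_seed(13, {
    G <- eldercap:::init_genomes(as.vector(p$upper_bounds), 25)
    ev <- eldercap:::evaluate_genomes(G, p)
    for (i in c(1, 7, 25)) {
      x <- matrix(G[i, ], p$cycles, p$n_grades)
      expect_equal(-ev$obj1[i], economic_benefit(x, p))
      expect_equal(ev$obj2[i], social_cost(x, p))
      expect_equal(ev$violation[i], evaluate_plan(x, p)$total_violation)
    }
  })
})

test_that("tidy, glance and autoplot expose the archive", {
  p <- toy_problem(bounds = 3)
  res <- moga(p, moga_config(population_size = 15, generations = 30, seed = 4))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("benefit", "cost") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$archive_size, nrow(td))
  expect_s3_class(autoplot(res), "ggplot")
})
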