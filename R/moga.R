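#' Genetic-algorithm settings
#'
#' Settings for the elitist non-dominated-sorting integer GA. Defaults follow
#' the solver configuration used for the Nanjing analysis: population 100,
#' up to 500 generations, and a Pareto fraction of 0.8 so that the returned
#' archive holds at most `round(0.8 * population_size)` solutions.
#'
#' @param population_size Number of individuals per generation.
#' @param generations Maximum number of generations.
#' @param pareto_fraction Fraction of the population size returned as the
#'   archive cap, in `(0, 1]`.
#' @param crossover_rate Per-cell probability that a pair of children swap a
#'   cell during uniform crossover.
#' @param mutation_rate Per-cell probability that a child's cell is resampled
#'   uniformly within its bounds.
#' @param stagnation_window,stagnation_tol Early stopping: the run ends when
#'   the archive hypervolume has improved by less than `stagnation_tol` over
#'   the last `stagnation_window` generations.
#' @param seed Integer seed; the run is fully reproducible given the same
#'   problem, settings and seed.
#' @return A list of class `moga_config`.
#' @export
moga_config <- function(population_size = 100,
                        generations = 500,
                        pareto_fraction = 0.8,
                        crossover_rate = 0.5,
                        mutation_rate = 0.1,
                        stagnation_window = 50,
                        stagnation_tol = 1e-9,
                        seed = 1L) {
  if (population_size < 1) stop("population_size must be >= 1")
  if (generations < 1) stop("generations must be >= 1")
  if (pareto_fraction <= 0 || pareto_fraction > 1) {
    stop("pareto_fraction must lie in (0, 1]")
  }
  if (round(pareto_fraction * population_size) < 1) {
    stop("pareto_fraction x population_size must be >= 1")
  }
  if (crossover_rate < 0 || crossover_rate > 1 ||
      mutation_rate < 0 || mutation_rate > 1) {
    stop("crossover_rate and mutation_rate must lie in [0, 1]")
  }
  structure(
    list(
      population_size = as.integer(population_size),
      generations = as.integer(generations),
      pareto_fraction = pareto_fraction,
      crossover_rate = crossover_rate,
      mutation_rate = mutation_rate,
      stagnation_window = as.integer(stagnation_window),
      stagnation_tol = stagnation_tol,
      seed = as.integer(seed)
    ),
    class = "moga_config"
  )
}

#' Constrained Pareto dominance
#'
#' `u` dominates `v` when: `u` is feasible and `v` is not; both are
#' infeasible and `u` has strictly smaller total constraint violation; or
#' both are feasible and `u` is no worse in both (minimisation-convention)
#' objectives and strictly better in at least one. This feasible-first rule
#' needs no penalty weights.
#'
#' @param obj_u,obj_v Length-2 minimisation-convention objective vectors.
#' @param viol_u,viol_v Total constraint violations (0 when feasible).
#' @return `TRUE` if `u` dominates `v`.
#' @export
dominates <- function(obj_u, obj_v, viol_u = 0, viol_v = 0) {
  if (viol_u == 0 && viol_v > 0) return(TRUE)
  if (viol_u > 0 && viol_v == 0) return(FALSE)
  if (viol_u > 0 && viol_v > 0) return(viol_u < viol_v)
  all(obj_u <= obj_v) && any(obj_u < obj_v)
}

# Pairwise constrained-domination matrix: dom[i, j] is TRUE when i dominates
# j.  Vectorised over the population; O(n^2) memory, fine for GA populations.
domination_matrix <- function(obj1, obj2, violation) {
  n <- length(obj1)
  feas <- violation == 0
  le1 <- outer(obj1, obj1, `<=`)
  le2 <- outer(obj2, obj2, `<=`)
  lt1 <- outer(obj1, obj1, `<`)
  lt2 <- outer(obj2, obj2, `<`)
  pareto <- le1 & le2 & (lt1 | lt2)
  both_feas <- outer(feas, feas, `&`)
  both_inf <- outer(!feas, !feas, `&`)
  dom <- (both_feas & pareto) |
    outer(feas, !feas, `&`) |
    (both_inf & outer(violation, violation, `<`))
  diag(dom) <- FALSE
  dom
}

#' Non-dominated sorting
#'
#' Assigns each individual its Pareto rank under constrained domination:
#' rank 1 is the non-dominated set, rank r the set that becomes
#' non-dominated once ranks below r are removed.
#'
#' @param obj1,obj2 Minimisation-convention objective vectors.
#' @param violation Total constraint violations (defaults to all feasible).
#' @return Integer vector of ranks (>= 1).
#' @export
non_dominated_sort <- function(obj1, obj2, violation = rep(0, length(obj1))) {
  n <- length(obj1)
  dom <- domination_matrix(obj1, obj2, violation)
  n_dominators <- colSums(dom)
  rank <- integer(n)
  current <- 1L
  remaining <- rep(TRUE, n)
  while (any(remaining)) {
    front <- remaining & n_dominators == 0
    if (!any(front)) stop("internal error: no front found (cyclic dominance?)")
    rank[front] <- current
    remaining[front] <- FALSE
    # removing the front releases the individuals it dominated
    if (sum(front) == 1L) {
      n_dominators <- n_dominators - dom[front, ]
    } else {
      n_dominators <- n_dominators - colSums(dom[front, , drop = FALSE])
    }
    current <- current + 1L
  }
  rank
}

#' Crowding distance within a front
#'
#' Diversity measure of a mutually non-dominated front: per objective, the
#' front is sorted, boundary solutions get infinite distance, and each
#' interior solution gets the range-normalised gap between its neighbours;
#' distances are summed over the objectives. A zero-range objective
#' contributes 0 for every interior solution.
#'
#' @param obj Numeric matrix, one row per solution, one column per objective.
#' @return Numeric vector of crowding distances (may be `Inf`).
#' @export
crowding_distance <- function(obj) {
  obj <- as.matrix(obj)
  n <- nrow(obj)
  if (n == 0) stop("empty front")
  if (n <= 2) return(rep(Inf, n))
  d <- numeric(n)
  for (j in seq_len(ncol(obj))) {
    ord <- order(obj[, j])
    rng <- obj[ord[n], j] - obj[ord[1], j]
    d[ord[c(1, n)]] <- Inf
    if (rng > 0) {
      gaps <- (obj[ord[3:n], j] - obj[ord[1:(n - 2)], j]) / rng
      d[ord[2:(n - 1)]] <- d[ord[2:(n - 1)]] + gaps
    }
  }
  d
}

#' Roulette-wheel parent selection
#'
#' Samples parents with replacement, with probability proportional to the
#' rank-reciprocal fitness `1 / rank`. Crowding distance is not part of the
#' roulette weights; it only breaks ties during elitist truncation.
#'
#' @param rank Integer Pareto ranks.
#' @param n_draws Number of parents to draw.
#' @return Integer vector of selected indices.
#' @export
roulette_select <- function(rank, n_draws) {
  if (length(rank) == 0) stop("empty population")
  w <- 1 / rank
  sample.int(length(rank), n_draws, replace = TRUE, prob = w / sum(w))
}

# Uniform per-cell crossover on genome row-vectors: each cell swaps between
# the two children with probability rate.
crossover_genomes <- function(a, b, rate) {
  swap <- stats::runif(length(a)) < rate
  child_a <- ifelse(swap, b, a)
  child_b <- ifelse(swap, a, b)
  list(child_a, child_b)
}

# Per-cell mutation: resample a cell uniformly in 0..bound with probability
# rate.  Bound-0 cells can only resample to 0.
mutate_genome <- function(g, bounds, rate) {
  hit <- stats::runif(length(g)) < rate
  if (any(hit)) {
    g[hit] <- floor(stats::runif(sum(hit)) * (bounds[hit] + 1))
    g[hit] <- pmin(g[hit], bounds[hit])  # guard the p = 1 edge of runif
  }
  g
}

#' Repair a real-valued plan to an integer plan in bounds
#'
#' Rounds to the nearest integer and clips into `[0, upper_bound]` cell-wise.
#' The GA itself is integer-coded and never needs repair; this is the
#' rounding rule applied when externally supplied real-valued solutions are
#' fed into the pipeline.
#'
#' @param x Numeric matrix or vector.
#' @param bounds Matching upper bounds.
#' @return Integer-valued object of the same shape.
#' @export
integer_repair <- function(x, bounds) {
  pmin(pmax(round(x), 0), bounds)
}

#' Hypervolume of a 2-D minimisation front
#'
#' Area dominated by the front and bounded by the reference point. Points
#' not strictly better than the reference in both coordinates are ignored.
#'
#' @param obj Two-column matrix of minimisation-convention objectives.
#' @param ref Length-2 reference point, component-wise worse than the front.
#' @return Non-negative scalar.
#' @export
hypervolume_2d <- function(obj, ref) {
  obj <- as.matrix(obj)
  keep <- obj[, 1] < ref[1] & obj[, 2] < ref[2]
  obj <- obj[keep, , drop = FALSE]
  if (nrow(obj) == 0) return(0)
  rnk <- non_dominated_sort(obj[, 1], obj[, 2])
  obj <- obj[rnk == 1, , drop = FALSE]
  obj <- unique(obj)
  ord <- order(obj[, 1], obj[, 2])
  obj <- obj[ord, , drop = FALSE]
  f1 <- obj[, 1]
  f2 <- obj[, 2]
  widths <- diff(c(f1, ref[1]))
  sum(widths * (ref[2] - f2))
}

#' Random initial population of integer plans
#'
#' Draws `population_size` plans, every cell uniform on `{0, ..., bound}`,
#' reproducibly under the configuration's seed.
#'
#' @param problem A [care_problem()].
#' @param config A [moga_config()].
#' @return Integer matrix, one genome per row (column-major plan cells).
#' @export
initialize_population <- function(problem, config = moga_config()) {
  withr::with_seed(config$seed, {
    init_genomes(as.vector(problem$upper_bounds), config$population_size)
  })
}

init_genomes <- function(bounds, pop_n) {
  G <- matrix(0, nrow = pop_n, ncol = length(bounds))
  for (j in seq_along(bounds)) {
    G[, j] <- sample.int(bounds[j] + 1L, pop_n, replace = TRUE) - 1L
  }
  G
}

new_archive <- function() {
  list(genomes = NULL, obj1 = numeric(0), obj2 = numeric(0),
       violation = numeric(0))
}

# Merge candidate individuals into the running archive and re-filter to the
# constrained non-dominated set, deduplicating identical genomes.  When the
# non-dominated set outgrows `cap`, it is thinned by crowding distance
# (keeping the extremes, which have infinite crowding).
update_archive <- function(archive, genomes, obj1, obj2, violation,
                           cap = Inf) {
  G <- rbind(archive$genomes, genomes)
  o1 <- c(archive$obj1, obj1)
  o2 <- c(archive$obj2, obj2)
  v <- c(archive$violation, violation)
  # one representative genome per objective pair: duplicates add nothing to
  # the front and would crowd real trade-offs out of the capped archive
  dup <- duplicated(cbind(o1, o2, v))
  G <- G[!dup, , drop = FALSE]
  o1 <- o1[!dup]; o2 <- o2[!dup]; v <- v[!dup]
  rnk <- non_dominated_sort(o1, o2, v)
  keep <- which(rnk == 1)
  if (length(keep) > cap) {
    cd <- crowding_distance(cbind(o1[keep], o2[keep]))
    keep <- keep[order(-cd)[seq_len(cap)]]
    keep <- sort(keep)
  }
  list(genomes = G[keep, , drop = FALSE],
       obj1 = o1[keep], obj2 = o2[keep], violation = v[keep])
}

#' Solve a planning problem with the multi-objective integer GA
#'
#' Elitist non-dominated-sorting genetic algorithm over integer-coded plans.
#' Each generation: parents are drawn by rank-reciprocal roulette selection,
#' offspring are produced by uniform per-cell crossover and in-bounds
#' resampling mutation, the offspring are merged with the parents, and the
#' best `population_size` individuals by (Pareto rank, crowding distance)
#' survive. A running archive accumulates every non-dominated feasible
#' solution found; the run stops at `generations` or when the archive's
#' hypervolume stagnates. The returned archive holds at most
#' `round(pareto_fraction * population_size)` members, preferring higher
#' crowding distance when truncating.
#'
#' @param problem A [care_problem()].
#' @param config A [moga_config()].
#' @return An object of class `moga_result` with elements `archive` (tibble:
#'   one row per solution, flattened plan cells, `benefit`, `cost`),
#'   `plans` (list of plan matrices), `history` (per-generation hypervolume
#'   and front size), `feasible` (whether any feasible solution was found),
#'   `problem`, and `config`.
#' @export
moga <- function(problem, config = moga_config()) {
  stopifnot(inherits(problem, "care_problem"))
  withr::with_seed(config$seed, moga_run(problem, config))
}

moga_run <- function(problem, config) {
  m <- problem$cycles
  n <- problem$n_grades
  len <- m * n
  bounds <- as.vector(problem$upper_bounds)
  pop_n <- config$population_size

  # initial population: each cell uniform on {0..bound}
  G <- init_genomes(bounds, pop_n)
  ev <- evaluate_genomes(G, problem)
  rank <- non_dominated_sort(ev$obj1, ev$obj2, ev$violation)

  archive <- new_archive()
  archive_cap <- max(1000L, 4L * pop_n)
  archive <- update_archive(archive, G[rank == 1, , drop = FALSE],
                            ev$obj1[rank == 1], ev$obj2[rank == 1],
                            ev$violation[rank == 1], cap = archive_cap)
  # hypervolume reference: component-wise worst of the initial archive,
  # nudged so boundary points still contribute area
  feas0 <- archive$violation == 0
  ref_src <- if (any(feas0)) {
    cbind(archive$obj1[feas0], archive$obj2[feas0])
  } else {
    cbind(archive$obj1, archive$obj2)
  }
  ref <- apply(ref_src, 2, max) + pmax(1, abs(apply(ref_src, 2, max))) * 1e-3

  hv_history <- numeric(0)
  history <- vector("list", config$generations)
  gens_run <- 0L

  for (gen in seq_len(config$generations)) {
    parents <- roulette_select(rank, pop_n)
    child <- matrix(0, nrow = pop_n, ncol = len)
    for (p in seq(1, pop_n, by = 2)) {
      pa <- G[parents[p], ]
      pb <- G[parents[min(p + 1, pop_n)], ]
      kids <- crossover_genomes(pa, pb, config$crossover_rate)
      child[p, ] <- mutate_genome(kids[[1]], bounds, config$mutation_rate)
      if (p + 1 <= pop_n) {
        child[p + 1, ] <- mutate_genome(kids[[2]], bounds, config$mutation_rate)
      }
    }
    ev_child <- evaluate_genomes(child, problem)

    # merge parents and offspring, then elitist truncation
    Gm <- rbind(G, child)
    o1 <- c(ev$obj1, ev_child$obj1)
    o2 <- c(ev$obj2, ev_child$obj2)
    vl <- c(ev$violation, ev_child$violation)
    rk <- non_dominated_sort(o1, o2, vl)
    keep <- truncate_by_rank(Gm, cbind(o1, o2), rk, pop_n)
    G <- Gm[keep, , drop = FALSE]
    ev <- list(obj1 = o1[keep], obj2 = o2[keep], violation = vl[keep])
    rank <- non_dominated_sort(ev$obj1, ev$obj2, ev$violation)

    new1 <- rk == 1
    archive <- update_archive(archive, Gm[new1, , drop = FALSE],
                              o1[new1], o2[new1], vl[new1],
                              cap = archive_cap)

    feas <- archive$violation == 0
    hv <- if (any(feas)) {
      hypervolume_2d(cbind(archive$obj1[feas], archive$obj2[feas]), ref)
    } else 0
    hv_history <- c(hv_history, hv)
    history[[gen]] <- c(generation = gen, hypervolume = hv,
                        front_size = sum(rank == 1),
                        archive_size = length(archive$obj1))
    gens_run <- gen
    if (gen > config$stagnation_window) {
      improvement <- hv - hv_history[gen - config$stagnation_window]
      if (improvement < config$stagnation_tol) break
    }
  }

  feasible_found <- any(archive$violation == 0)
  out <- finalize_archive(archive, problem, config)
  structure(
    list(
      archive = out$tbl,
      plans = out$plans,
      history = dplyr::bind_rows(lapply(history[seq_len(gens_run)], as.list)),
      generations_run = gens_run,
      feasible = feasible_found,
      problem = problem,
      config = config
    ),
    class = "moga_result"
  )
}

# Standard NSGA-II survivor selection on the merged population: fill by
# ascending rank; break the boundary rank by descending crowding distance,
# then by genome lexicographic order so truncation is deterministic.
truncate_by_rank <- function(G, obj, rank, n_keep) {
  keep <- integer(0)
  for (r in sort(unique(rank))) {
    idx <- which(rank == r)
    if (length(keep) + length(idx) <= n_keep) {
      keep <- c(keep, idx)
    } else {
      slots <- n_keep - length(keep)
      cd <- crowding_distance(obj[idx, , drop = FALSE])
      lex <- do.call(order, c(as.data.frame(G[idx, , drop = FALSE]), list(decreasing = FALSE)))
      lex_rank <- order(lex)
      ord <- order(-cd, lex_rank)
      keep <- c(keep, idx[ord[seq_len(slots)]])
      break
    }
    if (length(keep) == n_keep) break
  }
  keep
}

# Cap the final archive at round(pareto_fraction * population_size) members,
# preferring high crowding distance, and package it as a tibble + plan list.
finalize_archive <- function(archive, problem, config) {
  feas <- archive$violation == 0
  if (any(feas)) {
    G <- archive$genomes[feas, , drop = FALSE]
    o1 <- archive$obj1[feas]
    o2 <- archive$obj2[feas]
  } else {
    G <- archive$genomes
    o1 <- archive$obj1
    o2 <- archive$obj2
  }
  cap <- round(config$pareto_fraction * config$population_size)
  if (nrow(G) > cap) {
    cd <- crowding_distance(cbind(o1, o2))
    lex <- do.call(order, c(as.data.frame(G), list(decreasing = FALSE)))
    lex_rank <- order(lex)
    ord <- order(-cd, lex_rank)
    sel <- sort(ord[seq_len(cap)])
    G <- G[sel, , drop = FALSE]
    o1 <- o1[sel]
    o2 <- o2[sel]
  }
  ord <- order(-o1, o2)  # ascending benefit
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
  tbl <- dplyr::bind_cols(
    tibble::tibble(solution = seq_len(nrow(G))),
    cells,
    tibble::tibble(benefit = -o1, cost = o2)
  )
  list(tbl = tbl, plans = plans)
}

#' @export
print.moga_result <- function(x, ...) {
  cat(sprintf(
    "<moga_result> %d archived solutions after %d generations (%s)\n",
    nrow(x$archive), x$generations_run,
    if (x$feasible) "feasible" else "NO feasible solution found"
  ))
  if (nrow(x$archive) > 0) {
    cat(sprintf("  benefit range: [%.6g, %.6g]\n",
                min(x$archive$benefit), max(x$archive$benefit)))
    cat(sprintf("  cost range:    [%.6g, %.6g]\n",
                min(x$archive$cost), max(x$archive$cost)))
  }
  invisible(x)
}
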