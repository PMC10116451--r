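# eldercap

Cycle-by-cycle capacity planning for graded elder-care institutions, written
for health-services operations researchers and municipal planners. The
package answers one question: **how many institutions of each quality grade
should a district build in each planning cycle** so that beds-per-capita
floors and equity constraints are met, economic benefit is as high as
possible, and social cost as low as possible.

It was built around the Nanjing elder-care system — five institution grades
(A up to AAAAA), five three-year construction cycles (2021–2035), and a
policy floor of 60 beds per 1,000 registered elderly by the end of 2035 —
and ships that parameterisation as a fixture, but every coefficient is
configurable.

## The model

The decision variable is a matrix of non-negative integers `x[i, j]`: the
number of grade-`j` institutions built in cycle `i` (`i = 1..M`,
`j = 1..N`). Two objectives are traded off:

- economic benefit `F1 = Σᵢ Σⱼ φᵢ · bⱼ · x[i,j]` (maximised), with `bⱼ` the
  per-institution income coefficient and `φᵢ` a per-cycle income factor
  (all 1 in the baseline);
- social cost `F2 = Σᵢ Σⱼ aⱼ · x[i,j]` (minimised), with `aⱼ` the
  per-institution construction-cost coefficient.

subject to, in the baseline ("horizon") mode:

- a bed floor at the end of the horizon,
  `Σⱼ d₀ⱼ + Σᵢ Σⱼ cⱼ · x[i,j] ≥ rate · P`, where `cⱼ` is beds per
  institution, `d₀ⱼ` the initial bed stock, and `rate · P` the policy target
  (e.g. 0.06 × the 2035 elderly population);
- per-grade share floors: each grade's final bed stock must hold at least a
  fraction `pⱼ` of total beds (15% per grade by default — five grades
  matching the five disposable-income quintiles, 75% of demand guaranteed).

The *smart-community* scenario halves the income coefficients from cycle 3
(robot-substituted services) and replaces the single horizon floor with
escalating per-cycle floors (48, 51, 55, 59, 63 beds per 1,000), each grade
share enforced on the cumulative bed mix of every cycle.

The integer program is solved with an elitist non-dominated-sorting genetic
algorithm (integer-coded genomes, roulette selection with rank-reciprocal
fitness, uniform crossover, in-bounds resampling mutation, constrained
domination for feasibility). One plan is then selected from the Pareto
archive by TOPSIS: normalise, weight (default 0.5/0.5), measure Euclidean
separations from the ideal and anti-ideal points, and maximise the relative
closeness `R = d⁻ / (d⁺ + d⁻)`.

## Worked example

```r
library(eldercap)

problem <- nanjing_problem("Xuanwu")      # baseline horizon-mode problem
fit <- moga(problem, moga_config(population_size = 100,
                                 generations = 200, seed = 2024))
fit
#> <moga_result> 80 archived solutions after 200 generations (feasible)
#>   benefit range: [2.02677e+07, 6.62851e+07]
#>   cost range:    [1.88105e+07, 6.34501e+07]

decision <- topsis_decide(fit, weights = c(0.5, 0.5))
decision
#> <topsis_result> 80 candidates, weights (0.5, 0.5)
#>   selected solution 37: benefit 3.86892e+07, cost 3.4184e+07, closeness 0.5330
```

The archive holds 80 mutually non-dominated construction plans
(`round(0.8 × 100)`, the Pareto-fraction cap): the benefit range shows the
achievable trade-off, from the cheapest feasible expansions to the most
profitable ones, and TOPSIS picks the plan whose weighted distance profile
sits closest to the ideal corner — here a mid-front compromise with
closeness 0.53. `tidy(fit)` returns the archive as a tibble,
`autoplot(fit)` draws the Pareto front, and
`plan_tibble(decision$selected_plan, problem)` gives the chosen
cycle-by-grade construction schedule. The smart-community variant is one
call away: `nanjing_problem("Xuanwu", "smart")`.

Everything is reproducible: the same problem, settings and seed give the
same archive, bit for bit. A command-line front end with `solve`, `decide`,
`scenario`, `synth` and `oracle` subcommands ships in `inst/scripts/eldercap`
(see `?eldercap_cli`).

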