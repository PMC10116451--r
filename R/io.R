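#' Load a planning problem from a config file or fixture
#'
#' Accepts either a fixture reference `"nanjing/<district>"` (for example
#' `"nanjing/Qinhuai"`; append `"@smart"` for the smart-community variant,
#' as in `"nanjing/Xuanwu@smart"`) or the path to a YAML config file with
#' blocks `grades`, `district`, `horizon`, and optionally `scenario`.
#' Configs are schema-checked at load time with field-level messages;
#' structurally infeasible configs (grade shares summing past 1) are
#' rejected here rather than at solve time.
#'
#' @param source Fixture reference or file path.
#' @return A [care_problem()]. GA settings and decision weights present in
#'   the config are attached as attributes `ga_config` and `weights`.
#' @export
load_problem <- function(source) {
  if (grepl("^nanjing/", source)) {
    ref <- sub("^nanjing/", "", source)
    parts <- strsplit(ref, "@", fixed = TRUE)[[1]]
    scenario <- if (length(parts) > 1 && parts[2] == "smart") "smart" else "baseline"
    return(nanjing_problem(parts[1], scenario = scenario))
  }
  if (!file.exists(source)) {
    config_abort(sprintf("config file not found: %s", source))
  }
  cfg <- yaml::read_yaml(source)
  parse_problem_config(cfg)
}

require_field <- function(cfg, field, where) {
  if (is.null(cfg[[field]])) {
    config_abort(sprintf("config: missing required field '%s' in %s", field, where))
  }
  cfg[[field]]
}

parse_problem_config <- function(cfg) {
  grades_raw <- require_field(cfg, "grades", "top level")
  gtbl <- tryCatch(
    dplyr::bind_rows(lapply(grades_raw, tibble::as_tibble)),
    error = function(e) config_abort("config: 'grades' must be a list of grade records")
  )
  for (f in c("grade", "cost_coeff", "income_coeff", "bed_coeff")) {
    if (is.null(gtbl[[f]])) {
      config_abort(sprintf("config: every grades entry needs field '%s'", f))
    }
  }
  if (is.null(gtbl$min_share)) gtbl$min_share <- 0
  grades <- grade_params(gtbl$grade, gtbl$cost_coeff, gtbl$income_coeff,
                         gtbl$bed_coeff, gtbl$min_share)

  district <- cfg$district %||% list()
  name <- district$name %||% "district"
  counts <- district$counts
  initial_beds <- district$initial_beds
  if (is.null(counts) && is.null(initial_beds)) {
    config_abort("config: district needs 'counts' or 'initial_beds'")
  }

  cycles <- cfg$cycles %||% 5
  horizon <- cfg$horizon %||% list()

  base <- care_problem(
    grades = grades,
    counts = counts,
    initial_beds = initial_beds,
    cycles = cycles,
    horizon_population = horizon$population,
    bed_rate_target = horizon$bed_rate_target %||% 0.06,
    income_factors = cfg$income_factors %||% 1,
    upper_bounds = parse_bounds(cfg$upper_bounds, cycles, nrow(grades)),
    district = name
  )

  problem <- base
  if (!is.null(cfg$scenario)) {
    sc <- cfg$scenario
    schedule <- require_field(sc, "schedule", "scenario")
    refpop <- require_field(sc, "reference_population", "scenario")
    problem <- build_smart_problem(
      base,
      switch_cycle = sc$switch_cycle %||% 3,
      income_factor = sc$income_factor %||% 0.5,
      schedule = unlist(schedule),
      reference_population = unlist(refpop)
    )
  }

  if (!is.null(cfg$ga)) {
    attr(problem, "ga_config") <- do.call(moga_config, cfg$ga)
  }
  if (!is.null(cfg$weights)) {
    w <- unlist(cfg$weights)
    if (length(w) != 2 || any(w <= 0)) {
      config_abort("config: 'weights' must be two positive numbers")
    }
    attr(problem, "weights") <- w / sum(w)
  }
  problem
}

parse_bounds <- function(b, cycles, n_grades) {
  if (is.null(b)) return(NULL)
  b <- unlist(b)
  if (length(b) == cycles * n_grades) {
    return(matrix(b, nrow = cycles, byrow = TRUE))
  }
  b
}

#' Write and read plan / archive / decision files
#'
#' Plans are written as CSV with columns `cycle`, `grade`, `count`; archives
#' as CSV with one row per solution (flattened plan cells followed by
#' `benefit` and `cost`); TOPSIS decisions as JSON holding the weights,
#' ideal and anti-ideal points, per-solution scores, and the selected
#' solution. Integer fields round-trip bit-exactly; real fields are written
#' with enough digits to round-trip to at least 12 significant digits.
#'
#' @param plan Plan matrix or long data frame.
#' @param problem The matching [care_problem()].
#' @param path Output file path.
#' @return The written path, invisibly (writers); a tibble (readers).
#' @name plan_io
NULL

#' @rdname plan_io
#' @export
write_plan <- function(plan, problem, path) {
  tbl <- plan_tibble(plan, problem)
  utils::write.csv(tbl, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname plan_io
#' @export
read_plan <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' @rdname plan_io
#' @param archive A `moga_result`, `pareto_oracle`, or archive tibble.
#' @export
write_archive <- function(archive, path) {
  if (inherits(archive, c("moga_result", "pareto_oracle"))) {
    archive <- archive$archive
  }
  tbl <- dplyr::mutate(archive, dplyr::across(
    dplyr::where(is.double), ~ formatC(.x, digits = 15, format = "g")
  ))
  utils::write.csv(tbl, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname plan_io
#' @export
read_archive <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' @rdname plan_io
#' @param decision A `topsis_result`.
#' @export
write_decision <- function(decision, path) {
  stopifnot(inherits(decision, "topsis_result"))
  out <- list(
    weights = as.list(decision$weights),
    ideal = unname(decision$ideal),
    anti_ideal = unname(decision$anti_ideal),
    selected = decision$selected,
    scores = decision$scores
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname plan_io
#' @export
read_decision <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Run manifest
#'
#' A small provenance record written next to every CLI output: a digest of
#' the resolved problem, the seed, the scenario mode, the package version
#' and a timestamp. Identical configs produce identical digests, so a run
#' can be reproduced from its manifest alone.
#'
#' @param problem The resolved [care_problem()].
#' @param seed Seed used for the run.
#' @param mode Free-text scenario/run label.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(problem, seed, mode = problem$mode) {
  core <- problem[c("district", "grades", "initial_beds", "cycles", "mode",
                    "horizon_population", "bed_rate_target",
                    "cycle_rate_targets", "reference_population",
                    "income_factors", "upper_bounds")]
  structure(
    list(
      config_digest = rlang::hash(core),
      seed = as.integer(seed),
      mode = mode,
      package_version = as.character(utils::packageVersion("eldercap")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    class = "run_manifest"
  )
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
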