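#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a GA result
#'
#' One row per archived Pareto solution: flattened plan cells, `benefit`,
#' and `cost`.
#'
#' @param x A `moga_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.moga_result <- function(x, ...) {
  x$archive
}

#' @rdname tidy.moga_result
#' @export
glance.moga_result <- function(x, ...) {
  tibble::tibble(
    archive_size = nrow(x$archive),
    generations_run = x$generations_run,
    feasible = x$feasible,
    hypervolume = if (nrow(x$history) > 0) {
      x$history$hypervolume[nrow(x$history)]
    } else NA_real_,
    benefit_min = if (nrow(x$archive)) min(x$archive$benefit) else NA_real_,
    benefit_max = if (nrow(x$archive)) max(x$archive$benefit) else NA_real_,
    cost_min = if (nrow(x$archive)) min(x$archive$cost) else NA_real_,
    cost_max = if (nrow(x$archive)) max(x$archive$cost) else NA_real_
  )
}

#' Tidy a TOPSIS decision
#'
#' One row per candidate: objectives, separations from the ideal and
#' anti-ideal points, relative closeness, and whether it was selected.
#'
#' @param x A `topsis_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.topsis_result <- function(x, ...) {
  x$scores
}

#' @rdname tidy.topsis_result
#' @export
glance.topsis_result <- function(x, ...) {
  sel <- x$scores[x$selected, ]
  tibble::tibble(
    n_candidates = nrow(x$scores),
    selected = x$selected,
    closeness = sel$closeness,
    benefit = sel$benefit,
    cost = sel$cost,
    weight_benefit = x$weights[["benefit"]],
    weight_cost = x$weights[["cost"]]
  )
}

#' Plot a Pareto archive
#'
#' Scatter of the archived solutions in objective space (economic benefit
#' against social cost).
#'
#' @param object A `moga_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.moga_result <- function(object, ...) {
  ggplot2::ggplot(object$archive, ggplot2::aes(x = .data$cost, y = .data$benefit)) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(
      x = "social cost", y = "economic benefit",
      title = sprintf("Pareto archive: %s", object$problem$district),
      subtitle = sprintf("%d solutions after %d generations",
                         nrow(object$archive), object$generations_run)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a TOPSIS decision
#'
#' Candidates in objective space, coloured by relative closeness, with the
#' selected solution highlighted.
#'
#' @param object A `topsis_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.topsis_result <- function(object, ...) {
  sel <- object$scores[object$selected, ]
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$cost, y = .data$benefit,
                               colour = .data$closeness)) +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = sel, shape = 21, size = 4, stroke = 1.2,
                        colour = "firebrick", fill = NA) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(
      x = "social cost", y = "economic benefit", colour = "closeness",
      title = "TOPSIS selection from the Pareto archive"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
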