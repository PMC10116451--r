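#' Column-normalise a decision matrix
#'
#' Divides each column by its Euclidean norm so that every objective column
#' has unit sum of squares. Objectives of wildly different magnitude thereby
#' become comparable before weighting.
#'
#' @param f Numeric matrix, one row per candidate solution, one column per
#'   objective (minimisation convention).
#' @return Matrix of the same shape with unit-norm columns.
#' @export
topsis_normalize <- function(f) {
  f <- as.matrix(f)
  norms <- sqrt(colSums(f^2))
  if (any(norms == 0)) {
    stop("decision matrix has an all-zero objective column; cannot normalise")
  }
  sweep(f, 2, norms, `/`)
}

#' Ideal and anti-ideal points
#'
#' With every column in minimisation (cost-type) convention, the ideal point
#' is the column-wise minimum of the weighted-normalised matrix and the
#' anti-ideal point the column-wise maximum.
#'
#' @param v Weighted-normalised decision matrix.
#' @return List with elements `ideal` and `anti_ideal`.
#' @export
topsis_ideal_points <- function(v) {
  v <- as.matrix(v)
  list(ideal = apply(v, 2, min), anti_ideal = apply(v, 2, max))
}

#' Relative closeness to the ideal point
#'
#' `R = d_minus / (d_plus + d_minus)`: 1 at the ideal point, 0 at the
#' anti-ideal. Rows with both separations zero (all candidates identical)
#' are defined as 0.5.
#'
#' @param d_plus,d_minus Separations from the ideal and anti-ideal points.
#' @return Numeric vector in `[0, 1]`.
#' @export
topsis_closeness <- function(d_plus, d_minus) {
  total <- d_plus + d_minus
  r <- ifelse(total == 0, 0.5, d_minus / total)
  pmin(pmax(r, 0), 1)
}

#' Select one solution from a Pareto archive by TOPSIS
#'
#' Runs the distance-to-ideal pipeline on the archive's objective pairs:
#' normalise each column to unit Euclidean norm, weight, locate the ideal
#' (column minima) and anti-ideal (column maxima) points, compute Euclidean
#' separations from each, and pick the solution with the largest relative
#' closeness `R = d_minus / (d_plus + d_minus)`. Both objectives are handled
#' in minimisation convention — negated benefit and cost — so "smaller is
#' better" holds for every column. Ties in `R` are broken by the lowest
#' solution index.
#'
#' @param archive A `moga_result`, or a data frame / matrix with columns
#'   `benefit` and `cost` (one row per candidate solution).
#' @param weights Positive objective weights `(benefit, cost)`; normalised to
#'   sum to 1 at entry. Default `c(0.5, 0.5)` weighs the two equally.
#' @return An object of class `topsis_result`: per-solution tibble
#'   (`scores`), the selected index and (when available) selected plan, and
#'   the intermediate matrices.
#' @examples
#' archive <- data.frame(benefit = c(10, 6, 2), cost = c(9, 4, 1))
#' topsis_decide(archive)
#' @export
topsis_decide <- function(archive, weights = c(0.5, 0.5)) {
  if (length(weights) != 2 || any(weights <= 0)) {
    stop("weights must be two positive numbers")
  }
  weights <- weights / sum(weights)

  plans <- NULL
  if (inherits(archive, "moga_result")) {
    plans <- archive$plans
    tbl <- archive$archive
  } else if (is.matrix(archive)) {
    tbl <- tibble::as_tibble(archive)
  } else {
    tbl <- archive
  }
  if (nrow(tbl) == 0) {
    rlang::abort("empty archive: nothing to decide between",
                 class = "eldercap_infeasible_error")
  }
  if (!all(c("benefit", "cost") %in% names(tbl))) {
    stop("archive must have columns 'benefit' and 'cost'")
  }

  # minimisation convention in both columns
  f <- cbind(neg_benefit = -tbl$benefit, cost = tbl$cost)

  if (nrow(f) == 1 || all(apply(f, 2, function(col) length(unique(col)) == 1))) {
    # degenerate archive: identical rows carry no information
    nmat <- tryCatch(topsis_normalize(f), error = function(e) f)
    v <- sweep(nmat, 2, weights, `*`)
    r <- rep(0.5, nrow(f))
    d_plus <- d_minus <- rep(0, nrow(f))
    ideal <- anti_ideal <- v[1, ]
  } else {
    nmat <- topsis_normalize(f)
    v <- sweep(nmat, 2, weights, `*`)
    pts <- topsis_ideal_points(v)
    ideal <- pts$ideal
    anti_ideal <- pts$anti_ideal
    d_plus <- sqrt(rowSums(sweep(v, 2, ideal, `-`)^2))
    d_minus <- sqrt(rowSums(sweep(v, 2, anti_ideal, `-`)^2))
    r <- topsis_closeness(d_plus, d_minus)
  }
  selected <- which.max(r)  # which.max returns the first maximum: lowest index

  scores <- tibble::tibble(
    solution = seq_len(nrow(f)),
    benefit = tbl$benefit,
    cost = tbl$cost,
    d_plus = d_plus,
    d_minus = d_minus,
    closeness = r,
    selected = seq_len(nrow(f)) == selected
  )
  structure(
    list(
      scores = scores,
      selected = selected,
      selected_plan = if (!is.null(plans)) plans[[selected]] else NULL,
      weights = stats::setNames(weights, c("benefit", "cost")),
      normalized = nmat,
      weighted = v,
      ideal = ideal,
      anti_ideal = anti_ideal
    ),
    class = "topsis_result"
  )
}

#' @export
print.topsis_result <- function(x, ...) {
  sel <- x$scores[x$selected, ]
  cat(sprintf(
    "<topsis_result> %d candidates, weights (%.3g, %.3g)\n",
    nrow(x$scores), x$weights[1], x$weights[2]
  ))
  cat(sprintf(
    "  selected solution %d: benefit %.6g, cost %.6g, closeness %.4f\n",
    x$selected, sel$benefit, sel$cost, sel$closeness
  ))
  invisible(x)
}
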