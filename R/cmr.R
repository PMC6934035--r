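#' Weighted isotonic regression
#'
#' The weighted least-squares nondecreasing fit to a sequence of
#' observations, computed by pool-adjacent-violators (PAVA): scan left to
#' right, pooling any adjacent blocks whose weighted means violate the
#' ordering into their weighted mean. The fit is the unique minimiser of
#' `sum(w * (obs - fit)^2)` over nondecreasing vectors; the returned `sse`
#' is that minimum, exactly 0 when the observations are already
#' nondecreasing. Monotonicity is weak: ties are permitted, which matters
#' for bounded rating means that frequently tie.
#'
#' @param values Numeric observations, in the order to be respected.
#' @param weights Positive weights, same length.
#' @return A list of class `monotone_fit` with `fitted` (nondecreasing) and
#'   `sse`.
#' @examples
#' isotonic(c(1, 3, 2))           # pools the violating pair to 2.5
#' isotonic(c(3, 1), c(1, 3))     # weighted pool at 1.5
#' @export
isotonic <- function(values, weights = rep(1, length(values))) {
  if (length(values) == 0) {
    abort("empty input to isotonic regression",
          class = "statrace_domain_error")
  }
  if (length(weights) != length(values) || any(weights <= 0)) {
    abort("weights must be positive and match values in length",
          class = "statrace_domain_error")
  }
  fit <- pava_cpp(as.double(values), as.double(weights))
  structure(list(fitted = fit$fitted, sse = fit$sse),
            class = "monotone_fit")
}

#' @export
print.monotone_fit <- function(x, ...) {
  cat("Isotonic fit:", paste(signif(x$fitted, 4), collapse = " "),
      sprintf(" (sse %.6g)\n", x$sse))
  invisible(x)
}

new_cmr_result <- function(points, ord, fit_1d, fit_2d, method,
                           n_starts = NA_integer_) {
  fx <- isotonic(points$x[ord], points$wx[ord])
  fy <- isotonic(points$y[ord], points$wy[ord])
  fitted_x <- fitted_y <- numeric(nrow(points))
  fitted_x[ord] <- fx$fitted
  fitted_y[ord] <- fy$fitted
  structure(list(
    points = points, order = ord,
    fitted_x = fitted_x, fitted_y = fitted_y,
    fit_1d = fit_1d, fit_2d = fit_2d,
    statistic = max(fit_1d - fit_2d, 0),
    method = method, n_starts = n_starts
  ), class = "cmr_result")
}

#' Coupled monotonic regression by exhaustive enumeration
#'
#' The one-dimensional model of a state trace says a single latent order of
#' the units makes both outcome variables nondecreasing. Its lack of fit is
#' `fit_1d = min over orders pi of isotonic(x[pi], wx[pi])$sse +
#' isotonic(y[pi], wy[pi])$sse`. This routine minimises by enumerating all
#' `n!` orders, guaranteeing the global minimum; ties between optimal
#' orders are broken by the lexicographically smallest permutation. The
#' two-dimensional alternative lets each variable take its own order, so
#' its fit is 0 and the test statistic equals `fit_1d` (see [fit_2d()] for
#' constrained alternatives).
#'
#' @param points A tibble of state-trace points (`unit_id`, `x`, `y`, `wx`,
#'   `wy`), as from [state_trace_points()].
#' @param exact_n_max Refuse instances larger than this (default 9;
#'   9! orders is sub-second, sizes beyond that belong to
#'   [coupled_fit_heuristic()]).
#' @return A `cmr_result`: the best common order, fitted monotone values
#'   per unit, `fit_1d`, `fit_2d`, and `statistic = fit_1d - fit_2d`.
#' @examples
#' pts <- tibble::tibble(unit_id = c("a", "b"), x = c(0, 1), y = c(1, 0),
#'                       wx = 1, wy = 1)
#' coupled_fit_exact(pts)$fit_1d  # 0.5: either order pools one coordinate
#' @export
coupled_fit_exact <- function(points, exact_n_max = 9) {
  points <- validate_points(points)
  n <- nrow(points)
  if (n > exact_n_max) {
    abort(paste0("n = ", n, " exceeds exact_n_max = ", exact_n_max,
                 "; use coupled_fit_heuristic()"),
          class = "statrace_size_error")
  }
  res <- cmr_exact_cpp(points$x, points$y, points$wx, points$wy)
  new_cmr_result(points, res$order, res$sse, 0, "exact")
}

#' Coupled monotonic regression by multi-start local search
#'
#' Minimises the same joint lack of fit as [coupled_fit_exact()] without
#' enumerating `n!` orders: local search over permutations using adjacent
#' transpositions and single-element insertions, started from the order by
#' x, by y, by the average of the two rank vectors, and `restarts` random
#' shuffles. Jointly monotone data terminate immediately at the order-by-x
#' start with statistic 0. The heuristic fit can never beat the exact
#' minimum; on small instances it should match it (a property the test
#' suite pins against the enumeration).
#'
#' @inheritParams coupled_fit_exact
#' @param restarts Number of random restarts after the three deterministic
#'   starts.
#' @param seed Optional integer seed for the random restarts.
#' @return A `cmr_result` with `method = "heuristic"` and the number of
#'   search starts actually run in `n_starts`.
#' @export
coupled_fit_heuristic <- function(points, restarts = 20, seed = NULL) {
  points <- validate_points(points)
  local_seed_if(seed)
  n <- nrow(points)
  starts <- rbind(order(points$x, points$y),
                  order(points$y, points$x),
                  order(rank(points$x) + rank(points$y)))
  res <- cmr_heuristic_cpp(points$x, points$y, points$wx, points$wy,
                           starts, as.integer(restarts))
  new_cmr_result(points, res$order, res$sse, 0, "heuristic",
                 n_starts = res$n_starts)
}

#' Fit the one-dimensional state-trace model
#'
#' Dispatcher used throughout the package: exact enumeration up to
#' `exact_n_max` units, multi-start local search above.
#'
#' @inheritParams coupled_fit_heuristic
#' @inheritParams coupled_fit_exact
#' @return A `cmr_result`.
#' @export
coupled_fit <- function(points, exact_n_max = 9, restarts = 20, seed = NULL) {
  if (nrow(points) <= exact_n_max) {
    coupled_fit_exact(points, exact_n_max = exact_n_max)
  } else {
    coupled_fit_heuristic(points, restarts = restarts, seed = seed)
  }
}

#' Lack of fit of the two-dimensional model
#'
#' With no order constraints each variable may take its own order, so the
#' two-dimensional model fits perfectly and its lack of fit is exactly 0 --
#' the default alternative, under which the test statistic reduces to
#' `fit_1d`. A set of a-priori ordering constraints (pairs of units that
#' must be ordered, a "trace factor") restricts the alternative: the fit is
#' then the sum of each variable's least-squares monotone fit under the
#' partial order, computed by quadratic programming. A cyclic constraint
#' set is unsatisfiable and an error.
#'
#' @param points State-trace points.
#' @param partial_order Optional two-column matrix or data frame of
#'   `unit_id` pairs `(before, after)`.
#' @return The weighted SSE of the constrained two-dimensional model.
#' @export
fit_2d <- function(points, partial_order = NULL) {
  points <- validate_points(points)
  if (is.null(partial_order) || NROW(partial_order) == 0) return(0)
  po <- as.matrix(as.data.frame(partial_order))
  ids <- points$unit_id
  i <- match(po[, 1], ids)
  j <- match(po[, 2], ids)
  if (anyNA(i) || anyNA(j)) {
    abort("partial_order names unknown unit_id(s)",
          class = "statrace_domain_error")
  }
  check_acyclic(i, j, nrow(points))
  sse_constrained(points$x, points$wx, i, j) +
    sse_constrained(points$y, points$wy, i, j)
}

# Kahn's algorithm; errors on a cycle.
check_acyclic <- function(from, to, n) {
  indeg <- tabulate(to, n)
  adj <- split(to, factor(from, levels = seq_len(n)))
  queue <- which(indeg == 0)
  seen <- 0
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]; seen <- seen + 1
    for (w in adj[[v]]) {
      indeg[w] <- indeg[w] - 1
      if (indeg[w] == 0) queue <- c(queue, w)
    }
  }
  if (seen < n) {
    abort("partial_order constraints contain a cycle",
          class = "statrace_domain_error")
  }
  invisible(TRUE)
}

# least-squares fit of v under pairwise constraints fit[i] <= fit[j],
# as a QP: min sum w (v - f)^2 s.t. f[i] - f[j] <= 0
sse_constrained <- function(v, w, i, j, n = length(v)) {
  A <- matrix(0, length(i), n)
  A[cbind(seq_along(i), i)] <- 1
  A[cbind(seq_along(j), j)] <- -1
  sol <- pracma::quadprog(2 * diag(w), -2 * w * v, A = A,
                          b = rep(0, length(i)))
  sum(w * (v - sol$xmin)^2)
}

validate_points <- function(points) {
  points <- tibble::as_tibble(points)
  if (!all(c("x", "y") %in% names(points))) {
    abort("points need columns x and y", class = "statrace_domain_error")
  }
  if (!"unit_id" %in% names(points)) {
    points$unit_id <- sprintf("u%02d", seq_len(nrow(points)))
  }
  if (!"wx" %in% names(points)) points$wx <- 1
  if (!"wy" %in% names(points)) points$wy <- 1
  points$wx <- rep_len(as.double(points$wx), nrow(points))
  points$wy <- rep_len(as.double(points$wy), nrow(points))
  if (nrow(points) < 2) {
    abort("need at least 2 state-trace points",
          class = "statrace_domain_error")
  }
  if (any(points$wx <= 0) || any(points$wy <= 0)) {
    abort("weights must be positive", class = "statrace_domain_error")
  }
  points
}

#' @export
print.cmr_result <- function(x, ...) {
  cat(sprintf(
    "Coupled monotonic regression (%s): fit_1d %.6g, fit_2d %.6g, statistic %.6g\n",
    x$method, x$fit_1d, x$fit_2d, x$statistic))
  cat("  common order:", paste(x$points$unit_id[x$order], collapse = " < "),
      "\n")
  invisible(x)
}

#' @describeIn coupled_fit_exact One row per unit: observed and fitted
#'   coordinates and the unit's position in the best common order.
#' @param x A `cmr_result`.
#' @param ... Unused.
#' @method tidy cmr_result
#' @export
tidy.cmr_result <- function(x, ...) {
  pts <- x$points
  fx <- x$fitted_x
  fy <- x$fitted_y
  pos <- order(x$order)
  tibble::tibble(
    unit_id = pts$unit_id,
    x = pts$x, y = pts$y,
    wx = pts$wx, wy = pts$wy,
    fitted_x = fx, fitted_y = fy,
    position = pos
  )
}

#' @describeIn coupled_fit_exact One-row model summary.
#' @method glance cmr_result
#' @export
glance.cmr_result <- function(x, ...) {
  tibble::tibble(
    n_units = nrow(x$points),
    fit_1d = x$fit_1d, fit_2d = x$fit_2d, statistic = x$statistic,
    method = x$method, n_starts = x$n_starts
  )
}
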