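#' Finite-support competition strategies
#'
#' A species' strategy is a distribution of competitive abilities on
#' \eqn{[0,1]} scaled by its population abundance. In the finite-support
#' (discrete) model a strategy is a map \eqn{B} from an ordered set of
#' ability values \eqn{x_1 < \dots < x_J} (canonically the grid
#' \eqn{x_j = j/M}) to nonnegative weights, with total abundance
#' \eqn{|B| = \sum_j B(x_j) > 0}. The mean competitive ability
#' \eqn{MCA(B) = |B|^{-1} \sum_j x_j B(x_j)} is constrained to at most
#' \eqn{1/2}: individuals are not perfect.
#'
#' Arbitrary finite supports are accepted, a superset of the canonical
#' grid, so that designer strategies whose compensating ability falls off
#' the grid (e.g. Lake Wobegon) are represented exactly. The payoff
#' engine merges supports before evaluating communities.
#'
#' @param support Numeric vector of ability values in \eqn{[0,1]},
#'   strictly increasing.
#' @param weights Nonnegative weights, one per support point; their sum
#'   is the population abundance and must be positive.
#' @param label Identifier string for the species.
#'
#' @return An object of class `discrete_strategy`: a validated list with
#'   elements `support`, `weights` and `label`.
#' @seealso [make_uniform()], [make_invariant()], [make_lake_wobegon()],
#'   [make_bimodal()], [make_truncated_gaussian()], [mca()]
#' @examples
#' s <- discrete_strategy(c(0, 0.5, 1), c(1, 2, 1), "example")
#' mca(s)
#' @export
discrete_strategy <- function(support, weights, label = "strategy") {
  s <- structure(
    list(
      support = as.numeric(support),
      weights = as.numeric(weights),
      label = as.character(label)[1]
    ),
    class = "discrete_strategy"
  )
  validate_strategy(s)
}

#' Continuous competition strategies
#'
#' In the continuous model a strategy is a nonnegative density \eqn{f} on
#' \eqn{[0,1]} with abundance \eqn{F(1) = \int_0^1 f > 0} and
#' \eqn{MCA(f) = F(1)^{-1} \int_0^1 x f(x)\,dx \le 1/2}. Densities may be
#' given either as piecewise polynomials (all payoff and moment integrals
#' are then evaluated exactly) or as an arbitrary callable (adaptive
#' quadrature, absolute tolerance `1e-10`).
#'
#' @param density A function of one vectorised argument returning the
#'   density, or `NULL` when `pieces` is supplied.
#' @param pieces Optional exact representation: a list with `breaks` (an
#'   increasing vector from 0 to 1) and `coefs` (a list of ascending-degree
#'   polynomial coefficient vectors, one per segment).
#' @param label Identifier string.
#' @return An object of class `continuous_strategy`.
#' @examples
#' flat <- continuous_constant(2)        # abundance 2, MCA 1/2
#' ramp <- continuous_strategy(function(x) 2 * (1 - x), label = "ramp")
#' mca(ramp)
#' @export
continuous_strategy <- function(density = NULL, pieces = NULL, label = "strategy") {
  if (is.null(density) && is.null(pieces)) {
    rlang::abort("supply `density` or `pieces`", class = "heterogame_error_validation")
  }
  if (!is.null(pieces)) {
    stopifnot(is.list(pieces), !is.null(pieces$breaks), !is.null(pieces$coefs))
    breaks <- as.numeric(pieces$breaks)
    if (abs(breaks[1]) > 1e-12 || abs(breaks[length(breaks)] - 1) > 1e-12 ||
        any(diff(breaks) <= 0)) {
      rlang::abort("piece breaks must increase from 0 to 1",
        class = "heterogame_error_validation")
    }
    pieces <- list(breaks = breaks, coefs = lapply(pieces$coefs, as.numeric))
    if (is.null(density)) density <- pw_as_function(pieces)
  }
  s <- structure(
    list(density = density, pieces = pieces, label = as.character(label)[1]),
    class = "continuous_strategy"
  )
  validate_strategy(s)
}

#' @rdname continuous_strategy
#' @param value Positive constant density level; the abundance is `value`
#'   and the MCA is exactly 1/2. Positive constant densities are exactly
#'   the equilibrium strategies of the continuous model.
#' @export
continuous_constant <- function(value, label = paste0("const_", format(value))) {
  if (!is.numeric(value) || length(value) != 1 || value <= 0) {
    rlang::abort("constant density level must be a positive number",
      class = "heterogame_error_validation")
  }
  continuous_strategy(
    pieces = list(breaks = c(0, 1), coefs = list(value)),
    label = label
  )
}

#' @rdname continuous_strategy
#' @param x,y Breakpoints in \eqn{[0,1]} (first 0, last 1) and density
#'   values at them; the density interpolates linearly and is handled
#'   exactly.
#' @export
continuous_piecewise_linear <- function(x, y, label = "piecewise_linear") {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) == length(y), length(x) >= 2)
  coefs <- vector("list", length(x) - 1)
  for (i in seq_len(length(x) - 1)) {
    slope <- (y[i + 1] - y[i]) / (x[i + 1] - x[i])
    coefs[[i]] <- c(y[i] - slope * x[i], slope)  # a + b x on [x_i, x_{i+1}]
  }
  continuous_strategy(pieces = list(breaks = x, coefs = coefs), label = label)
}

# Tolerance on the MCA <= 1/2 constraint, absorbing floating-point
# construction error.
MCA_TOL <- 1e-9

#' Validate a strategy
#'
#' Checks the defining constraints: support values in \eqn{[0,1]} and
#' strictly increasing, nonnegative weights (or density), positive total
#' abundance, and mean competitive ability at most \eqn{1/2} (tolerance
#' `1e-9`). Called by every constructor; returns its input invisibly
#' unchanged so it can be chained.
#'
#' @param strategy A `discrete_strategy` or `continuous_strategy`.
#' @return The validated strategy, invisibly.
#' @export
validate_strategy <- function(strategy) {
  UseMethod("validate_strategy")
}

#' @export
validate_strategy.discrete_strategy <- function(strategy) {
  sup <- strategy$support
  w <- strategy$weights
  if (length(sup) == 0 || length(sup) != length(w)) {
    rlang::abort("support and weights must be non-empty and equal length",
      class = "heterogame_error_validation")
  }
  if (anyNA(sup) || anyNA(w)) {
    rlang::abort("support and weights must not contain NA",
      class = "heterogame_error_validation")
  }
  if (any(sup < 0) || any(sup > 1)) {
    rlang::abort("competitive abilities must lie in [0, 1]",
      class = "heterogame_error_validation")
  }
  if (any(diff(sup) <= 0)) {
    rlang::abort("support values must be strictly increasing",
      class = "heterogame_error_validation")
  }
  if (any(w < 0)) {
    rlang::abort("weights must be nonnegative",
      class = "heterogame_error_validation")
  }
  if (sum(w) <= 0) {
    rlang::abort(
      "total abundance must be positive: a species whose population abundance is zero cannot compete",
      class = "heterogame_error_validation"
    )
  }
  m <- sum(sup * w) / sum(w)
  if (m > 0.5 + MCA_TOL) {
    rlang::abort(
      sprintf("mean competitive ability %.6g exceeds the 1/2 bound", m),
      class = "heterogame_error_mca"
    )
  }
  invisible(strategy)
}

#' @export
validate_strategy.continuous_strategy <- function(strategy) {
  probe <- seq(0, 1, length.out = 101)
  vals <- strategy$density(probe)
  if (anyNA(vals) || any(vals < -1e-12)) {
    rlang::abort("density must be nonnegative on [0, 1]",
      class = "heterogame_error_validation")
  }
  ab <- total_abundance(strategy)
  if (!is.finite(ab) || ab <= 0) {
    rlang::abort(
      "abundance F(1) must be positive: a species whose population abundance is zero cannot compete",
      class = "heterogame_error_validation"
    )
  }
  m <- mca(strategy)
  if (m > 0.5 + MCA_TOL) {
    rlang::abort(
      sprintf("mean competitive ability %.6g exceeds the 1/2 bound", m),
      class = "heterogame_error_mca"
    )
  }
  invisible(strategy)
}

#' Strategy summaries: abundance, mean competitive ability, probabilities
#'
#' `total_abundance()` returns \eqn{|B|} (discrete) or \eqn{F(1)}
#' (continuous); `mca()` the abundance-weighted mean competitive ability;
#' `as_probabilities()` the normalized weight vector \eqn{B/|B|}, which
#' sums to one and is the distribution individuals are drawn from in the
#' simulator.
#'
#' @param strategy A strategy object.
#' @return A scalar for `total_abundance()` and `mca()`; for
#'   `as_probabilities()` a numeric vector aligned with the support.
#' @examples
#' mca(make_uniform(10, 1))            # 0.5 by symmetry
#' as_probabilities(make_lake_wobegon(10, 0.5, 100))
#' @export
mca <- function(strategy) UseMethod("mca")

#' @export
mca.discrete_strategy <- function(strategy) {
  sum(strategy$support * strategy$weights) / sum(strategy$weights)
}

#' @export
mca.continuous_strategy <- function(strategy) {
  first_moment <- if (!is.null(strategy$pieces)) {
    pw_moment(strategy$pieces, 1)
  } else {
    quad(function(x) x * strategy$density(x))
  }
  first_moment / total_abundance(strategy)
}

#' @rdname mca
#' @export
total_abundance <- function(strategy) UseMethod("total_abundance")

#' @export
total_abundance.discrete_strategy <- function(strategy) sum(strategy$weights)

#' @export
total_abundance.continuous_strategy <- function(strategy) {
  if (!is.null(strategy$pieces)) pw_moment(strategy$pieces, 0) else quad(strategy$density)
}

#' @rdname mca
#' @export
as_probabilities <- function(strategy) UseMethod("as_probabilities")

#' @export
as_probabilities.discrete_strategy <- function(strategy) {
  strategy$weights / sum(strategy$weights)
}

#' @export
print.discrete_strategy <- function(x, ...) {
  cat(sprintf(
    "<discrete_strategy> %s: %d support point%s, abundance %.6g, MCA %.6g\n",
    x$label, length(x$support), if (length(x$support) == 1) "" else "s",
    total_abundance(x), mca(x)
  ))
  invisible(x)
}

#' @export
print.continuous_strategy <- function(x, ...) {
  cat(sprintf(
    "<continuous_strategy> %s (%s): abundance %.6g, MCA %.6g\n",
    x$label, if (is.null(x$pieces)) "callable" else "piecewise polynomial",
    total_abundance(x), mca(x)
  ))
  invisible(x)
}

# --- piecewise-polynomial helpers (coefficients in ascending degree) ----

poly_eval <- function(coef, x) {
  out <- numeric(length(x))
  for (k in rev(seq_along(coef))) out <- out * x + coef[k]
  out
}

poly_mul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    idx <- i + seq_along(b) - 1
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# antiderivative with zero constant term
poly_antider <- function(coef) c(0, coef / seq_along(coef))

pw_as_function <- function(pieces) {
  force(pieces)
  function(x) {
    idx <- findInterval(x, pieces$breaks, rightmost.closed = TRUE, all.inside = TRUE)
    out <- numeric(length(x))
    for (seg in unique(idx)) {
      sel <- idx == seg
      out[sel] <- poly_eval(pieces$coefs[[seg]], x[sel])
    }
    out
  }
}

# integral over [0,1] of x^k * f(x) for piecewise-polynomial f, exact
pw_moment <- function(pieces, k) {
  xk <- c(numeric(k), 1)
  if (k == 0) xk <- 1
  total <- 0
  for (seg in seq_along(pieces$coefs)) {
    p <- poly_antider(poly_mul(xk, pieces$coefs[[seg]]))
    a <- pieces$breaks[seg]; b <- pieces$breaks[seg + 1]
    total <- total + poly_eval(p, b) - poly_eval(p, a)
  }
  total
}

# adaptive quadrature wrapper with the engine-wide absolute tolerance
quad <- function(f, lower = 0, upper = 1, abs.tol = 1e-10) {
  res <- stats::integrate(function(x) f(x), lower, upper,
    abs.tol = abs.tol, rel.tol = 1e-10, subdivisions = 500L
  )
  if (res$message != "OK") {
    rlang::abort(
      sprintf("quadrature failed: %s (estimated error %.3g)",
        res$message, res$abs.error),
      class = "heterogame_error_numeric"
    )
  }
  res$value
}
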