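#' Named strategy constructors
#'
#' Constructors for the strategy shapes used throughout the competition
#' experiments: uniform (maximal phenotypic heterogeneity — the canonical
#' equilibrium strategy), invariant/degenerate (no heterogeneity), the
#' Lake Wobegon designer distribution, and bimodal and truncated-gaussian
#' shapes common in ecological models.
#'
#' @param M Grid resolution: support is the canonical grid
#'   \eqn{x_j = j/M}, \eqn{j = 0, \dots, M}.
#' @param abundance Positive total population abundance.
#' @param label Species label.
#' @return A [discrete_strategy()].
#' @name strategy-constructors
NULL

check_abundance <- function(abundance) {
  if (!is.numeric(abundance) || length(abundance) != 1 || !is.finite(abundance) ||
      abundance <= 0) {
    rlang::abort("abundance must be a positive number",
      class = "heterogame_error_validation")
  }
}

canonical_grid <- function(M) {
  if (!is.numeric(M) || length(M) != 1 || M < 1 || M != round(M)) {
    rlang::abort("M must be an integer >= 1",
      class = "heterogame_error_validation")
  }
  (0:M) / M
}

#' @describeIn strategy-constructors Equal weight on every grid point;
#'   all abilities between 0 and 1 equally likely, MCA exactly 1/2 by
#'   symmetry.
#' @export
make_uniform <- function(M, abundance = 1, label = "uniform") {
  check_abundance(abundance)
  grid <- canonical_grid(M)
  discrete_strategy(grid, rep(abundance / (M + 1), M + 1), label)
}

#' @describeIn strategy-constructors All individuals share the single
#'   ability `value` (a degenerate distribution); the MCA constraint
#'   forces `value <= 1/2`.
#' @param value Competitive ability shared by all individuals.
#' @export
make_invariant <- function(value, abundance = 1, label = "invariant") {
  check_abundance(abundance)
  if (!is.numeric(value) || length(value) != 1 || value < 0 || value > 1) {
    rlang::abort("value must lie in [0, 1]", class = "heterogame_error_validation")
  }
  if (value > 0.5 + MCA_TOL) {
    rlang::abort("an invariant strategy at value > 1/2 violates the MCA bound",
      class = "heterogame_error_mca")
  }
  discrete_strategy(value, abundance, label)
}

#' @describeIn strategy-constructors Designer two-point distribution: one
#'   individual in `n` has ability 0, the remaining `n - 1` share the
#'   compensating ability `m = target_mca * n / (n - 1)`, so the MCA
#'   equals `target_mca` exactly ("all the children except one are above
#'   average"). Infeasible when `m > 1`.
#' @param n Population size the two-point split refers to (`>= 2`).
#' @param target_mca Desired mean competitive ability in `(0, 1/2]`.
#' @export
make_lake_wobegon <- function(n, target_mca = 0.5, abundance = 1,
                              label = "lake_wobegon") {
  check_abundance(abundance)
  if (!is.numeric(n) || length(n) != 1 || n < 2 || n != round(n)) {
    rlang::abort("n must be an integer >= 2", class = "heterogame_error_validation")
  }
  if (!is.numeric(target_mca) || target_mca <= 0 || target_mca > 0.5 + MCA_TOL) {
    rlang::abort("target_mca must lie in (0, 1/2]",
      class = "heterogame_error_validation")
  }
  m <- target_mca * n / (n - 1)
  if (m > 1) {
    rlang::abort(
      sprintf("compensating ability %.4g exceeds 1: population of %d cannot reach MCA %.3g",
        m, n, target_mca),
      class = "heterogame_error_infeasible"
    )
  }
  discrete_strategy(c(0, m), abundance * c(1 / n, (n - 1) / n), label)
}

#' @describeIn strategy-constructors Mass `low_frac` at ability 0 and
#'   `high_frac` at ability 1, the remainder spread evenly over the
#'   interior grid points; with `low_frac = high_frac` and no interior
#'   mass this is the symmetric two-extremes distribution with MCA 1/2.
#' @param low_frac,high_frac Probability mass at abilities 0 and 1.
#' @export
make_bimodal <- function(M, low_frac = 0.5, high_frac = 0.5, abundance = 1,
                         label = "bimodal") {
  check_abundance(abundance)
  if (low_frac < 0 || high_frac < 0 || low_frac + high_frac > 1 + 1e-12) {
    rlang::abort("low_frac and high_frac must be nonnegative and sum to at most 1",
      class = "heterogame_error_validation")
  }
  grid <- canonical_grid(M)
  J <- length(grid)
  w <- numeric(J)
  w[1] <- low_frac
  w[J] <- w[J] + high_frac
  interior <- 1 - low_frac - high_frac
  if (J > 2 && interior > 0) {
    w[2:(J - 1)] <- w[2:(J - 1)] + interior / (J - 2)
  } else if (interior > 0) {
    # M = 1 has no interior grid points; fold the remainder symmetrically
    w <- w + interior / 2
  }
  out <- try(discrete_strategy(grid, w * abundance, label), silent = TRUE)
  if (inherits(out, "try-error")) {
    rlang::abort("bimodal shape parameters violate the MCA <= 1/2 bound",
      class = "heterogame_error_mca")
  }
  out
}

#' @describeIn strategy-constructors Gaussian density evaluated on the
#'   grid and truncated to \eqn{[0,1]}, then renormalized to `abundance`;
#'   shapes whose truncated mean exceeds 1/2 are rejected.
#' @param mean,sd Location and scale of the gaussian before truncation
#'   (`sd > 0`).
#' @export
make_truncated_gaussian <- function(M, mean = 0.5, sd = 0.1, abundance = 1,
                                    label = "gaussian") {
  check_abundance(abundance)
  if (!is.numeric(sd) || sd <= 0) {
    rlang::abort("sd must be positive", class = "heterogame_error_validation")
  }
  grid <- canonical_grid(M)
  w <- stats::dnorm(grid, mean, sd)
  if (sum(w) <= 0) {
    rlang::abort("gaussian weights vanish on the grid",
      class = "heterogame_error_validation")
  }
  w <- w / sum(w) * abundance
  out <- try(discrete_strategy(grid, w, label), silent = TRUE)
  if (inherits(out, "try-error")) {
    rlang::abort("truncated gaussian violates the MCA <= 1/2 bound",
      class = "heterogame_error_mca")
  }
  out
}
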