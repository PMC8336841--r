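#' Closed-form equilibrium classification on the canonical grid
#'
#' Classifies a finite-support strategy whose support is exactly the
#' canonical grid \eqn{\{j/M\}_{j=0}^M}. For odd \eqn{M}, equilibrium
#' strategies are precisely those with positive and identical weights at
#' every grid point. For even \eqn{M}, a strategy is an equilibrium
#' strategy if and only if its even-index weights all equal the weight at
#' \eqn{x_0 > 0}, its odd-index weights all equal the weight at
#' \eqn{x_1 > 0}, and its mean competitive ability equals \eqn{1/2}
#' (which the alternating pattern implies, but is checked explicitly).
#' All checks use relative tolerance `1e-9`.
#'
#' @param strategy A [discrete_strategy()] supported on a canonical
#'   grid. An off-grid support is an error: the characterization is a
#'   grid statement, and off-grid deviations can defeat it (see
#'   [design_counter_strategy()]).
#' @param M Grid resolution; inferred from the support when `NULL`.
#' @return A logical scalar with attribute `reason` naming the first
#'   failed condition (or `"equilibrium"`).
#' @examples
#' is_equilibrium_strategy_discrete(make_uniform(5, 12))        # TRUE
#' s <- discrete_strategy((0:2) / 2, c(2, 6, 2))
#' is_equilibrium_strategy_discrete(s)                          # TRUE (alternating)
#' @export
is_equilibrium_strategy_discrete <- function(strategy, M = NULL) {
  stopifnot(inherits(strategy, "discrete_strategy"))
  sup <- strategy$support
  if (is.null(M)) M <- length(sup) - 1
  if (M < 1 || length(sup) != M + 1 ||
      max(abs(sup - (0:M) / M)) > 1e-12) {
    rlang::abort(
      "support is not the canonical grid {j/M}: the classification is a grid statement",
      class = "heterogame_error_domain"
    )
  }
  w <- strategy$weights
  verdict <- function(ok, reason) structure(ok, reason = reason)
  rel_equal <- function(v) {
    m <- max(abs(v))
    m == 0 || (max(v) - min(v)) <= 1e-9 * m
  }
  if (M %% 2 == 1) {
    if (!rel_equal(w)) {
      return(verdict(FALSE, "odd M: weights are not identical across the grid"))
    }
    if (w[1] <= 0) {
      return(verdict(FALSE, "odd M: weights are not positive"))
    }
    return(verdict(TRUE, "equilibrium"))
  }
  even <- w[seq(1, M + 1, by = 2)]
  odd <- w[seq(2, M + 1, by = 2)]
  if (!rel_equal(even) || even[1] <= 0) {
    return(verdict(FALSE, "even M: even-index weights not equal and positive"))
  }
  if (!rel_equal(odd) || odd[1] <= 0) {
    return(verdict(FALSE, "even M: odd-index weights not equal and positive"))
  }
  if (abs(mca(strategy) - 0.5) > 1e-9) {
    return(verdict(FALSE, "even M: mean competitive ability differs from 1/2"))
  }
  verdict(TRUE, "equilibrium")
}

#' Equilibrium classification, continuous model
#'
#' In the continuous model a strategy is an equilibrium strategy if and
#' only if its density is a positive constant. The density is probed on
#' an equispaced grid and declared constant when its range is within
#' relative tolerance `1e-9` of its level.
#'
#' @param strategy A [continuous_strategy()].
#' @param n_probe Number of probe points (default 201).
#' @return Logical with attribute `reason`.
#' @examples
#' is_equilibrium_strategy_continuous(continuous_constant(3))   # TRUE
#' @export
is_equilibrium_strategy_continuous <- function(strategy, n_probe = 201) {
  stopifnot(inherits(strategy, "continuous_strategy"))
  vals <- strategy$density(seq(0, 1, length.out = n_probe))
  verdict <- function(ok, reason) structure(ok, reason = reason)
  if (min(vals) <= 0) {
    return(verdict(FALSE, "density is not strictly positive"))
  }
  if ((max(vals) - min(vals)) > 1e-9 * max(vals)) {
    return(verdict(FALSE, "density is not constant"))
  }
  verdict(TRUE, "equilibrium")
}

# Vertices of {p >= 0, sum(p) = 1, sum(x * p) <= bound} and the maximum
# of a linear objective over them. Single support points with x <= bound,
# plus two-point mixtures x_i < bound < x_j held at mean exactly `bound`.
lp_vertex_max <- function(support, objective, bound, tol = 1e-12) {
  best <- NULL
  lo <- which(support <= bound + tol)
  if (length(lo)) {
    j <- lo[which.max(objective[lo])]
    best <- list(
      value = objective[j], support = support[j], probs = 1,
      vertex = sprintf("single point x = %.6g", support[j])
    )
  }
  below <- which(support < bound - tol)
  above <- which(support > bound + tol)
  if (length(below) && length(above)) {
    for (i in below) {
      wj <- (bound - support[i]) / (support[above] - support[i])
      vals <- (1 - wj) * objective[i] + wj * objective[above]
      j <- which.max(vals)
      if (is.null(best) || vals[j] > best$value) {
        best <- list(
          value = vals[j],
          support = c(support[i], support[above[j]]),
          probs = c(1 - wj[j], wj[j]),
          vertex = sprintf(
            "two-point mixture x = (%.6g, %.6g) at mean %.6g",
            support[i], support[above[j]], bound
          )
        )
      }
    }
  }
  if (is.null(best)) {
    rlang::abort("no feasible deviation: MCA bound excludes every support point",
      class = "heterogame_error_infeasible")
  }
  best
}

#' Best response to a community, by exact vertex enumeration
#'
#' Maximizes the payoff a deviating species can obtain against fixed
#' opponents, over all strategies on the community's shared grid with
#' nonnegative weights, total abundance `deviation_abundance`, and mean
#' competitive ability at most \eqn{1/2}. Because a species'
#' self-interaction cancels out of the zero-sum payoff, the objective is
#' linear in the normalized weights, so the maximum is attained at a
#' vertex of the constraint polytope: a single support point
#' \eqn{x_j \le 1/2}, or a two-point mixture \eqn{x_i < 1/2 < x_j} held
#' at mean exactly \eqn{1/2}. All \eqn{O(M^2)} vertices are enumerated
#' exactly.
#'
#' @param comm A [community()] of finite-support strategies.
#' @param focal_index Which species considers deviating.
#' @param deviation_abundance Abundance of the deviation; defaults to the
#'   incumbent's (matched abundance makes the gain comparison well-posed,
#'   and the optimizer is abundance-invariant).
#' @return A list of class `best_response` with `optimal_deviation` (a
#'   [discrete_strategy()]), `deviation_gain` (payoff of the deviation
#'   minus payoff of the incumbent; always `>= 0` up to roundoff since
#'   the incumbent is feasible), and `argmax_vertex` (a description of
#'   the optimizing vertex).
#' @examples
#' comm <- community(make_uniform(10, 5), make_invariant(0.5, 5))
#' best_response(comm, focal_index = 2)$deviation_gain  # > 0
#' @export
best_response <- function(comm, focal_index, deviation_abundance = NULL) {
  comm <- as_community(comm)
  if (!is_discrete_community(comm)) {
    rlang::abort("best_response needs finite-support strategies",
      class = "heterogame_error_validation")
  }
  stopifnot(focal_index >= 1, focal_index <= length(comm))
  m <- merge_supports(comm)
  focal <- comm[[focal_index]]
  if (is.null(deviation_abundance)) deviation_abundance <- total_abundance(focal)
  check_abundance(deviation_abundance)

  opp <- colSums(m$W) - m$W[focal_index, ]
  below <- cumsum(opp) - opp
  above <- rev(cumsum(rev(opp))) - opp
  cvec <- below - above                # per-unit score against the opponents
  total <- sum(opp) + deviation_abundance
  scale <- deviation_abundance / total

  best <- lp_vertex_max(m$support, cvec, 0.5)
  incumbent_obj <- sum(m$W[focal_index, ] / sum(m$W[focal_index, ]) * cvec)
  deviation <- discrete_strategy(
    best$support, best$probs * deviation_abundance,
    label = paste0(focal$label, "_deviation")
  )
  structure(
    list(
      optimal_deviation = deviation,
      deviation_gain = scale * (best$value - incumbent_obj),
      argmax_vertex = best$vertex,
      deviation_payoff = scale * best$value,
      incumbent_payoff = scale * incumbent_obj
    ),
    class = "best_response"
  )
}

#' @export
print.best_response <- function(x, ...) {
  cat(sprintf("<best_response> gain %.6g at %s\n", x$deviation_gain, x$argmax_vertex))
  invisible(x)
}

#' Verify an equilibrium point numerically
#'
#' A community is an equilibrium point when no single species can
#' increase its payoff by unilaterally changing strategy. This is
#' checked with the exact [best_response()] oracle: the community passes
#' when every species' best-response gain is at most `tol`. All
#' strategies must share the same canonical grid — the characterization
#' being verified is a grid statement.
#'
#' @param comm A [community()] of strategies on a common canonical grid.
#' @param tol Gain tolerance (default `1e-9`).
#' @return A list with `is_equilibrium` (logical) and `gains`, a tibble
#'   of per-species best-response gains.
#' @examples
#' comm <- community(
#'   make_uniform(5, 1), make_uniform(5, 10), make_uniform(5, 100)
#' )
#' verify_equilibrium_point(comm)$is_equilibrium  # TRUE
#' @export
verify_equilibrium_point <- function(comm, tol = 1e-9) {
  comm <- as_community(comm)
  if (!is_discrete_community(comm)) {
    rlang::abort("verify_equilibrium_point needs finite-support strategies",
      class = "heterogame_error_validation")
  }
  sup <- merge_supports(comm)$support
  M <- length(sup) - 1
  if (M < 1 || max(abs(sup - (0:M) / M)) > 1e-12) {
    rlang::abort(
      "mixed grids: the union of supports must form a canonical grid {j/M}",
      class = "heterogame_error_domain"
    )
  }
  gains <- vapply(seq_along(comm), function(k) {
    best_response(comm, k)$deviation_gain
  }, numeric(1))
  list(
    is_equilibrium = all(gains <= tol),
    gains = tibble::tibble(species = names(comm), gain = gains)
  )
}

#' Design a counter-strategy that defeats a non-equilibrium strategy
#'
#' Constructs, for any finite-support strategy that is not an equilibrium
#' strategy, a "cumulatively equally fit" competitor: a strategy whose
#' mean competitive ability does not exceed the target's, yet whose
#' expected pairwise score against the target is strictly positive — so
#' at equal abundance the target's payoff in the two-species community is
#' strictly negative and the target is driven out. The defeat of the
#' invariant strategy by a Lake-Wobegon-type two-point distribution is
#' the canonical instance.
#'
#' Targets on a canonical grid are first classified with
#' [is_equilibrium_strategy_discrete()]; equilibrium strategies cannot be
#' defeated and yield a flag instead. For non-equilibrium targets, the
#' designer searches mixtures over a candidate set containing ability 0,
#' the target's own atoms (exploiting draws), and points just above each
#' atom (winning against it), holding the mean at the target's MCA by a
#' two-point vertex mixture — the same linear-programming geometry as
#' [best_response()], but with the tighter MCA bound and off-grid
#' candidates permitted.
#'
#' A target with mean competitive ability 0 concentrates all mass at
#' ability 0 and cannot be beaten under the equal-MCA bound; the flag is
#' returned with an explanatory reason.
#'
#' @param target A [discrete_strategy()].
#' @param gap_frac Fractional offset (of the gap to the next candidate)
#'   used for "just above an atom" candidates; default `2^-10`.
#' @return A list of class `counter_strategy` with elements
#'   `equilibrium` (flag: `TRUE` when no defeating strategy exists),
#'   `counter` (the defeating [discrete_strategy()] or `NULL`), `score`
#'   (its expected pairwise score against the target) and `reason`.
#' @examples
#' res <- design_counter_strategy(make_invariant(0.5, 100))
#' res$counter      # two atoms: 0 and just above 0.5, mean exactly 0.5
#' res$score        # > 0
#' design_counter_strategy(make_uniform(7))$equilibrium  # TRUE
#' @export
design_counter_strategy <- function(target, gap_frac = 2^-10) {
  stopifnot(inherits(target, "discrete_strategy"))
  sup <- target$support
  M <- length(sup) - 1
  on_grid <- M >= 1 && max(abs(sup - (0:M) / M)) <= 1e-12
  if (on_grid && isTRUE(as.logical(is_equilibrium_strategy_discrete(target)))) {
    return(structure(
      list(equilibrium = TRUE, counter = NULL, score = 0,
        reason = "equilibrium strategy: no defeating strategy exists"),
      class = "counter_strategy"
    ))
  }
  mu <- mca(target)
  if (mu <= 0) {
    return(structure(
      list(equilibrium = TRUE, counter = NULL, score = 0,
        reason = "target has MCA 0: no strategy with MCA <= 0 can defeat it"),
      class = "counter_strategy"
    ))
  }
  # candidate abilities: 0, the target's atoms (draws), and points just
  # above each atom (wins against it); score vs target is piecewise
  # constant between atoms, and smaller candidates spend less MCA budget
  gaps <- diff(c(sup, 1))
  just_above <- sup + pmax(gaps, 0) * gap_frac
  cand <- sort(unique(c(0, sup, just_above[just_above <= 1])))
  pb <- as_probabilities(target)
  below <- vapply(cand, function(a) sum(pb[sup < a]), numeric(1))
  above <- vapply(cand, function(a) sum(pb[sup > a]), numeric(1))
  score_fn <- below - above
  best <- lp_vertex_max(cand, score_fn, mu)
  if (best$value <= 1e-12) {
    return(structure(
      list(equilibrium = TRUE, counter = NULL, score = best$value,
        reason = "no defeating strategy found under the equal-MCA bound"),
      class = "counter_strategy"
    ))
  }
  keep <- best$probs > 0
  counter <- discrete_strategy(
    best$support[keep], best$probs[keep] * total_abundance(target),
    label = paste0("counter_", target$label)
  )
  structure(
    list(equilibrium = FALSE, counter = counter, score = best$value,
      reason = best$vertex),
    class = "counter_strategy"
  )
}

#' @export
print.counter_strategy <- function(x, ...) {
  if (x$equilibrium) {
    cat("<counter_strategy>", x$reason, "\n")
  } else {
    cat(sprintf("<counter_strategy> expected score %.6g (%s)\n", x$score, x$reason))
    print(x$counter)
  }
  invisible(x)
}
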