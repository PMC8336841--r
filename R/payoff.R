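#' Pairwise win/lose/draw kernel
#'
#' The outcome of a single cell-to-cell contest is decided by comparing
#' competitive abilities: the higher ability wins (+1, self-replicates),
#' the lower loses (-1, dies while the winner's species replicates), and
#' equal abilities draw (0, status quo). The game is zero-sum: the two
#' payoffs of a pair always sum to zero.
#'
#' @param ca_a,ca_b Competitive abilities in \eqn{[0,1]}; vectorised.
#' @return Integer vector in `{-1, 0, +1}`: the payoff to the first
#'   individual.
#' @examples
#' sign_kernel(0.8, 0.3)  # +1, win
#' sign_kernel(0.5, 0.5)  #  0, draw
#' sign_kernel(0.0, 1.0)  # -1, lose
#' @export
sign_kernel <- function(ca_a, ca_b) {
  if (anyNA(ca_a) || anyNA(ca_b) ||
      any(ca_a < 0 | ca_a > 1) || any(ca_b < 0 | ca_b > 1)) {
    rlang::abort("competitive abilities must lie in [0, 1]",
      class = "heterogame_error_validation")
  }
  as.integer(sign(ca_a - ca_b))
}

#' Multi-species payoffs, finite-support model
#'
#' Evaluates, for every species \eqn{A_k} in the community, the expected
#' net change in population abundance when all species compete at once:
#' \deqn{\wp_k = \frac{1}{\sum_\ell |A_\ell|} \sum_j A_k(x_j)
#'   \Big[\sum_{i<j} P(x_i) - \sum_{i>j} P(x_i)\Big],}
#' where \eqn{P(x_i) = \sum_\ell A_\ell(x_i)} pools all species
#' (including \eqn{A_k} itself; its self-interaction terms cancel by the
#' zero-sum structure). Finite supports are merged to a common sorted
#' grid with zero padding before evaluation, so off-grid designer
#' strategies mix freely with canonical-grid ones.
#'
#' @param comm A [community()] of `discrete_strategy` objects (a bare
#'   list or individual strategies are accepted and coerced).
#' @return A tibble of class `payoff_tbl` with columns `species`,
#'   `abundance` and `payoff`, carrying attributes `total_abundance` and
#'   `residual` (the zero-sum defect, numerically ~0). Payoffs sum to
#'   zero and each satisfies \eqn{|\wp_k| \le |A_k|}.
#' @examples
#' payoff_discrete(community(
#'   make_invariant(0.5, 1000),
#'   make_lake_wobegon(1000, 0.5, 1000)
#' ))
#' @export
payoff_discrete <- function(comm) {
  comm <- as_community(comm)
  if (!is_discrete_community(comm)) {
    rlang::abort("payoff_discrete needs finite-support strategies",
      class = "heterogame_error_validation")
  }
  m <- merge_supports(comm)
  pooled <- colSums(m$W)
  below <- cumsum(pooled) - pooled
  above <- rev(cumsum(rev(pooled))) - pooled
  bracket <- below - above
  total <- sum(pooled)
  payoff <- as.numeric(m$W %*% bracket) / total
  new_payoff_tbl(names(comm), rowSums(m$W), payoff, total)
}

#' Multi-species payoffs, continuous model
#'
#' Continuous analogue of [payoff_discrete()]:
#' \deqn{\wp_k = \frac{1}{\sum_\ell F_\ell(1)} \int_0^1 f_k(x)
#'   \Big[\int_0^x \textstyle\sum_\ell f_\ell - \int_x^1 \sum_\ell f_\ell\Big] dx.}
#' When every density carries a piecewise-polynomial representation the
#' integrals are evaluated exactly; otherwise adaptive quadrature is used
#' at absolute tolerance `1e-10`.
#'
#' @inheritParams payoff_discrete
#' @return A `payoff_tbl` tibble as for [payoff_discrete()].
#' @examples
#' payoff_continuous(community(continuous_constant(1), continuous_constant(3)))
#' @export
payoff_continuous <- function(comm) {
  comm <- as_community(comm)
  if (!all(vapply(comm, inherits, logical(1), "continuous_strategy"))) {
    rlang::abort("payoff_continuous needs continuous strategies",
      class = "heterogame_error_validation")
  }
  abund <- vapply(comm, total_abundance, numeric(1))
  total <- sum(abund)
  exact <- all(vapply(comm, function(s) !is.null(s$pieces), logical(1)))
  if (exact) {
    pooled <- pw_sum(lapply(comm, function(s) s$pieces))
    S <- pw_antider(pooled)             # S(x) = integral_0^x pooled
    S1 <- pw_eval(S, 1)
    payoff <- vapply(comm, function(s) {
      fk <- pw_align(s$pieces, S$breaks)
      # integrand f_k(x) * (2 S(x) - S1), exact per segment
      val <- 0
      for (seg in seq_along(fk$coefs)) {
        g <- 2 * S$coefs[[seg]]
        g[1] <- g[1] - S1
        p <- poly_antider(poly_mul(fk$coefs[[seg]], g))
        val <- val + poly_eval(p, S$breaks[seg + 1]) - poly_eval(p, S$breaks[seg])
      }
      val / total
    }, numeric(1))
  } else {
    fs <- lapply(comm, function(s) s$density)
    pooled_fn <- function(x) Reduce(`+`, lapply(fs, function(f) f(x)))
    Sfun <- function(x) vapply(x, function(xi) quad(pooled_fn, 0, xi), numeric(1))
    S1 <- quad(pooled_fn)
    payoff <- vapply(comm, function(s) {
      quad(function(x) s$density(x) * (2 * Sfun(x) - S1)) / total
    }, numeric(1))
  }
  new_payoff_tbl(names(comm), abund, unname(payoff), total)
}

#' Expected score of one strategy against another
#'
#' The expected value of the pairwise kernel under independent draws from
#' the two normalized strategies:
#' \eqn{P(X_a > X_b) - P(X_a < X_b) \in [-1, 1]}. This is the
#' per-contest decomposition of the payoff functional: in a two-species
#' community, \eqn{\wp_a = |A_a||A_b| \, s_{ab} / (|A_a| + |A_b|)}.
#'
#' @param strategy_a,strategy_b Strategies (finite-support or
#'   continuous).
#' @return A scalar in \eqn{[-1, 1]}.
#' @examples
#' expected_pairwise_score(
#'   make_invariant(0.5),
#'   make_lake_wobegon(10, 0.5)
#' )  # 0.1 * (+1) + 0.9 * (-1) = -0.8
#' @export
expected_pairwise_score <- function(strategy_a, strategy_b) {
  da <- inherits(strategy_a, "discrete_strategy")
  db <- inherits(strategy_b, "discrete_strategy")
  if (da && db) {
    m <- merge_supports(community(list(strategy_a, strategy_b)))
    pa <- m$W[1, ] / sum(m$W[1, ])
    pb <- m$W[2, ] / sum(m$W[2, ])
    below <- cumsum(pb) - pb
    above <- rev(cumsum(rev(pb))) - pb
    return(sum(pa * (below - above)))
  }
  if (da && !db) return(-expected_pairwise_score(strategy_b, strategy_a))
  if (!da && db) {
    # continuous vs finite-support: the continuous draw is tied with an
    # atom with probability zero
    Fa <- normalized_cdf(strategy_a)
    pb <- as_probabilities(strategy_b)
    return(sum(pb * (1 - 2 * Fa(strategy_b$support))))
  }
  # both continuous
  Fb <- normalized_cdf(strategy_b)
  fa <- strategy_a$density
  Fa1 <- total_abundance(strategy_a)
  quad(function(x) fa(x) * (2 * Fb(x) - 1)) / Fa1
}

normalized_cdf <- function(strategy) {
  ab <- total_abundance(strategy)
  if (!is.null(strategy$pieces)) {
    S <- pw_antider(strategy$pieces)
    function(x) pw_eval(S, x) / ab
  } else {
    f <- strategy$density
    function(x) vapply(x, function(xi) quad(f, 0, xi), numeric(1)) / ab
  }
}

new_payoff_tbl <- function(species, abundance, payoff, total) {
  out <- tibble::tibble(
    species = species,
    abundance = unname(abundance),
    payoff = payoff
  )
  attr(out, "total_abundance") <- total
  attr(out, "residual") <- sum(payoff)
  class(out) <- c("payoff_tbl", class(out))
  out
}

as_community <- function(x) {
  if (inherits(x, "community")) x else community(x)
}

# --- piecewise-polynomial algebra on [0,1] ------------------------------

# align a piecewise polynomial onto a refined break vector
pw_align <- function(pieces, breaks) {
  coefs <- vector("list", length(breaks) - 1)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  seg_of <- findInterval(mids, pieces$breaks, rightmost.closed = TRUE,
    all.inside = TRUE)
  for (i in seq_along(coefs)) coefs[[i]] <- pieces$coefs[[seg_of[i]]]
  list(breaks = breaks, coefs = coefs)
}

pw_sum <- function(piece_list) {
  breaks <- sort(unique(unlist(lapply(piece_list, function(p) p$breaks))))
  aligned <- lapply(piece_list, pw_align, breaks = breaks)
  coefs <- vector("list", length(breaks) - 1)
  for (i in seq_along(coefs)) {
    segs <- lapply(aligned, function(p) p$coefs[[i]])
    deg <- max(vapply(segs, length, integer(1)))
    acc <- numeric(deg)
    for (s in segs) acc[seq_along(s)] <- acc[seq_along(s)] + s
    coefs[[i]] <- acc
  }
  list(breaks = breaks, coefs = coefs)
}

# continuous antiderivative vanishing at 0
pw_antider <- function(pieces) {
  coefs <- vector("list", length(pieces$coefs))
  run <- 0
  for (i in seq_along(coefs)) {
    p <- poly_antider(pieces$coefs[[i]])
    p[1] <- run - poly_eval(p, pieces$breaks[i])
    coefs[[i]] <- p
    run <- poly_eval(p, pieces$breaks[i + 1])
  }
  list(breaks = pieces$breaks, coefs = coefs)
}

pw_eval <- function(pieces, x) {
  idx <- findInterval(x, pieces$breaks, rightmost.closed = TRUE, all.inside = TRUE)
  out <- numeric(length(x))
  for (seg in unique(idx)) {
    sel <- idx == seg
    out[sel] <- poly_eval(pieces$coefs[[seg]], x[sel])
  }
  out
}
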