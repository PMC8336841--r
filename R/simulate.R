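#' Draw per-round competitive abilities for a cohort
#'
#' Each round, every individual is independently assigned a fresh
#' competitive ability from its species' normalized strategy — clonal
#' individuals express the trait heterogeneously, and there is no
#' heritability of a specific ability across rounds: prior wins or
#' losses do not bias the next draw.
#'
#' @param strategy A [discrete_strategy()] (abilities sampled from the
#'   normalized weights) or a [continuous_strategy()] (inverse-CDF
#'   sampling; exact `runif()` draws for a constant density, so the
#'   maximally heterogeneous uniform strategy carries no discretization
#'   artifact).
#' @param n_individuals Number of draws (`>= 0`).
#' @return Numeric vector of abilities of length `n_individuals`.
#' @examples
#' set.seed(1)
#' assign_abilities(make_invariant(0.5), 5)  # all 0.5
#' @export
assign_abilities <- function(strategy, n_individuals) {
  stopifnot(n_individuals >= 0)
  UseMethod("assign_abilities")
}

#' @export
assign_abilities.discrete_strategy <- function(strategy, n_individuals) {
  if (n_individuals == 0) return(numeric(0))
  if (length(strategy$support) == 1) {
    return(rep(strategy$support, n_individuals))
  }
  sample(strategy$support, n_individuals, replace = TRUE,
    prob = as_probabilities(strategy))
}

#' @export
assign_abilities.continuous_strategy <- function(strategy, n_individuals) {
  if (n_individuals == 0) return(numeric(0))
  p <- strategy$pieces
  if (!is.null(p) && length(p$coefs) == 1 && length(p$coefs[[1]]) == 1) {
    return(stats::runif(n_individuals))  # constant density: exact
  }
  # numeric inverse CDF on a fine lattice
  x <- seq(0, 1, length.out = 2049)
  cdf <- if (!is.null(p)) {
    pw_eval(pw_antider(p), x) / total_abundance(strategy)
  } else {
    dens <- strategy$density(x)
    c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2)) * (x[2] - x[1])
  }
  cdf <- cummax(cdf / cdf[length(cdf)])
  keep <- !duplicated(cdf)
  stats::approx(cdf[keep], x[keep], xout = stats::runif(n_individuals),
    rule = 2)$y
}

#' Population state for the tournament simulator
#'
#' Bundles the community's strategies with integer head-counts. Initial
#' counts default to the rounded strategy abundances; every count must be
#' at least 1. The per-individual abilities are transient: they are
#' redrawn inside every round.
#'
#' @param comm A [community()]; finite-support and continuous strategies
#'   may be mixed (abilities are drawn per [assign_abilities()]).
#' @param counts Optional integer head-counts, one per species.
#' @return An object of class `population_state` with elements
#'   `community`, `counts` (named integer vector) and `round`.
#' @export
population_state <- function(comm, counts = NULL) {
  comm <- as_community(comm)
  if (is.null(counts)) {
    counts <- round(vapply(comm, total_abundance, numeric(1)))
  }
  counts <- as.integer(counts)
  if (length(counts) != length(comm) || any(counts < 1)) {
    rlang::abort("every species needs an integer head-count >= 1",
      class = "heterogame_error_validation")
  }
  names(counts) <- names(comm)
  structure(
    list(community = comm, counts = counts, round = 0L),
    class = "population_state"
  )
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("<population_state> round %d, total %d individuals\n",
    x$round, sum(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Advance the tournament by one round
#'
#' Every living individual draws a fresh ability, the pooled community is
#' paired by a uniform-random perfect matching (one uniformly chosen
#' individual sits out when the pooled count is odd), and each pair is
#' resolved by [sign_kernel()]: the winner's species gains one
#' individual, the loser's loses one, draws change nothing. Pairs within
#' a species therefore never change that species' count, and with an
#' even pooled count the community total is conserved exactly. Extinct
#' species (count 0) are never resampled. Uses R's global RNG; seed via
#' [run_simulation()] or `set.seed()` for reproducibility.
#'
#' @param state A [population_state()].
#' @return The updated `population_state` (round index incremented).
#' @export
run_round <- function(state) {
  stopifnot(inherits(state, "population_state"))
  counts <- state$counts
  N <- sum(counts)
  if (N < 2) {
    rlang::abort("fewer than two individuals remain: simulation complete",
      class = "heterogame_error_complete"
    )
  }
  alive <- which(counts > 0)
  sp <- rep.int(alive, counts[alive])
  ab <- numeric(N)
  pos <- 1L
  for (k in alive) {
    nk <- counts[k]
    ab[pos:(pos + nk - 1L)] <- assign_abilities(state$community[[k]], nk)
    pos <- pos + nk
  }
  perm <- sample.int(N)
  n_pair <- N %/% 2L
  i1 <- perm[seq.int(1L, by = 2L, length.out = n_pair)]
  i2 <- perm[seq.int(2L, by = 2L, length.out = n_pair)]
  d <- sign(ab[i1] - ab[i2])
  K <- length(counts)
  wins <- tabulate(c(sp[i1][d > 0], sp[i2][d < 0]), nbins = K)
  losses <- tabulate(c(sp[i1][d < 0], sp[i2][d > 0]), nbins = K)
  state$counts <- counts + wins - losses
  state$round <- state$round + 1L
  state
}

#' Run a stochastic competition tournament
#'
#' Repeats [run_round()] for `rounds` rounds and records the abundance
#' trajectory. The result is bit-reproducible given `(comm, rounds,
#' seed)`.
#'
#' @param comm A [community()] of finite-support strategies; initial
#'   head-counts are the rounded abundances.
#' @param rounds Number of rounds (`>= 1`).
#' @param seed Optional integer seed; the global RNG state is restored
#'   afterwards.
#' @param counts Optional initial head-counts (see [population_state()]).
#' @param stop_on_extinction Stop early once any species is extinct
#'   (remaining rounds carry the frozen counts forward so the trajectory
#'   keeps its full length).
#' @return An object of class `competition_sim`: list with `trajectory`
#'   (tibble: `round`, `species`, `count`; rounds `0..rounds`),
#'   `extinctions` (tibble: `species`, `round` of first zero), `seed`,
#'   `rounds` and `final_counts`.
#' @examples
#' sim <- run_simulation(
#'   community(make_invariant(0.5, 50), make_lake_wobegon(50, 0.5, 50)),
#'   rounds = 20, seed = 1
#' )
#' glance(sim)
#' @export
run_simulation <- function(comm, rounds, seed = NULL, counts = NULL,
                           stop_on_extinction = FALSE) {
  stopifnot(rounds >= 1)
  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_seed(old_seed), add = TRUE)
    set.seed(seed)
  }
  state <- population_state(comm, counts)
  K <- length(state$counts)
  traj <- matrix(0L, nrow = rounds + 1L, ncol = K,
    dimnames = list(NULL, names(state$counts)))
  traj[1L, ] <- state$counts
  extinct_round <- rep(NA_integer_, K)
  names(extinct_round) <- names(state$counts)
  halted <- FALSE
  for (r in seq_len(rounds)) {
    if (!halted) {
      state <- run_round(state)
      newly <- state$counts == 0L & is.na(extinct_round)
      extinct_round[newly] <- r
      if (stop_on_extinction && any(state$counts == 0L)) halted <- TRUE
    }
    traj[r + 1L, ] <- state$counts
  }
  trajectory <- tibble::tibble(
    round = rep(0:rounds, times = K),
    species = rep(colnames(traj), each = rounds + 1L),
    count = as.integer(traj)
  )
  ext <- extinct_round[!is.na(extinct_round)]
  structure(
    list(
      trajectory = trajectory,
      extinctions = tibble::tibble(
        species = names(ext),
        round = as.integer(ext)
      ),
      final_counts = state$counts,
      rounds = rounds,
      seed = seed
    ),
    class = "competition_sim"
  )
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

#' @export
print.competition_sim <- function(x, ...) {
  cat(sprintf("<competition_sim> %d species, %d rounds, seed %s\n",
    length(x$final_counts), x$rounds,
    if (is.null(x$seed)) "none" else format(x$seed)))
  cat("final counts:\n")
  print(x$final_counts)
  if (nrow(x$extinctions)) {
    cat("extinctions:\n")
    print(as.data.frame(x$extinctions))
  }
  invisible(x)
}

#' Monte Carlo estimate of the expected one-round abundance change
#'
#' Repeats a single round from the same initial state and reports the
#' mean change in head-count per species with its standard error. Used
#' as the simulator/payoff agreement oracle: with an even pooled count
#' \eqn{N}, the expectation equals the analytic payoff rescaled by
#' \eqn{N/(N-1)} (an individual is matched with one of the \eqn{N-1}
#' others, never itself).
#'
#' @param comm A [community()] of finite-support strategies.
#' @param replicates Number of independent one-round replicates
#'   (`>= 100`).
#' @param seed Optional seed.
#' @return A tibble with columns `species`, `mean_change`, `se`.
#' @export
estimate_expected_change <- function(comm, replicates = 1000, seed = NULL) {
  stopifnot(replicates >= 100)
  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_seed(old_seed), add = TRUE)
    set.seed(seed)
  }
  state0 <- population_state(comm)
  K <- length(state0$counts)
  changes <- matrix(0, nrow = replicates, ncol = K)
  for (r in seq_len(replicates)) {
    changes[r, ] <- run_round(state0)$counts - state0$counts
  }
  tibble::tibble(
    species = names(state0$counts),
    mean_change = colMeans(changes),
    se = apply(changes, 2, stats::sd) / sqrt(replicates)
  )
}
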