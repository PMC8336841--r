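# Independent brute-force oracles and randomized-case generators.
# The oracles deliberately avoid the package's merged-grid code path:
# they loop over every ordered pair of support atoms directly.

brute_payoff <- function(comm) {
  total <- sum(vapply(comm, function(s) sum(s$weights), numeric(1)))
  vapply(seq_along(comm), function(k) {
    a <- comm[[k]]
    acc <- 0
    for (j in seq_along(a$support)) {
      for (l in seq_along(comm)) {
        b <- comm[[l]]
        for (i in seq_along(b$support)) {
          acc <- acc + a$weights[j] * b$weights[i] *
            sign(a$support[j] - b$support[i])
        }
      }
    }
    acc / total
  }, numeric(1))
}

brute_score <- function(a, b) {
  pa <- a$weights / sum(a$weights)
  pb <- b$weights / sum(b$weights)
  acc <- 0
  for (i in seq_along(pa)) {
    for (j in seq_along(pb)) {
      acc <- acc + pa[i] * pb[j] * sign(a$support[i] - b$support[j])
    }
  }
  acc
}

# random strictly positive weights on the canonical grid, mirrored if
# needed so the MCA constraint holds (reversal maps MCA to 1 - MCA)
random_grid_strategy <- function(M, abundance = stats::runif(1, 0.5, 5),
                                 label = "rnd") {
  w <- stats::runif(M + 1, 0.05, 1)
  x <- (0:M) / M
  if (sum(x * w) / sum(w) > 0.5) w <- rev(w)
  discrete_strategy(x, w / sum(w) * abundance, label)
}

# random strategy on a random finite support (not necessarily a grid)
random_support_strategy <- function(n_atoms = sample(2:6, 1),
                                    abundance = stats::runif(1, 0.5, 5),
                                    label = "rnd") {
  x <- sort(sample(seq(0, 1, by = 0.01), n_atoms))
  w <- stats::runif(n_atoms, 0.05, 1)
  if (sum(x * w) / sum(w) > 0.5) {
    x <- rev(1 - x)
    w <- rev(w)
  }
  discrete_strategy(x, w / sum(w) * abundance, label)
}

random_community <- function(n_species = sample(2:4, 1), M = sample(2:6, 1)) {
  community(lapply(seq_len(n_species), function(k) {
    random_grid_strategy(M, label = paste0("sp", k))
  }))
}

# random equilibrium strategy on the M grid (constant for odd M,
# alternating two-level for even M)
random_equilibrium_strategy <- function(M, label = "eq") {
  if (M %% 2 == 1) {
    w <- rep(stats::runif(1, 0.2, 2), M + 1)
  } else {
    a <- stats::runif(1, 0.2, 2)
    b <- stats::runif(1, 0.2, 2)
    w <- rep(c(a, b), length.out = M + 1)
  }
  discrete_strategy((0:M) / M, w, label)
}

# random piecewise-linear density on [0,1] with MCA <= 1/2 (mirrored if
# needed) and strictly positive values
random_pw_density <- function(label = "g") {
  breaks <- sort(unique(c(0, sample(seq(0.05, 0.95, by = 0.05), 3), 1)))
  y <- stats::runif(length(breaks), 0.1, 2)
  s <- try(continuous_piecewise_linear(breaks, y, label = label), silent = TRUE)
  if (inherits(s, "try-error")) {
    # mirroring the density maps MCA to 1 - MCA
    s <- continuous_piecewise_linear(rev(1 - breaks), rev(y), label = label)
  }
  s
}

# pair oracle for "is B an equilibrium strategy": the community of two
# copies of B is an equilibrium point iff B is an equilibrium strategy
oracle_is_equilibrium <- function(strategy, tol = 1e-9) {
  twin <- strategy
  twin$label <- paste0(strategy$label, "_twin")
  verify_equilibrium_point(community(strategy, twin), tol = tol)$is_equilibrium
}
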