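test_that("the pairwise kernel scores win, lose and draw", {
  expect_identical(sign_kernel(0.8, 0.3), 1L)
  expect_identical(sign_kernel(0.3, 0.8), -1L)
  expect_identical(sign_kernel(0.5, 0.5), 0L)
  expect_identical(sign_kernel(0.0, 1.0), -1L)
  expect_error(sign_kernel(1.2, 0.5), class = "heterogame_error_validation")
  expect_error(sign_kernel(0.5, -0.1), class = "heterogame_error_validation")
})

test_that("discrete payoffs match the brute-force double loop exactly", {
  withr::local_seed(101)
  for (i in 1:25) {
    comm <- community(lapply(seq_len(sample(2:5, 1)), function(k) {
      random_support_strategy(sample(2:20, 1), label = paste0("sp", k))
    }))
    p <- payoff_discrete(comm)
    expect_equal(p$payoff, brute_payoff(comm), tolerance = 1e-12)
    expect_lt(abs(sum(p$payoff)), 1e-10)
    # expected score per individual contest is bounded by the abundance
    expect_true(all(abs(p$payoff) <= p$abundance + 1e-12))
  }
})

test_that("identical strategies receive zero payoff by symmetry", {
  withr::local_seed(7)
  s <- random_grid_strategy(6, abundance = 3, label = "a")
  twin <- s
  twin$label <- "b"
  p <- payoff_discrete(community(s, twin))
  expect_equal(p$payoff, c(0, 0), tolerance = 1e-12)
})

test_that("a uniform pool is neutral towards any strategy with MCA 1/2", {
  withr::local_seed(31)
  M <- 10
  for (i in 1:10) {
    w <- runif(M + 1, 0.05, 1)
    w <- w + rev(w)  # symmetrized: MCA exactly 1/2
    g <- discrete_strategy((0:M) / M, w, "g")
    p <- payoff_discrete(community(make_uniform(M, runif(1, 0.5, 4)), g))
    expect_equal(p$payoff, c(0, 0), tolerance = 1e-10)
  }
})

test_that("against a uniform pool the payoff is proportional to 2*MCA - 1", {
  withr::local_seed(57)
  M <- 8
  a <- 2.5
  for (i in 1:10) {
    g <- random_grid_strategy(M, label = "g")
    p <- payoff_discrete(community(make_uniform(M, a, label = "pool"), g))
    total <- a + total_abundance(g)
    predicted <- a * M / (M + 1) * total_abundance(g) * (2 * mca(g) - 1) / total
    expect_equal(p$payoff[2], predicted, tolerance = 1e-10)
  }
})

test_that("the invariant strategy scores negatively against Lake Wobegon", {
  p <- payoff_discrete(community(
    make_invariant(0.5, 1000),
    make_lake_wobegon(1000, 0.5, 1000)
  ))
  expect_lt(p$payoff[1], 0)
  expect_equal(p$payoff[1], -p$payoff[2])
})

test_that("excluding self-interaction terms does not change any payoff", {
  withr::local_seed(19)
  for (i in 1:10) {
    comm <- random_community()
    p <- payoff_discrete(comm)
    total <- sum(vapply(comm, total_abundance, numeric(1)))
    without_self <- vapply(seq_along(comm), function(k) {
      a <- comm[[k]]
      acc <- 0
      for (j in seq_along(a$support)) {
        for (l in seq_along(comm)[-k]) {
          b <- comm[[l]]
          for (ii in seq_along(b$support)) {
            acc <- acc + a$weights[j] * b$weights[ii] *
              sign(a$support[j] - b$support[ii])
          }
        }
      }
      acc / total
    }, numeric(1))
    expect_equal(p$payoff, without_self, tolerance = 1e-12)
  }
})

test_that("payoffs scale linearly with a common abundance factor", {
  withr::local_seed(23)
  comm <- random_community(3, 5)
  lambda <- 3.7
  scaled <- community(lapply(comm, function(s) {
    discrete_strategy(s$support, s$weights * lambda, s$label)
  }))
  expect_equal(payoff_discrete(scaled)$payoff,
    lambda * payoff_discrete(comm)$payoff,
    tolerance = 1e-10)
})

test_that("expected pairwise score matches enumeration and known values", {
  expect_equal(
    expected_pairwise_score(make_invariant(0.5), make_lake_wobegon(10, 0.5)),
    0.1 * 1 + 0.9 * (-1)
  )
  expect_equal(expected_pairwise_score(make_invariant(0.4), make_invariant(0.5)), -1)
  withr::local_seed(43)
  for (i in 1:10) {
    a <- random_support_strategy(label = "a")
    b <- random_support_strategy(label = "b")
    expect_equal(expected_pairwise_score(a, b), brute_score(a, b),
      tolerance = 1e-12)
    expect_equal(expected_pairwise_score(a, a), 0, tolerance = 1e-12)
    expect_equal(expected_pairwise_score(b, a), -expected_pairwise_score(a, b),
      tolerance = 1e-12)
  }
})

test_that("two positive constant densities are mutually neutral", {
  p <- payoff_continuous(community(continuous_constant(1), continuous_constant(3)))
  expect_equal(p$payoff, c(0, 0), tolerance = 1e-12)
})

test_that("continuous payoff against a constant follows the closed form", {
  # against a constant pool c the payoff of g is c G(1) (2 MCA - 1) / total
  cc <- 2
  g <- continuous_piecewise_linear(c(0, 1), c(2, 0), label = "ramp")  # MCA 1/3
  p <- payoff_continuous(community(continuous_constant(cc), g))
  total <- cc + 1
  expect_equal(p$payoff[2], cc * 1 * (2 * (1 / 3) - 1) / total, tolerance = 1e-12)
  expect_lt(p$payoff[2], 0)

  withr::local_seed(77)
  for (i in 1:5) {
    g <- random_pw_density()
    cc <- runif(1, 0.5, 3)
    p <- payoff_continuous(community(continuous_constant(cc), g))
    G1 <- total_abundance(g)
    expect_equal(p$payoff[2], cc * G1 * (2 * mca(g) - 1) / (cc + G1),
      tolerance = 1e-9)
    expect_lt(abs(sum(p$payoff)), 1e-10)
  }
})

test_that("quadrature and exact piecewise paths agree", {
  exact <- community(
    continuous_constant(2, label = "flat"),
    continuous_piecewise_linear(c(0, 1), c(2, 0), label = "ramp")
  )
  numeric_comm <- community(
    continuous_strategy(function(x) rep(2, length(x)), label = "flat"),
    continuous_strategy(function(x) 2 - 2 * x, label = "ramp")
  )
  expect_equal(payoff_continuous(numeric_comm)$payoff,
    payoff_continuous(exact)$payoff,
    tolerance = 1e-8)
})

test_that("discrete payoffs on refined grids converge to the continuous model", {
  # continuous pair: constant 1 and the symmetrized tent density
  tent <- continuous_piecewise_linear(c(0, 0.5, 1), c(0, 2, 0), label = "tent")
  target <- payoff_continuous(community(continuous_constant(1, label = "flat"), tent))
  for (M in c(100, 1000)) {
    grid <- (0:M) / M
    tent_w <- pmax(0, 1 - 2 * abs(grid - 0.5)) * 2
    disc <- community(
      make_uniform(M, 1, label = "flat"),
      discrete_strategy(grid, tent_w / sum(tent_w), "tent")
    )
    err <- max(abs(payoff_discrete(disc)$payoff - target$payoff))
    expect_lt(err, if (M == 100) 2e-2 else 1e-3)
  }
})

test_that("mixed discrete/continuous expected scores use the CDF correctly", {
  flat <- continuous_constant(1)
  expect_equal(expected_pairwise_score(make_invariant(0.25), flat),
    0.25 - 0.75,
    tolerance = 1e-9)
  expect_equal(expected_pairwise_score(flat, make_invariant(0.25)),
    0.5,
    tolerance = 1e-9)
  expect_equal(expected_pairwise_score(flat, continuous_constant(4)), 0,
    tolerance = 1e-9)
})

test_that("degenerate communities are rejected", {
  expect_error(community(), class = "heterogame_error_validation")
  expect_error(payoff_discrete(community(continuous_constant(1))),
    class = "heterogame_error_validation")
})
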