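test_that("odd-M classifier accepts exactly the positive constant strategies", {
  expect_true(is_equilibrium_strategy_discrete(make_uniform(5, 3)))
  expect_true(is_equilibrium_strategy_discrete(make_uniform(1, 0.2)))
  s <- discrete_strategy((0:5) / 5, c(1, 1.1, 1, 1, 1, 1))
  res <- is_equilibrium_strategy_discrete(s)
  expect_false(as.logical(res))
  expect_match(attr(res, "reason"), "identical")
})

test_that("even-M classifier accepts the alternating pattern with MCA 1/2", {
  s <- discrete_strategy((0:2) / 2, c(2, 6, 2))
  expect_true(is_equilibrium_strategy_discrete(s))
  # constant weights satisfy the alternating pattern trivially
  expect_true(is_equilibrium_strategy_discrete(make_uniform(4, 2)))
  # break the alternation
  bad <- discrete_strategy((0:4) / 4, c(2, 6, 2.2, 6, 2) / 2)
  expect_false(as.logical(is_equilibrium_strategy_discrete(bad)))
  # perturbing one weight of a constant strategy breaks equilibrium
  pert <- discrete_strategy((0:4) / 4, c(1, 1, 1.1, 1, 1))
  expect_false(as.logical(is_equilibrium_strategy_discrete(pert)))
})

test_that("off-grid support is a domain error for the grid classifier", {
  s <- discrete_strategy(c(0, 0.3, 1), c(1, 1, 0.2))
  expect_error(is_equilibrium_strategy_discrete(s),
    class = "heterogame_error_domain")
})

test_that("continuous classifier accepts positive constants and their sums", {
  expect_true(is_equilibrium_strategy_continuous(continuous_constant(3)))
  expect_false(as.logical(is_equilibrium_strategy_continuous(
    continuous_strategy(function(x) 2 * (1 - x))
  )))
  two <- continuous_strategy(function(x) rep(1.5 + 2.5, length(x)), label = "sum")
  expect_true(is_equilibrium_strategy_continuous(two))
})

test_that("best response against uniform incumbents gains nothing", {
  comm <- community(make_uniform(10, 2, label = "a"), make_uniform(10, 5, label = "b"))
  br <- best_response(comm, 1)
  expect_lt(abs(br$deviation_gain), 1e-12)
  expect_gte(br$deviation_gain, -1e-12)
})

test_that("best response against an invariant incumbent straddles its atom", {
  comm <- community(make_invariant(0.5, 1), make_uniform(10, 1))
  br <- best_response(comm, 2)
  expect_gt(br$deviation_gain, 0)
  expect_match(br$argmax_vertex, "two-point mixture")
  expect_lte(mca(br$optimal_deviation), 0.5 + 1e-12)
  expect_equal(total_abundance(br$optimal_deviation), 1)
})

test_that("the incumbent is always a feasible deviation: gain is nonnegative", {
  withr::local_seed(5)
  for (i in 1:20) {
    comm <- random_community()
    k <- sample(length(comm), 1)
    expect_gte(best_response(comm, k)$deviation_gain, -1e-12)
  }
})

test_that("collections of equilibrium strategies form equilibrium points", {
  comm <- community(
    make_uniform(5, 1, label = "a"),
    make_uniform(5, 10, label = "b"),
    make_uniform(5, 100, label = "c")
  )
  v <- verify_equilibrium_point(comm)
  expect_true(v$is_equilibrium)
  expect_true(all(v$gains$gain <= 1e-9))

  # mixing constant and alternating equilibria on an even grid
  alt <- discrete_strategy((0:4) / 4, c(1, 3, 1, 3, 1), "alt")
  expect_true(verify_equilibrium_point(community(make_uniform(4, 2), alt))$is_equilibrium)

  expect_true(verify_equilibrium_point(community(make_uniform(5, 2)))$is_equilibrium)
  expect_false(verify_equilibrium_point(
    community(make_uniform(4, 1), make_invariant(0.5, 1))
  )$is_equilibrium)
})

test_that("mixed grids are rejected by the equilibrium verifier", {
  expect_error(
    verify_equilibrium_point(community(make_uniform(4, 1), make_uniform(5, 1))),
    class = "heterogame_error_domain"
  )
})

test_that("classifier and best-response oracle agree on randomized strategies", {
  withr::local_seed(97)
  for (M in 1:6) {
    for (i in 1:25) {
      s <- random_grid_strategy(M, label = "s")
      expect_identical(
        as.logical(is_equilibrium_strategy_discrete(s)),
        oracle_is_equilibrium(s)
      )
      e <- random_equilibrium_strategy(M)
      expect_true(as.logical(is_equilibrium_strategy_discrete(e)))
      expect_true(oracle_is_equilibrium(e))
    }
  }
})

test_that("sums of equilibrium strategies remain equilibrium strategies", {
  withr::local_seed(13)
  for (M in 2:7) {
    a <- random_equilibrium_strategy(M)
    b <- random_equilibrium_strategy(M)
    s <- discrete_strategy(a$support, a$weights + b$weights, "sum")
    expect_true(as.logical(is_equilibrium_strategy_discrete(s)))
  }
})

test_that("equilibrium strategies dominate lower-MCA strategies and are neutral at 1/2", {
  withr::local_seed(29)
  for (i in 1:10) {
    M <- sample(2:8, 1)
    e <- random_equilibrium_strategy(M)
    # equal-MCA opponent: symmetrized weights have MCA exactly 1/2
    w <- runif(M + 1, 0.05, 1)
    g_eq <- discrete_strategy((0:M) / M, w + rev(w), "g")
    expect_equal(payoff_discrete(community(e, g_eq))$payoff, c(0, 0),
      tolerance = 1e-10)
    # lower-MCA opponent loses
    g_low <- random_grid_strategy(M, label = "low")
    if (mca(g_low) < 0.5 - 1e-6) {
      expect_lt(payoff_discrete(community(e, g_low))$payoff[2], 0)
    }
  }
})

test_that("counter-strategy designer defeats non-equilibrium strategies", {
  res <- design_counter_strategy(make_invariant(0.5, 100))
  expect_false(res$equilibrium)
  expect_length(res$counter$support, 2)
  expect_equal(res$counter$support[1], 0)
  expect_gt(res$counter$support[2], 0.5)
  expect_equal(mca(res$counter), 0.5, tolerance = 1e-12)
  expect_gt(res$score, 0)
  # at equal abundance the target's payoff is strictly negative
  p <- payoff_discrete(community(res$counter, make_invariant(0.5, 100)))
  expect_lt(p$payoff[2], 0)

  g <- make_truncated_gaussian(20, 0.5, 0.1)
  rg <- design_counter_strategy(g)
  expect_false(rg$equilibrium)
  expect_gt(rg$score, 0)
  expect_lte(mca(rg$counter), mca(g) + 1e-12)
  expect_lt(payoff_discrete(community(rg$counter, g))$payoff[2], 0)
})

test_that("counter-strategy designer flags equilibrium strategies", {
  for (M in c(3, 8)) {
    res <- design_counter_strategy(make_uniform(M))
    expect_true(res$equilibrium)
    expect_null(res$counter)
  }
  alt <- discrete_strategy((0:4) / 4, c(2, 5, 2, 5, 2), "alt")
  expect_true(design_counter_strategy(alt)$equilibrium)
  # MCA-0 target cannot be beaten under the equal-MCA bound
  expect_true(design_counter_strategy(make_invariant(0, 5))$equilibrium)
})

test_that("counters never exceed the target's MCA across a randomized suite", {
  withr::local_seed(71)
  for (i in 1:20) {
    target <- if (i %% 2) {
      random_grid_strategy(sample(1:8, 1), label = "t")
    } else {
      random_support_strategy(label = "t")
    }
    res <- design_counter_strategy(target)
    if (!res$equilibrium) {
      expect_lte(mca(res$counter), mca(target) + 1e-12)
      expect_gt(res$score, 0)
      expect_equal(res$score, brute_score(res$counter, target), tolerance = 1e-12)
    }
  }
})
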