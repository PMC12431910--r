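test_that("fitness and average fitness match direct arithmetic", {
  expect_equal(fitness(RPS, c(1, 1, 1) / 3), c(0, 0, 0))
  expect_equal(fitness(RPS, c(0.9, 0.05, 0.05)), c(0, -0.85, 0.85))
  expect_equal(fitness(HDG, c(0.5, 0.5)), c(2.5, 2.5))
  expect_equal(average_fitness(HDG, c(0.5, 0.5)), 2.5)
  expect_equal(average_fitness(HDG, c(1, 0)), 2)
  # skew-symmetric games are zero-sum for every mixture
  for (m in 1:20) {
    x <- sweep_points(3, 20)[m, ]
    expect_equal(average_fitness(RPS, x), 0, tolerance = 1e-12)
  }
  expect_error(fitness(RPS, c(0.5, 0.5)), "length 2")
})

test_that("replicator field vanishes at equilibria and conserves mass", {
  expect_equal(replicator_rhs(RPS, c(1, 1, 1) / 3), c(0, 0, 0))
  expect_equal(replicator_rhs(RPS, c(0.9, 0.05, 0.05)), c(0, -0.0425, 0.0425))
  expect_equal(replicator_rhs(HDG, c(1, 0)), c(0, 0))
  pts <- sweep_points(4, 50)
  A <- random_payoff(4, seed = 7)
  for (m in seq_len(nrow(pts))) {
    expect_lt(abs(sum(replicator_rhs(A, pts[m, ]))), 1e-12)
  }
  # faces are invariant: zero coordinates stay exactly zero
  x <- c(0, 0.3, 0.7)
  expect_identical(replicator_rhs(RPS, x)[1], 0)
})

test_that("interior equilibria solve the equal-fitness system", {
  eq <- interior_equilibrium(RPS)
  expect_equal(as.numeric(eq), rep(1 / 3, 3))
  expect_equal(attr(eq, "status"), "interior")
  eq2 <- interior_equilibrium(HDG)
  expect_equal(as.numeric(eq2), c(0.5, 0.5))
  # inconsistent system: one strategy strictly dominates
  expect_equal(attr(interior_equilibrium(payoff_matrix(rbind(c(1, 1), c(0, 0)))),
                    "status"), "absent")
  # singular with a manifold of equilibria (all payoffs equal)
  expect_equal(attr(interior_equilibrium(payoff_matrix(matrix(1, 3, 3))),
                    "status"), "degenerate")
  # equal-fitness residual at a returned equilibrium
  for (s in 1:20) {
    A <- random_payoff(3, seed = s)
    eq <- interior_equilibrium(A)
    if (length(eq)) {
      f <- fitness(A, eq)
      expect_lt(max(abs(f - average_fitness(A, eq))), 1e-10)
    }
  }
})

test_that("Nash classification reduces to vertex comparisons", {
  expect_true(is_nash(HDG, c(0.5, 0.5)))
  expect_false(is_nash(HDG, c(1, 0)))
  expect_true(is_nash(RPS, c(1, 1, 1) / 3))
  # HDG vertices are fixed points of the flow but not Nash
  expect_true(is_fixed_point(HDG, c(1, 0)))
  expect_true(is_fixed_point(HDG, c(0, 1)))
  expect_false(is_nash(HDG, c(0, 1)))
})

test_that("ESS classification: exact two-species branch and sampler", {
  expect_true(is_ess(HDG, c(0.5, 0.5)))
  expect_false(is_ess(RPS, c(1, 1, 1) / 3))  # zero-sum: never strict
  expect_true(is_ess(payoff_matrix(diag(c(-1, -1))), c(0.5, 0.5)))
  rep <- classify_equilibrium(HDG, c(0.5, 0.5))
  expect_true(rep$is_fixed_point && rep$is_nash && rep$is_ess)
})

test_that("sampled ESS branch agrees with the exact closed form", {
  agree <- vapply(1:50, function(s) {
    A <- random_payoff(2, seed = 1000 + s)
    eq <- interior_equilibrium(A)
    x <- if (length(eq)) as.numeric(eq) else c(1, 0)
    isTRUE(is_ess(A, x, method = "exact") ==
             is_ess(A, x, method = "sampled", n_samples = 400, seed = s))
  }, logical(1))
  expect_true(all(agree))
})

test_that("ESS implies Nash on random games", {
  for (s in 1:50) {
    n <- if (s %% 2) 2 else 3
    A <- random_payoff(n, seed = s)
    eq <- interior_equilibrium(A)
    cands <- c(list(if (length(eq)) as.numeric(eq)),
               lapply(seq_len(n), function(k) as.numeric(diag(n)[k, ])))
    for (x in Filter(Negate(is.null), cands)) {
      if (is_ess(A, x, seed = s)) expect_true(is_nash(A, x))
    }
  }
})

test_that("diagonal reduction preserves the replicator field", {
  red <- diagonal_reduction(HDG)
  expect_equal(unclass(structure(red, label = NULL)),
               diag(c(-2, -2)), ignore_attr = TRUE)
  A1 <- payoff_matrix(diag(c(-1, -1)))
  expect_equal(as.numeric(diagonal_reduction(A1)), as.numeric(diag(c(-1, -1))))
  redrps <- diagonal_reduction(RPS)
  expect_equal(as.numeric(redrps[3, ]), c(0, 0, 0))
  pts <- sweep_points(3, 100, seed = 9)
  for (m in seq_len(nrow(pts))) {
    expect_equal(replicator_rhs(RPS, pts[m, ]), replicator_rhs(redrps, pts[m, ]),
                 tolerance = 1e-12)
  }
})

test_that("invasion margin psi matches its quadratic-form identity", {
  expect_equal(ess_gap(HDG, c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(ess_gap(payoff_matrix(diag(c(-1, -1))), c(0.5, 0.5), c(0.25, 0.75)),
               1 / 8)
  expect_equal(ess_gap(HDG, c(0.5, 0.5), c(0.9, 0.1)), 0.64)
})

test_that("random generators are seeded and correctly distributed", {
  expect_identical(random_payoff(3, seed = 5), random_payoff(3, seed = 5))
  expect_equal(dim(random_payoff(3, seed = 1)), c(3L, 3L))
  expect_true(all(random_payoff(4, scale = 0, seed = 2) == 0))
  expect_identical(random_simplex_point(3, seed = 8), random_simplex_point(3, seed = 8))
  pts <- random_simplex_point(3, seed = 3, n_points = 1e5)
  expect_true(all(abs(rowSums(pts) - 1) < 1e-12))
  # flat Dirichlet mean is the barycenter; per-coordinate SE = sqrt(2/9)/2/sqrt(m)
  se <- sqrt(1 / 18 / 1e5)
  expect_true(all(abs(colMeans(pts) - 1 / 3) < 3 * se))
  # a generator call must not clobber the session RNG stream
  set.seed(123); a <- runif(1)
  set.seed(123); invisible(random_simplex_point(3, seed = 1)); b <- runif(1)
  expect_identical(a, b)
})
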