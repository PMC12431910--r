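test_that("Gauss-Legendre tableau satisfies the order conditions", {
  tb <- gl4_tableau()
  expect_equal(sum(tb$b), 1)
  expect_equal(rowSums(tb$A), tb$c)
  expect_equal(sum(tb$b * tb$c), 1 / 2)
  expect_equal(sum(tb$b * tb$c^2), 1 / 3)
  expect_equal(prod(tb$c), 1 / 6)
})

test_that("a single step integrates cubics exactly (Gauss quadrature)", {
  st <- pec_step(function(t, y) 0 * y, c(1, 2), 0, 0.5)
  expect_identical(st$y, c(1, 2))
  expect_equal(st$iterations, 1)
  st2 <- pec_step(function(t, y) t^3, 0, 0, 1)
  expect_equal(st2$y, 1 / 4, tolerance = 1e-15)
})

test_that("converged steps reproduce the (2,2) Pade amplification", {
  for (z in c(-0.2, -0.5, 0.3)) {
    st <- pec_step(function(t, y) z * y, 1, 0, 1, epsilon = 1e-14)
    expect_equal(st$y, pade22(z), tolerance = 1e-12)
  }
})

test_that("A-stability: strongly negative eigenvalues are damped", {
  # functional iteration cannot contract here; the Newton fallback takes over
  for (z in c(-10, -100)) {
    st <- pec_step(function(t, y) z * y, 1, 0, 1, epsilon = 1e-13)
    expect_equal(st$y, pade22(z), tolerance = 1e-10)
    expect_lt(abs(st$y), 1)
  }
})

test_that("corrector agrees with a direct solve of the stage equations", {
  # independent oracle: damped Newton on the stacked stage system with a
  # central-difference Jacobian, written here from scratch
  direct_stages <- function(f, y, t, dt, tol = 1e-14) {
    tb <- gl4_tableau()
    m <- length(y)
    K <- rep(as.numeric(f(t, y)), 2)
    Fk <- function(K) {
      Y1 <- y + dt * (tb$A[1, 1] * K[1:m] + tb$A[1, 2] * K[m + 1:m])
      Y2 <- y + dt * (tb$A[2, 1] * K[1:m] + tb$A[2, 2] * K[m + 1:m])
      c(f(t + tb$c[1] * dt, Y1), f(t + tb$c[2] * dt, Y2))
    }
    for (it in 1:200) {
      G <- K - Fk(K)
      if (sqrt(sum(G^2)) < tol) break
      J <- matrix(0, 2 * m, 2 * m)
      h <- 1e-7
      for (q in seq_len(2 * m)) {
        ep <- em <- K
        ep[q] <- ep[q] + h
        em[q] <- em[q] - h
        J[, q] <- ((ep - Fk(ep)) - (em - Fk(em))) / (2 * h)
      }
      K <- K - solve(J, G)
    }
    y + dt / 2 * (K[1:m] + K[m + 1:m])
  }
  # bare field, no simplex validation: stage iterates drift off by O(h)
  f <- function(t, y) {
    fv <- drop(unclass(RPS) %*% y)
    y * (fv - sum(y * fv))
  }
  for (s in 1:5) {
    y0 <- sweep_points(3, 5, seed = 60)[s, ]
    mine <- pec_step(f, y0, 0, 0.05, epsilon = 1e-15)$y
    ref <- direct_stages(f, y0, 0, 0.05)
    expect_equal(mine, ref, tolerance = 1e-13)
  }
})

test_that("Euler baselines have textbook amplification factors", {
  z <- -0.4
  expect_equal(euler_explicit_step(function(t, y) z * y, 1, 0, 1), 1 + z)
  st <- euler_implicit_step(function(t, y) z * y, 1, 0, 1, epsilon = 1e-14)
  expect_equal(st$y, 1 / (1 - z), tolerance = 1e-12)
})

test_that("compiled march agrees with the reference R stepper", {
  M <- model_spec(build_inline(3), HDG, transport_spec("linear", nu = 0.1))
  x0 <- rbind(c(0.5, 0.5), c(0, 1), c(0, 1))
  traj <- integrate_model(M, x0, integrator_config(dt = 0.05, t_end = 1))
  y <- x0
  for (k in 1:20) {
    y <- pec_step(function(t, v) network_rhs(M, v), y, (k - 1) * 0.05, 0.05)$y
  }
  expect_equal(trajectory_state(traj, 21), unname(y), tolerance = 1e-13)
})

test_that("integration is deterministic and respects stored grids", {
  M <- single_node_model(RPS)
  cfg <- integrator_config(dt = 0.01, t_end = 2)
  t1 <- integrate_model(M, c(0.9, 0.05, 0.05), cfg)
  t2 <- integrate_model(M, c(0.9, 0.05, 0.05), cfg)
  expect_identical(t1$states, t2$states)
  expect_equal(t1$times, seq(0, 2, by = 0.01))
  expect_equal(trajectory_state(t1, 1), matrix(c(0.9, 0.05, 0.05), 1))
  # store_every thins the grid without changing the march
  t3 <- integrate_model(M, c(0.9, 0.05, 0.05),
                        integrator_config(dt = 0.01, t_end = 2, store_every = 10))
  expect_equal(t3$times, seq(0, 2, by = 0.1))
  expect_equal(t3$states[2, 1, ], t1$states[11, 1, ])
})

test_that("starting at the mixed equilibrium the system stays put", {
  M <- single_node_model(RPS)
  traj <- integrate_model(M, rep(1, 3) / 3, integrator_config(dt = 0.01, t_end = 20))
  expect_lt(max(abs(traj$states - 1 / 3)), 1e-12)
})

test_that("single-node flow matches an adaptive reference solver", {
  skip_if_not_installed("deSolve")
  f <- function(t, y, parms) list(replicator_rhs(RPS, y))
  ref <- deSolve::ode(c(0.9, 0.05, 0.05), seq(0, 10, by = 0.1), f, NULL,
                      method = "lsoda", rtol = 1e-12, atol = 1e-12)
  traj <- integrate_model(single_node_model(RPS), c(0.9, 0.05, 0.05),
                          integrator_config(dt = 0.005, t_end = 10, store_every = 20))
  expect_equal(traj$states[, 1, ], unname(ref[, 2:4]), tolerance = 1e-8)
})

test_that("delayed-transport flow matches a reference DDE solver", {
  skip_if_not_installed("deSolve")
  G <- build_inline(2)
  tau <- 0.4
  p <- 2
  M <- model_spec(network_graph(G$adjacency, p = p, tau = tau),
                  HDG, transport_spec("delayed", p = p, tau = tau,
                                      formulation = "departure"))
  x0 <- rbind(c(0.5, 0.5), c(0.1, 0.9))
  w <- exp(-p * tau)
  f <- function(t, y, parms) {
    x <- matrix(y, 2, 2, byrow = TRUE)
    lag <- function(i) {
      if (t <= tau) x0[i, ] else
        sapply(seq_len(2), function(k) deSolve::lagvalue(t - tau, 2 * (i - 1) + k))
    }
    r1 <- replicator_rhs(HDG, x[1, ]) + w * (lag(2) - x[1, ])
    r2 <- replicator_rhs(HDG, x[2, ]) + w * (lag(1) - x[2, ])
    list(c(r1, r2))
  }
  ref <- deSolve::dede(as.numeric(t(x0)), seq(0, 5, by = 0.1), f, NULL,
                       control = list(mxhist = 1e5))
  traj <- integrate_model(M, x0, integrator_config(dt = 0.01, t_end = 5,
                                                   store_every = 10))
  ours <- cbind(traj$states[, 1, ], traj$states[, 2, ])
  expect_equal(ours, unname(ref[, 2:5]), tolerance = 1e-5)
})

test_that("the march refuses configurations it cannot integrate", {
  M <- single_node_model(RPS)
  expect_error(integrate_model(M, c(0.9, 0.05, 0.05),
                               integrator_config(dt = 1.5, t_end = 3,
                                                 max_corrector_iters = 3)),
               "corrector")
  expect_error(integrate_model(M, c(2, -0.5, -0.5)), "negative")
  expect_error(integrator_config(dt = -1), "positive")
})
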