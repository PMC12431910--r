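#' Fourth-order Gauss-Legendre predictor-corrector integration
#'
#' The two-stage Gauss-Legendre implicit Runge-Kutta method (order 4,
#' A-stable, symplectic) is solved in predictor-corrector form: explicit
#' Euler predictors at the two Gauss abscissae seed a fixed-point iteration
#' of the stage equations, stopped when
#' `max(||k1 - k1c||_2, ||k2 - k2c||_2) < epsilon`.
#' First-order explicit and implicit Euler steps are provided as baselines.
#'
#' @name integrator
NULL

#' Butcher tableau of the two-stage Gauss-Legendre method
#'
#' @return list with the 2 x 2 stage matrix `A`, weights `b = (1/2, 1/2)`
#'   and abscissae `c = (1/2 - sqrt(3)/6, 1/2 + sqrt(3)/6)`.
#' @export
gl4_tableau <- function() {
  s <- sqrt(3) / 6
  list(
    A = matrix(c(1 / 4, 1 / 4 - s,
                 1 / 4 + s, 1 / 4), 2, 2, byrow = TRUE),
    b = c(1 / 2, 1 / 2),
    c = c(1 / 2 - s, 1 / 2 + s)
  )
}

#' Integrator configuration
#'
#' @param dt step size (> 0).
#' @param t_end horizon (> 0); rounded to a whole number of steps.
#' @param epsilon corrector tolerance on the stage residuals.
#' @param max_corrector_iters iteration cap per step.
#' @param method `"gl4pec"`, `"euler_explicit"` or `"euler_implicit"`.
#' @param store_every keep every k-th step in the trajectory (all steps by
#'   default); must divide the step count.
#' @param guard_tol abort when the per-node row-sum deviation from 1 exceeds
#'   this (signals a step size too large for the configuration).
#' @return an object of class `integrator_config`.
#' @export
integrator_config <- function(dt = 0.01, t_end = 100, epsilon = 1e-12,
                              max_corrector_iters = 50,
                              method = c("gl4pec", "euler_explicit", "euler_implicit"),
                              store_every = 1, guard_tol = 1e-6) {
  method <- match.arg(method)
  if (dt <= 0 || t_end <= 0) stop("dt and t_end must be positive")
  if (epsilon <= 0) stop("epsilon must be positive")
  if (max_corrector_iters < 1) stop("max_corrector_iters must be at least 1")
  structure(list(dt = dt, t_end = t_end, epsilon = epsilon,
                 max_corrector_iters = max_corrector_iters, method = method,
                 store_every = as.integer(store_every), guard_tol = guard_tol),
            class = "integrator_config")
}

#' One Gauss-Legendre predictor-corrector step (reference implementation)
#'
#' Generic over the right-hand-side function `f(t, y)` (`y` any numeric
#' vector or matrix).  Used for micro-oracles and as the readable reference
#' the compiled model march is tested against.  When the fixed-point
#' iteration fails to contract within `max_iters` (stiff probes), a
#' simplified-Newton solve of the stage equations using a finite-difference
#' Jacobian at `(t, y)` is attempted before giving up.
#'
#' @param f function of `(t, y)` returning `dy/dt` with the shape of `y`.
#' @param y current state.
#' @param t current time.
#' @param dt step size.
#' @param epsilon stage-residual tolerance (Euclidean norm over all
#'   components).
#' @param max_iters iteration cap.
#' @return list with `y` (the new state), `iterations` used, and the final
#'   `residual`.
#' @export
pec_step <- function(f, y, t, dt, epsilon = 1e-12, max_iters = 50) {
  tb <- gl4_tableau()
  shape <- y
  fn <- f(t, y)
  k1 <- f(t + tb$c[1] * dt, y + tb$c[1] * dt * fn)
  k2 <- f(t + tb$c[2] * dt, y + tb$c[2] * dt * fn)
  res <- Inf
  it <- 0
  while (it < max_iters) {
    k1c <- f(t + tb$c[1] * dt, y + dt * (tb$A[1, 1] * k1 + tb$A[1, 2] * k2))
    k2c <- f(t + tb$c[2] * dt, y + dt * (tb$A[2, 1] * k1 + tb$A[2, 2] * k2))
    res <- max(sqrt(sum((k1 - k1c)^2)), sqrt(sum((k2 - k2c)^2)))
    k1 <- k1c
    k2 <- k2c
    it <- it + 1
    if (res < epsilon) break
  }
  if (res >= epsilon) {
    sol <- pec_newton_stages(f, y, t, dt, epsilon, max_iters, k1, k2)
    if (is.null(sol)) {
      stop("corrector did not reach tolerance ", epsilon, " in ", max_iters,
           " iterations (residual ", format(res), "); reduce dt")
    }
    k1 <- sol$k1
    k2 <- sol$k2
    it <- it + sol$iterations
    res <- sol$residual
  }
  ynew <- y + dt / 2 * (k1 + k2)
  attributes(ynew) <- attributes(shape)
  list(y = ynew, iterations = it, residual = res)
}

# simplified-Newton fallback for stiff probes: solve the 2-stage system
# K = F(K) with the Jacobian of f frozen at (t, y)
pec_newton_stages <- function(f, y, t, dt, epsilon, max_iters, k1, k2) {
  tb <- gl4_tableau()
  m <- length(y)
  yv <- as.numeric(y)
  wrap <- function(v) { attributes(v) <- attributes(y); v }
  fv <- function(tt, v) as.numeric(f(tt, wrap(v)))
  J <- matrix(0, m, m)
  f0 <- fv(t, yv)
  h <- sqrt(.Machine$double.eps) * pmax(abs(yv), 1)
  for (q in seq_len(m)) {
    e <- yv
    e[q] <- e[q] + h[q]
    J[, q] <- (fv(t, e) - f0) / h[q]
  }
  # G(K) = K - F(K); J_G = I - dt (A x J)
  Abig <- diag(2 * m) - dt * rbind(
    cbind(tb$A[1, 1] * J, tb$A[1, 2] * J),
    cbind(tb$A[2, 1] * J, tb$A[2, 2] * J))
  K <- c(as.numeric(k1), as.numeric(k2))
  for (it in seq_len(max_iters)) {
    Y1 <- yv + dt * (tb$A[1, 1] * K[1:m] + tb$A[1, 2] * K[m + 1:m])
    Y2 <- yv + dt * (tb$A[2, 1] * K[1:m] + tb$A[2, 2] * K[m + 1:m])
    FK <- c(fv(t + tb$c[1] * dt, Y1), fv(t + tb$c[2] * dt, Y2))
    G <- K - FK
    res <- max(sqrt(sum(G[1:m]^2)), sqrt(sum(G[m + 1:m]^2)))
    if (res < epsilon) {
      return(list(k1 = wrap(K[1:m]), k2 = wrap(K[m + 1:m]),
                  iterations = it, residual = res))
    }
    K <- K - solve(Abig, G)
  }
  NULL
}

#' First-order Euler baseline steps
#'
#' The implicit variant solves `y1 = y + dt f(t + dt, y1)` by fixed-point
#' iteration to `epsilon`.
#'
#' @inheritParams pec_step
#' @return the new state (explicit), or a list like [pec_step] (implicit).
#' @export
euler_explicit_step <- function(f, y, t, dt) {
  y + dt * f(t, y)
}

#' @rdname euler_explicit_step
#' @export
euler_implicit_step <- function(f, y, t, dt, epsilon = 1e-12, max_iters = 50) {
  z <- y + dt * f(t, y)
  res <- Inf
  it <- 0
  while (it < max_iters) {
    znew <- y + dt * f(t + dt, z)
    res <- sqrt(sum((znew - z)^2))
    z <- znew
    it <- it + 1
    if (res < epsilon) break
  }
  if (res >= epsilon) stop("implicit Euler solve did not converge (residual ",
                           format(res), ")")
  list(y = z, iterations = it, residual = res)
}

#' Integrate the networked replicator model
#'
#' Fixed-step march of the coupled system from `t = 0` to the horizon, with
#' a cubic Hermite history of accepted steps serving the delay lookups.
#' Deterministic given `(M, x0, config)`.
#'
#' @param M a [model_spec].
#' @param x0 N x n matrix of initial node states (rows on the simplex), or a
#'   single simplex vector for a one-node model.
#' @param config an [integrator_config].
#' @return an object of class `trajectory`: list with `times`, `states`
#'   (array `n_stored` x N x n), `model`, `config` and `meta` (corrector
#'   statistics and simplex-drift maxima).
#' @export
integrate_model <- function(M, x0, config = integrator_config()) {
  if (!inherits(M, "model_spec")) stop("M must be a model_spec")
  x0 <- if (is.null(dim(x0))) matrix(x0, nrow = 1) else as.matrix(x0)
  if (nrow(x0) != M$G$N) stop("x0 must have one row per node")
  for (i in seq_len(nrow(x0))) check_simplex(x0[i, ], M$n_species,
                                             what = sprintf("x0[%d,]", i))
  n_steps <- round(config$t_end / config$dt)
  if (abs(n_steps * config$dt - config$t_end) > 1e-8 * config$t_end) {
    n_steps <- ceiling(config$t_end / config$dt)
  }
  if (n_steps %% config$store_every != 0) {
    stop("store_every must divide the number of steps (", n_steps, ")")
  }
  tr <- M$transport
  kind <- match(tr$kind, c("none", "linear", "delayed")) - 1L
  cmodel <- list(
    N = M$G$N, n = M$n_species, shared = M$shared_payoff,
    payoffs = lapply(M$payoffs, function(a) matrix(as.numeric(a), nrow(a))),
    neighbor_matrix = matrix(as.integer(neighbor_matrix(M$G)), M$G$N),
    nu = edge_param(M$G, tr$nu, M$G$nu),
    p = edge_param(M$G, tr$p, M$G$p),
    tau = edge_param(M$G, tr$tau, M$G$tau),
    kind = kind,
    formulation = match(tr$formulation, c("printed", "departure")) - 1L
  )
  method <- match(config$method,
                  c("gl4pec", "euler_explicit", "euler_implicit")) - 1L
  res <- .cpp_integrate(cmodel, x0, config$dt, as.integer(n_steps),
                        config$epsilon, as.integer(config$max_corrector_iters),
                        method, config$store_every, config$guard_tol)
  structure(list(
    times = res$times,
    states = res$states,
    model = M,
    config = config,
    meta = list(
      total_corrector_iters = res$total_corrector_iters,
      max_corrector_iters_used = res$max_corrector_iters_used,
      max_simplex_deviation = res$max_simplex_deviation,
      min_coordinate = res$min_coordinate
    )
  ), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$states)
  cat(sprintf(paste0("trajectory: %d nodes x %d species, %d stored times ",
                     "(dt = %g, t_end = %g, %s)\n"),
              d[2], d[3], d[1], x$config$dt, x$config$t_end, x$config$method))
  cat(sprintf("  max simplex deviation %.3g, min coordinate %.3g\n",
              x$meta$max_simplex_deviation, x$meta$min_coordinate))
  invisible(x)
}

#' Extract the ensemble state at a stored time index
#'
#' @param traj a `trajectory`.
#' @param idx time index (1-based into the stored grid).
#' @return N x n matrix.
#' @export
trajectory_state <- function(traj, idx) {
  matrix(traj$states[idx, , ], dim(traj$states)[2], dim(traj$states)[3])
}

#' Tidy data frame view of a trajectory
#'
#' @param traj a `trajectory`.
#' @return data frame with columns `time`, `node`, `species`, `frequency`.
#' @export
trajectory_frame <- function(traj) {
  d <- dim(traj$states)
  data.frame(
    time = rep(traj$times, times = d[2] * d[3]),
    node = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    species = rep(seq_len(d[3]), each = d[1] * d[2]),
    frequency = as.numeric(traj$states)
  )
}
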