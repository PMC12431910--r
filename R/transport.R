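#' Inter-node transport terms
#'
#' Two exchange mechanisms couple the nodes.  Linear transport moves density
#' down the inter-node difference at a transfer velocity nu:
#' `T_nu(i) = sum_{j in c(i)} nu_ij (x^j(t) - x^i(t))`.
#' Delayed transport weights the exchange by the probability of surviving the
#' journey and looks back one travel time on the receiving node:
#' `T_p(i) = sum_{j in c(i)} exp(-p_ij tau_ij) (x^j(t) - x^i(t - tau_ij))`.
#' With `p = 0, tau = 0` the delayed form reduces exactly to linear transport
#' with unit velocity.
#'
#' @name transport
NULL

#' Transport specification
#'
#' @param kind `"none"`, `"linear"` or `"delayed"`.
#' @param nu global transfer velocity (linear kind), overridden by per-edge
#'   values stored on the graph.
#' @param p global survival rate (delayed kind), per unit time.
#' @param tau global travel time (delayed kind).
#' @param formulation delayed-kind variant: `"printed"` pairs the neighbor's
#'   current state with the node's own delayed state; `"departure"` instead
#'   uses the neighbor state one travel time ago against the node's current
#'   state (sensitivity checks only).
#' @return an object of class `transport_spec`.
#' @export
transport_spec <- function(kind = c("none", "linear", "delayed"),
                           nu = 0.1, p = 2, tau = 1,
                           formulation = c("printed", "departure")) {
  kind <- match.arg(kind)
  formulation <- match.arg(formulation)
  if (kind == "linear" && nu < 0) stop("nu must be nonnegative")
  if (kind == "delayed" && (p < 0 || tau < 0)) stop("p and tau must be nonnegative")
  structure(list(kind = kind, nu = nu, p = p, tau = tau,
                 formulation = formulation), class = "transport_spec")
}

# effective per-edge parameter matrix: per-edge values on the graph override
# the spec's global scalar
edge_param <- function(G, spec_value, graph_value) {
  P <- matrix(spec_value, G$N, G$N)
  if (!is.null(graph_value)) P <- graph_value
  P
}

#' Linear velocity transport
#'
#' @param states N x n matrix of node states.
#' @param G a [network_graph].
#' @param nu scalar velocity or N x N per-edge matrix.
#' @return N x n matrix; row i is `sum_{j in c(i)} nu_ij (x^j - x^i)`.  Rows
#'   sum to zero whenever all node states are on the simplex, which is the
#'   mechanism behind simplex invariance of the coupled flow.
#' @export
linear_transport <- function(states, G, nu) {
  states <- as.matrix(states)
  if (nrow(states) != G$N) stop("states must have one row per node")
  W <- neighbor_matrix(G)
  nuM <- if (length(nu) == 1) matrix(nu, G$N, G$N) else as.matrix(nu)
  if (any(nuM[W == 1] < 0)) stop("nu must be nonnegative on every edge")
  C <- W * nuM
  C %*% states - rowSums(C) * states
}

#' Dense-output history buffer
#'
#' Stores accepted step times, states and right-hand-side evaluations for
#' delay lookups.  Queries at `t <= t0` return the initial state (constant
#' pre-history); queries between accepted steps use cubic Hermite
#' interpolation, which is exact at stored times and reproduces cubics
#' exactly; queries beyond the last accepted time extrapolate the last
#' segment's cubic (the previous step's Hermite extension).
#'
#' @param t0 initial time.
#' @param x0 initial N x n state.
#' @param f0 right-hand side at `(t0, x0)`.
#' @return an object of class `history_buffer` (environment-backed).
#' @export
history_buffer <- function(t0, x0, f0) {
  e <- new.env(parent = emptyenv())
  e$times <- t0
  e$states <- list(as.matrix(x0))
  e$derivs <- list(as.matrix(f0))
  e$t0 <- t0
  class(e) <- "history_buffer"
  e
}

#' @rdname history_buffer
#' @param H a `history_buffer`.
#' @param t accepted time (must exceed the last stored time).
#' @param x,f state and right-hand side at `t`.
#' @export
history_append <- function(H, t, x, f) {
  n <- length(H$times)
  if (t <= H$times[n]) stop("history times must be strictly increasing")
  H$times <- c(H$times, t)
  H$states[[n + 1]] <- as.matrix(x)
  H$derivs[[n + 1]] <- as.matrix(f)
  invisible(H)
}

#' Interpolate the stored trajectory
#'
#' @param H a [history_buffer].
#' @param t query time.
#' @return N x n state at `t`.
#' @export
interpolate_history <- function(H, t) {
  if (t <= H$t0) return(H$states[[1]])
  n <- length(H$times)
  if (n == 1) return(H$states[[1]])  # constant extension of a bare initial state
  # bracketing segment; beyond the last accepted time, extend the last cubic
  k <- findInterval(t, H$times, rightmost.closed = FALSE)
  if (k >= n) k <- n - 1
  if (k < 1) k <- 1
  t0 <- H$times[k]; t1 <- H$times[k + 1]
  h <- t1 - t0
  s <- (t - t0) / h
  y0 <- H$states[[k]]; y1 <- H$states[[k + 1]]
  d0 <- H$derivs[[k]]; d1 <- H$derivs[[k + 1]]
  h00 <- (1 + 2 * s) * (1 - s)^2
  h10 <- s * (1 - s)^2
  h01 <- s^2 * (3 - 2 * s)
  h11 <- s^2 * (s - 1)
  h00 * y0 + h10 * h * d0 + h01 * y1 + h11 * h * d1
}

#' Delayed survival-weighted transport
#'
#' @param states current N x n node states (e.g. an integrator stage value).
#' @param H a [history_buffer] covering `[t - max(tau), t]` (constant
#'   pre-history below the initial time).
#' @param t current time.
#' @param G a [network_graph].
#' @param p survival rate: scalar or N x N per-edge matrix.
#' @param tau travel time: scalar or N x N per-edge matrix.
#' @param formulation see [transport_spec].
#' @return N x n matrix; row i is
#'   `sum_{j in c(i)} exp(-p_ij tau_ij) (x^j(t) - x^i(t - tau_ij))`.
#' @export
delayed_transport <- function(states, H, t, G, p, tau,
                              formulation = c("printed", "departure")) {
  formulation <- match.arg(formulation)
  states <- as.matrix(states)
  W <- neighbor_matrix(G)
  pM <- if (length(p) == 1) matrix(p, G$N, G$N) else as.matrix(p)
  tM <- if (length(tau) == 1) matrix(tau, G$N, G$N) else as.matrix(tau)
  if (any(pM[W == 1] < 0) || any(tM[W == 1] < 0)) {
    stop("p and tau must be nonnegative on every edge")
  }
  out <- matrix(0, nrow(states), ncol(states))
  # cache history lookups by delay value (taus are typically shared)
  lookup <- local({
    cache <- list()
    function(d) {
      key <- format(d, digits = 17)
      if (is.null(cache[[key]])) cache[[key]] <<- interpolate_history(H, t - d)
      cache[[key]]
    }
  })
  for (i in seq_len(G$N)) {
    for (j in which(W[i, ] == 1)) {
      w <- exp(-pM[i, j] * tM[i, j])
      if (formulation == "printed") {
        out[i, ] <- out[i, ] + w * (states[j, ] - lookup(tM[i, j])[i, ])
      } else {
        out[i, ] <- out[i, ] + w * (lookup(tM[i, j])[j, ] - states[i, ])
      }
    }
  }
  out
}
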