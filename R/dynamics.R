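#' Coupled replicator-transport dynamics
#'
#' The full model couples one replicator equation per node through a
#' transport term:
#' `xdot^i_k = x^i_k ((A^i x^i)_k - x^i' A^i x^i) + T_k(x^i)(t)`.
#'
#' @name dynamics
NULL

#' Model specification
#'
#' @param G a [network_graph].
#' @param payoff a single [payoff_matrix] shared by all nodes, or a list of
#'   N matrices (one per node, all the same dimension).
#' @param transport a [transport_spec]; default no transport.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(G, payoff, transport = transport_spec("none")) {
  if (!inherits(G, "network_graph")) stop("G must be a network_graph")
  if (!inherits(transport, "transport_spec")) stop("transport must be a transport_spec")
  payoffs <- if (is.list(payoff)) payoff else list(payoff)
  if (!length(payoffs) %in% c(1L, G$N)) {
    stop("need 1 shared payoff matrix or one per node (", G$N, ")")
  }
  ns <- vapply(payoffs, nrow, integer(1))
  if (length(unique(ns)) != 1) stop("all payoff matrices must share one species count")
  structure(list(G = G, payoffs = payoffs, n_species = ns[1],
                 shared_payoff = length(payoffs) == 1, transport = transport),
            class = "model_spec")
}

node_payoff <- function(M, i) {
  if (M$shared_payoff) M$payoffs[[1]] else M$payoffs[[i]]
}

#' Full networked right-hand side
#'
#' Row i is the local replicator field plus the transport row.  For linear
#' (and absent) transport the rows sum to zero whenever every node state is
#' on the simplex, which is what keeps the flow on the simplex.
#'
#' @param M a [model_spec].
#' @param x N x n matrix of node states.
#' @param t current time (matters only for delayed transport).
#' @param H a [history_buffer]; required when the transport kind is
#'   `"delayed"`.
#' @return N x n matrix of time derivatives.
#' @export
network_rhs <- function(M, x, t = 0, H = NULL) {
  x <- as.matrix(x)
  if (nrow(x) != M$G$N) stop("x must have one row per node")
  if (ncol(x) != M$n_species) stop("x must have one column per species")
  out <- x
  for (i in seq_len(nrow(x))) {
    A <- node_payoff(M, i)
    f <- drop(A %*% x[i, ])
    out[i, ] <- x[i, ] * (f - sum(x[i, ] * f))
  }
  tr <- M$transport
  if (tr$kind == "linear") {
    out <- out + linear_transport(x, M$G, edge_param(M$G, tr$nu, M$G$nu))
  } else if (tr$kind == "delayed") {
    if (is.null(H)) stop("delayed transport needs a history buffer")
    out <- out + delayed_transport(x, H, t, M$G,
                                   edge_param(M$G, tr$p, M$G$p),
                                   edge_param(M$G, tr$tau, M$G$tau),
                                   tr$formulation)
  }
  out
}

#' Relative-entropy Lyapunov function
#'
#' `V(x) = -sum_i sum_k x*_k log(x^i_k / x*_k)`: nonnegative, zero exactly
#' when every node sits at the interior state `x*`, and non-increasing along
#' trajectories when `x*` is an ESS and the transfer velocity satisfies the
#' stability condition.
#'
#' @param xstar strictly interior reference state.
#' @param x N x n matrix of node states with positive entries.
#' @return scalar.
#' @export
lyapunov_V <- function(xstar, x) {
  x <- as.matrix(x)
  if (any(xstar <= 0)) stop("xstar must be strictly interior")
  if (any(x <= 0)) stop("all node frequencies must be positive inside the log")
  -sum(sweep(log(sweep(x, 2, xstar, "/")), 2, xstar, "*"))
}

#' Simplex drift monitor
#'
#' @param x N x n matrix of node states.
#' @return list with `max_deviation` (max over nodes of `|sum_k x_k - 1|`)
#'   and `min_coordinate`.
#' @export
simplex_drift <- function(x) {
  x <- as.matrix(x)
  list(max_deviation = max(abs(rowSums(x) - 1)), min_coordinate = min(x))
}
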