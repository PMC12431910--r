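#' Network graphs for metapopulation transport
#'
#' A network is a node set with a 0/1 adjacency matrix (no self-loops) and
#' optional per-edge transport parameters: a transfer velocity `nu`, a
#' survival rate `p` and a travel time `tau`.  For directed graphs the
#' transport sum at node i runs, by default, over its in-neighbors: an arc
#' j -> i moves density from j's state into i's balance (`direction = "in"`);
#' the opposite convention is available behind `direction = "out"`.
#'
#' @name network
NULL

#' Construct a network graph
#'
#' @param adjacency N x N 0/1 matrix, zero diagonal; symmetric unless
#'   `directed`.
#' @param directed logical.
#' @param nu,p,tau optional per-edge parameter matrices (N x N, read on
#'   adjacent pairs only); scalars are recycled to all edges.
#' @param direction neighbor convention for directed graphs: `"in"`
#'   (default) or `"out"`.
#' @return an object of class `network_graph`.
#' @export
network_graph <- function(adjacency, directed = FALSE, nu = NULL, p = NULL,
                          tau = NULL, direction = c("in", "out")) {
  direction <- match.arg(direction)
  M <- as.matrix(adjacency)
  N <- nrow(M)
  if (N != ncol(M)) stop("adjacency must be square")
  if (!all(M %in% c(0, 1))) stop("adjacency entries must be 0 or 1")
  if (any(diag(M) != 0)) stop("self-loops are not allowed")
  if (!directed && !isTRUE(all.equal(M, t(M)))) {
    stop("undirected graph needs a symmetric adjacency matrix")
  }
  expand <- function(v, name) {
    if (is.null(v)) return(NULL)
    if (length(v) == 1) v <- matrix(as.numeric(v), N, N)
    v <- as.matrix(v)
    if (any(v[M == 1] < 0)) stop(name, " must be nonnegative on every edge")
    if (!directed && !isTRUE(all.equal(v * M, t(v * M)))) {
      stop(name, " must be symmetric on an undirected graph")
    }
    v
  }
  structure(list(
    N = N, adjacency = M, directed = directed, direction = direction,
    nu = expand(nu, "nu"), p = expand(p, "p"), tau = expand(tau, "tau")
  ), class = "network_graph")
}

#' @export
print.network_graph <- function(x, ...) {
  cat(sprintf("network_graph: %d nodes, %s, %d edges (max degree %d)\n",
              x$N, if (x$directed) paste0("directed (", x$direction, ")") else "undirected",
              if (x$directed) sum(x$adjacency) else sum(x$adjacency) / 2,
              max_degree(x)))
  invisible(x)
}

#' Neighbor set used by the transport term
#'
#' For undirected graphs, the adjacent nodes; for directed graphs, the
#' in-neighbors under the default `"in"` convention (nodes whose arcs point
#' at `i`), or the out-neighbors under `"out"`.
#'
#' @param G a [network_graph].
#' @param i node index (1-based).
#' @return integer vector of node indices.
#' @export
neighbors <- function(G, i) {
  if (i < 1 || i > G$N) stop("node index ", i, " out of range 1..", G$N)
  which(neighbor_matrix(G)[i, ] == 1)
}

# adjacency as seen by the transport sum: row i lists the nodes j whose state
# enters node i's balance
neighbor_matrix <- function(G) {
  if (!G$directed || G$direction == "out") G$adjacency else t(G$adjacency)
}

#' Maximum degree of the transport-relevant neighbor sets
#'
#' @param G a [network_graph].
#' @return integer `max_i |c(i)|`.
#' @export
max_degree <- function(G) {
  max(rowSums(neighbor_matrix(G)))
}

#' Transfer-velocity stability bound
#'
#' Asymptotic stability of an ESS shared by every node is guaranteed for
#' transfer velocities below `1 / max_degree`; an edgeless graph imposes no
#' constraint (`Inf`).
#'
#' @param G a [network_graph].
#' @return `1 / max_degree(G)`, or `Inf` when the graph has no edges.
#' @export
stability_bound <- function(G) {
  d <- max_degree(G)
  if (d == 0) Inf else 1 / d
}

#' Per-node transport stability margins
#'
#' For each node i with state `x^i`, computes the margin
#' `x*'Ax^i - x^i'Ax^i - nu |c(i)|`.  When every margin is positive the
#' Lyapunov argument applies and the shared ESS `x*` is asymptotically stable
#' under linear transport.  Note the condition fails identically at
#' `x^i = x*` (the first two terms cancel); it is a condition on a punctured
#' neighborhood.
#'
#' @param G a [network_graph].
#' @param A a [payoff_matrix].
#' @param xstar the shared equilibrium state.
#' @param states N x n matrix of node states (rows on the simplex).
#' @param nu transfer velocity (scalar).
#' @return list with `margins` (length N), `satisfied` (all margins > 0),
#'   `nu`, `delta` (max degree) and `bound` (`1/delta`).
#' @export
transport_stability_margins <- function(G, A, xstar, states, nu) {
  states <- as.matrix(states)
  if (nrow(states) != G$N) stop("states must have one row per node")
  xstar <- check_simplex(xstar, nrow(A), what = "xstar")
  deg <- rowSums(neighbor_matrix(G))
  margins <- vapply(seq_len(G$N), function(i) {
    xi <- check_simplex(states[i, ], nrow(A), what = sprintf("states[%d,]", i))
    f <- drop(A %*% xi)
    sum(xstar * f) - sum(xi * f) - nu * deg[i]
  }, numeric(1))
  list(margins = margins, satisfied = all(margins > 0),
       nu = nu, delta = max_degree(G), bound = stability_bound(G))
}

#' Prototype topologies
#'
#' `build_inline(N)` is the chain 1-2-...-N.  `build_triangle()` is the
#' 3-cycle; its oriented variant is the directed cycle 1 -> 2 -> 3 -> 1.
#' `build_roundabout()` has 6 nodes: two chain stubs 1-2 and 5-6 attached to
#' the quadrangle 2-3-5-4; the oriented variant directs the quadrangle
#' 2 -> 3 -> 5 -> 4 -> 2 with entry arc 1 -> 2 and exit arc 5 -> 6.
#'
#' @param N chain length (>= 2).
#' @param oriented build the directed variant.
#' @return a [network_graph].
#' @export
build_inline <- function(N) {
  if (N < 2) stop("a chain needs at least 2 nodes")
  M <- matrix(0, N, N)
  for (i in seq_len(N - 1)) M[i, i + 1] <- M[i + 1, i] <- 1
  network_graph(M)
}

#' @rdname build_inline
#' @export
build_triangle <- function(oriented = FALSE) {
  if (!oriented) {
    M <- 1 - diag(3)
    network_graph(M)
  } else {
    M <- matrix(0, 3, 3)
    M[1, 2] <- M[2, 3] <- M[3, 1] <- 1
    network_graph(M, directed = TRUE)
  }
}

roundabout_arcs <- list(
  undirected = rbind(c(1, 2), c(2, 3), c(2, 4), c(3, 5), c(4, 5), c(5, 6)),
  oriented   = rbind(c(1, 2), c(2, 3), c(3, 5), c(5, 4), c(4, 2), c(5, 6))
)

#' @rdname build_inline
#' @export
build_roundabout <- function(oriented = FALSE) {
  M <- matrix(0, 6, 6)
  arcs <- roundabout_arcs[[if (oriented) "oriented" else "undirected"]]
  for (r in seq_len(nrow(arcs))) {
    M[arcs[r, 1], arcs[r, 2]] <- 1
    if (!oriented) M[arcs[r, 2], arcs[r, 1]] <- 1
  }
  network_graph(M, directed = oriented)
}

#' Build a named prototype network
#'
#' @param name one of `"inline"`, `"triangle"`, `"triangle-oriented"`,
#'   `"roundabout"`, `"roundabout-oriented"`.
#' @param N chain length for `"inline"`.
#' @return a [network_graph].
#' @export
build_network <- function(name, N = 3) {
  switch(name,
    "inline" = build_inline(N),
    "triangle" = build_triangle(FALSE),
    "triangle-oriented" = build_triangle(TRUE),
    "roundabout" = build_roundabout(FALSE),
    "roundabout-oriented" = build_roundabout(TRUE),
    stop("unknown network '", name, "'")
  )
}

#' Edge-list I/O
#'
#' Reads/writes a CSV with columns `src,dst,nu,p,tau` (1-based node indices;
#' one row per undirected edge or per directed arc).  Missing parameter
#' columns are written as NA and read back as unset.
#'
#' @param G a [network_graph].
#' @param path file path.
#' @param directed whether the rows are directed arcs.
#' @return `read_edge_list` returns a [network_graph]; `write_edge_list`
#'   returns `path` invisibly.
#' @export
write_edge_list <- function(G, path) {
  M <- G$adjacency
  idx <- which(M == 1, arr.ind = TRUE)
  if (!G$directed) idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  getp <- function(P) if (is.null(P)) rep(NA_real_, nrow(idx)) else P[idx]
  df <- data.frame(src = idx[, 1], dst = idx[, 2],
                   nu = getp(G$nu), p = getp(G$p), tau = getp(G$tau))
  df <- df[order(df$src, df$dst), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path, directed = FALSE) {
  df <- utils::read.csv(path)
  need <- c("src", "dst")
  if (!all(need %in% names(df))) stop("edge list needs columns src,dst")
  N <- max(df$src, df$dst)
  M <- matrix(0, N, N)
  mk <- function(col) {
    if (!col %in% names(df) || all(is.na(df[[col]]))) return(NULL)
    P <- matrix(0, N, N)
    P[cbind(df$src, df$dst)] <- df[[col]]
    if (!directed) P[cbind(df$dst, df$src)] <- df[[col]]
    P
  }
  M[cbind(df$src, df$dst)] <- 1
  if (!directed) M[cbind(df$dst, df$src)] <- 1
  network_graph(M, directed = directed, nu = mk("nu"), p = mk("p"), tau = mk("tau"))
}
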