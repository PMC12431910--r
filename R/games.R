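#' Payoff matrices and single-node replicator dynamics
#'
#' A payoff (fitness) matrix is an n x n real matrix A whose product with a
#' frequency vector x on the probability simplex gives each species' fitness
#' (Ax)_k.  The replicator equation evolves each frequency at a rate equal to
#' its fitness advantage over the population average x'Ax.
#'
#' @name games
NULL

#' Construct a payoff matrix
#'
#' @param entries numeric n x n matrix of (dimensionless) payoffs, n >= 2.
#' @param label optional free-text label, e.g. `"RPS"`.
#' @return an object of class `payoff_matrix` (a plain matrix with a label
#'   attribute).
#' @export
payoff_matrix <- function(entries, label = "") {
  entries <- as.matrix(entries)
  if (nrow(entries) != ncol(entries)) {
    stop("payoff matrix must be square, got ", nrow(entries), " x ", ncol(entries))
  }
  if (nrow(entries) < 2) stop("payoff matrix needs at least 2 species")
  if (!all(is.finite(entries))) stop("payoff matrix entries must be finite")
  storage.mode(entries) <- "double"
  structure(entries, label = label, class = c("payoff_matrix", "matrix", "array"))
}

#' @export
print.payoff_matrix <- function(x, ...) {
  lab <- attr(x, "label")
  cat("payoff matrix", if (nzchar(lab)) paste0("'", lab, "'") else "",
      sprintf("(%d species)\n", nrow(x)))
  print(unclass(structure(x, label = NULL)))
  invisible(x)
}

#' Built-in named games
#'
#' `"RPS"` is the cyclic rock-paper-scissors game (skew-symmetric, zero-sum);
#' `"HDG"` is a hawk-dove variant in which the dove also receives a positive
#' payoff in asymmetric encounters.
#'
#' @param name `"RPS"` or `"HDG"` (case-insensitive).
#' @return a [payoff_matrix].
#' @examples
#' builtin_game("RPS")
#' interior_equilibrium(builtin_game("HDG"))
#' @export
builtin_game <- function(name) {
  switch(toupper(name),
    RPS = payoff_matrix(matrix(c(
      0,  1, -1,
      -1, 0,  1,
      1, -1,  0), 3, 3, byrow = TRUE), label = "RPS"),
    HDG = payoff_matrix(matrix(c(
      2, 3,
      4, 1), 2, 2, byrow = TRUE), label = "HDG"),
    stop("unknown game '", name, "'; available: RPS, HDG")
  )
}

# internal: validate a simplex point against A's dimension
check_simplex <- function(x, n = NULL, tol = 1e-9, what = "x") {
  x <- as.numeric(x)
  if (!is.null(n) && length(x) != n) {
    stop(what, " has length ", length(x), " but the payoff matrix is ", n, " x ", n)
  }
  if (any(x < -tol)) stop(what, " has negative coordinates beyond tolerance ", tol)
  if (abs(sum(x) - 1) > tol) {
    stop(what, " does not sum to 1 (sum = ", format(sum(x)), ", tol = ", tol, ")")
  }
  x
}

#' Membership test for the probability simplex
#'
#' @param x numeric vector.
#' @param tol nonnegative tolerance for the nonnegativity and unit-sum checks.
#' @return logical.
#' @export
on_simplex <- function(x, tol = 1e-9) {
  all(x >= -tol) && abs(sum(x) - 1) <= tol
}

#' Species fitness vector
#'
#' Fitness of species k at state x is `(A x)_k`.
#'
#' @param A a [payoff_matrix] (or plain square matrix).
#' @param x frequency vector on the simplex.
#' @return numeric vector `A %*% x`.
#' @export
fitness <- function(A, x) {
  x <- check_simplex(x, nrow(A))
  drop(A %*% x)
}

#' Population-average fitness
#'
#' The quadratic form `x' A x`.
#'
#' @inheritParams fitness
#' @return scalar.
#' @export
average_fitness <- function(A, x) {
  x <- check_simplex(x, nrow(A))
  drop(crossprod(x, A %*% x))
}

#' Single-node replicator vector field
#'
#' `xdot_k = x_k ((Ax)_k - x'Ax)`.  Components sum to zero on the simplex and
#' vanish on faces (`x_k = 0` implies `xdot_k = 0` exactly), so the simplex is
#' invariant for an isolated node.
#'
#' @inheritParams fitness
#' @return numeric vector of the same length as `x`.
#' @export
replicator_rhs <- function(A, x) {
  x <- check_simplex(x, nrow(A))
  f <- drop(A %*% x)
  x * (f - drop(crossprod(x, f)))
}

#' Interior equilibrium of a replicator game
#'
#' Solves the linear system `(Ax)_k = x'Ax` for all k, i.e. the equal-fitness
#' conditions `(Ax)_k - (Ax)_n = 0` (k = 1..n-1) together with `sum(x) = 1`.
#' The solution is returned only when it lies in the open simplex (all
#' coordinates strictly positive).
#'
#' @param A a [payoff_matrix].
#' @param tol rank / positivity tolerance.
#' @return the equilibrium as a numeric vector with a `status` attribute
#'   (`"interior"`), or a zero-length numeric with `status` `"absent"` (no
#'   interior solution) or `"degenerate"` (a singular system admitting a
#'   manifold of equilibria).
#' @export
interior_equilibrium <- function(A, tol = 1e-10) {
  n <- nrow(A)
  if (n != ncol(A)) stop("payoff matrix must be square")
  # rows: (A[k,] - A[n,]) x = 0 for k < n; last row: sum(x) = 1
  B <- rbind(sweep(A[-n, , drop = FALSE], 2, A[n, ]), rep(1, n))
  rhs <- c(rep(0, n - 1), 1)
  sv <- svd(B)
  rank <- sum(sv$d > tol * max(sv$d))
  if (rank < n) {
    # singular: either inconsistent or a solution manifold
    # least-squares residual decides
    xls <- sv$v %*% ((ifelse(sv$d > tol * max(sv$d), 1 / sv$d, 0)) * crossprod(sv$u, rhs))
    if (max(abs(B %*% xls - rhs)) < 1e-8) {
      return(structure(numeric(0), status = "degenerate"))
    }
    return(structure(numeric(0), status = "absent"))
  }
  x <- drop(solve(B, rhs))
  if (all(x > tol)) structure(x, status = "interior")
  else structure(numeric(0), status = "absent")
}

#' Nash equilibrium test
#'
#' A state `x*` is a Nash equilibrium when `x*'Ax* >= x'Ax*` for every simplex
#' state x.  Because `x -> x'Ax*` is linear over the simplex, its maximum is
#' attained at a vertex, so it suffices to compare `x*'Ax*` with each
#' `(Ax*)_k` -- an exact, finite check.
#'
#' @param A a [payoff_matrix].
#' @param xstar candidate state on the simplex.
#' @param tol slack allowed in the vertex comparisons.
#' @return logical.
#' @export
is_nash <- function(A, xstar, tol = 1e-9) {
  xstar <- check_simplex(xstar, nrow(A), what = "xstar")
  f <- drop(A %*% xstar)
  all(drop(crossprod(xstar, f)) >= f - tol)
}

#' Fixed-point test for the replicator field
#'
#' @inheritParams is_nash
#' @return logical: `TRUE` when the replicator field vanishes at `xstar`.
#' @export
is_fixed_point <- function(A, xstar, tol = 1e-9) {
  max(abs(replicator_rhs(A, xstar))) <= tol
}

#' Evolutionarily stable state test
#'
#' `x*` is an ESS when `x*'Ax > x'Ax` for all simplex states x near `x*`
#' (equivalently: nearby invading mixtures score strictly less against
#' themselves than the incumbent does).  For two species the test is exact
#' (sign analysis of the quadratic in one variable, using the diagonal
#' reduction a' = a - c, b' = d - b); for n >= 3 the condition is verified on
#' seeded random simplex points within `radius` of `x*`, after the (exact)
#' Nash pre-check.
#'
#' @param A a [payoff_matrix].
#' @param xstar candidate state on the simplex.
#' @param radius sampling neighborhood radius (Euclidean, restricted to the
#'   simplex).  Default 0.1.
#' @param n_samples number of seeded test points for the sampled branch.
#' @param seed integer seed for the sampled branch.
#' @param tol strictness tolerance for the inequality.
#' @param method `"auto"` picks the exact branch for n = 2 and sampling
#'   otherwise; `"exact"` forces the closed form (n = 2 only); `"sampled"`
#'   forces the sampler (any n, used to cross-validate the two branches).
#' @return logical.
#' @export
is_ess <- function(A, xstar, radius = 0.1, n_samples = 200, seed = 1,
                   tol = 1e-12, method = c("auto", "exact", "sampled")) {
  method <- match.arg(method)
  if (radius <= 0) stop("radius must be positive")
  if (n_samples < 1) stop("n_samples must be at least 1")
  n <- nrow(A)
  xstar <- check_simplex(xstar, n, what = "xstar")
  if (method == "exact" && n != 2) stop("the exact branch needs n = 2")
  if (!is_nash(A, xstar)) return(FALSE)
  if (n == 2 && method != "sampled") return(ess_exact_2x2(A, xstar))
  pts <- random_simplex_point(n, seed = seed, n_points = n_samples)
  for (m in seq_len(n_samples)) {
    y <- pts[m, ]
    d <- y - xstar
    nd <- sqrt(sum(d^2))
    if (nd < 1e-12) next
    x <- xstar + min(1, radius / nd) * d  # convex combination: stays in simplex
    psi <- sum((xstar - x) * drop(A %*% x))
    if (psi <= tol) return(FALSE)
  }
  TRUE
}

# exact ESS classification for 2 species via the diagonal reduction.
# With x = (z, 1-z), x* = (z*, 1-z*) and reduced payoffs a' = a - c,
# b' = d - b, the invasion margin is (z* - z)(a'z - b'(1-z)).
ess_exact_2x2 <- function(A, xstar) {
  ap <- A[1, 1] - A[2, 1]
  bp <- A[2, 2] - A[1, 2]
  zs <- xstar[1]
  if (abs(zs - 1) < 1e-12) {          # vertex (1, 0)
    ap > 0 || (ap == 0 && bp < 0)
  } else if (abs(zs) < 1e-12) {       # vertex (0, 1)
    bp > 0 || (bp == 0 && ap < 0)
  } else {
    # interior candidate: must be the mixed equilibrium b'/(a'+b')
    if (abs(zs - bp / (ap + bp)) > 1e-9) return(FALSE)
    ap + bp < 0
  }
}

#' Diagonal reduction of a payoff matrix
#'
#' Subtracting a constant from each column of A leaves the replicator field
#' unchanged on the simplex.  For two species the off-diagonal entries are
#' used as the per-column reference, giving `diag(a - c, d - b)`; for n >= 3
#' the designated reference row (default the last) is subtracted from every
#' row, so that row becomes zero.
#'
#' @param A a [payoff_matrix].
#' @param ref reference row for the general-n branch.
#' @return a [payoff_matrix] with the same replicator field.
#' @export
diagonal_reduction <- function(A, ref = nrow(A)) {
  n <- nrow(A)
  if (n == 2) {
    out <- diag(c(A[1, 1] - A[2, 1], A[2, 2] - A[1, 2]))
  } else {
    out <- sweep(unclass(A), 2, A[ref, ])
  }
  payoff_matrix(out, label = paste0(attr(A, "label"), "'"))
}

#' Invasion margin against an incumbent state
#'
#' `psi(x) = sum_k (x*_k - x_k) (Ax)_k = x*'Ax - x'Ax`: positive when the
#' incumbent `x*` out-scores the invading mixture x against x itself.
#'
#' @param A a [payoff_matrix].
#' @param xstar incumbent state on the simplex.
#' @param x invading state on the simplex.
#' @return scalar.
#' @export
ess_gap <- function(A, xstar, x) {
  xstar <- check_simplex(xstar, nrow(A), what = "xstar")
  x <- check_simplex(x, nrow(A))
  sum((xstar - x) * drop(A %*% x))
}

#' Full equilibrium report for a candidate state
#'
#' @inheritParams is_ess
#' @return a list with flags `is_interior`, `is_fixed_point`, `is_nash`,
#'   `is_ess` and the point itself.
#' @export
classify_equilibrium <- function(A, xstar, radius = 0.1, n_samples = 200, seed = 1) {
  xstar <- check_simplex(xstar, nrow(A), what = "xstar")
  fp <- is_fixed_point(A, xstar)
  nash <- fp && is_nash(A, xstar)
  list(
    point = xstar,
    is_interior = all(xstar > 0),
    is_fixed_point = fp,
    is_nash = nash,
    is_ess = nash && is_ess(A, xstar, radius, n_samples, seed)
  )
}

# run expr with a private RNG stream; global .Random.seed is untouched
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Random payoff matrix
#'
#' Entries are independent draws from a centered normal with standard
#' deviation `scale`; deterministic under a fixed seed.
#'
#' @param n species count (>= 2).
#' @param scale spread of the entries.
#' @param seed integer seed.
#' @return a [payoff_matrix].
#' @export
random_payoff <- function(n, scale = 1, seed = 1) {
  if (n < 2) stop("need at least 2 species")
  if (scale < 0) stop("scale must be nonnegative")
  entries <- with_seed(seed, matrix(stats::rnorm(n * n, sd = 1), n, n) * scale)
  payoff_matrix(entries, label = sprintf("random(n=%d, seed=%d)", n, seed))
}

#' Uniform random point(s) on the simplex
#'
#' Flat Dirichlet draws (normalized unit-rate exponentials), deterministic
#' under a fixed seed.
#'
#' @param n simplex dimension (species count, >= 2).
#' @param seed integer seed.
#' @param n_points number of points; for `n_points > 1` a matrix with one
#'   point per row is returned.
#' @return numeric vector, or `n_points` x `n` matrix.
#' @export
random_simplex_point <- function(n, seed = 1, n_points = 1) {
  if (n < 2) stop("simplex dimension must be at least 2")
  e <- with_seed(seed, matrix(stats::rexp(n_points * n), n_points, n))
  pts <- e / rowSums(e)
  if (n_points == 1) drop(pts) else pts
}
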