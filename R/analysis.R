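#' Post-processing: error norms, convergence orders, event times
#'
#' @name analysis
NULL

#' Discrete error norms between a trajectory and a finer reference
#'
#' Differences are taken at the coarse trajectory's stored times (the
#' reference grid must contain them) over all nodes and species.  The
#' L-infinity error is the maximum absolute difference; the L2 error is the
#' time-weighted root sum of squares `sqrt(dt * sum(diff^2))` with `dt` the
#' coarse step.
#'
#' @param traj a `trajectory`.
#' @param ref a reference `trajectory` of the same model on a nested grid.
#' @return list with `l2` and `linf`.
#' @export
trajectory_error <- function(traj, ref) {
  dt <- traj$times[2] - traj$times[1]
  dtr <- ref$times[2] - ref$times[1]
  ratio <- dt / dtr
  if (abs(ratio - round(ratio)) > 1e-6) {
    stop("reference grid does not contain the trajectory's grid (dt ratio ",
         format(ratio), ")")
  }
  ratio <- round(ratio)
  m <- length(traj$times)
  idx <- seq(1, by = ratio, length.out = m)
  if (idx[m] > length(ref$times)) stop("reference trajectory is too short")
  diffs <- traj$states - ref$states[idx, , , drop = FALSE]
  list(l2 = sqrt(dt * sum(diffs^2)), linf = max(abs(diffs)))
}

#' Experimental orders of convergence
#'
#' Entry i (i >= 2) is `log(e[i-1]/e[i]) / log(dt[i-1]/dt[i])`; the first
#' entry is `NA`.  Zero errors yield `NA` entries.
#'
#' @param errors positive error norms.
#' @param dts matching, strictly decreasing step sizes.
#' @return numeric vector of the same length, first entry `NA`.
#' @export
eoc <- function(errors, dts) {
  if (length(errors) != length(dts)) stop("errors and dts must match in length")
  if (any(diff(dts) >= 0)) stop("dts must be strictly decreasing")
  out <- rep(NA_real_, length(errors))
  for (i in seq_along(errors)[-1]) {
    if (errors[i - 1] > 0 && errors[i] > 0) {
      out[i] <- log(errors[i - 1] / errors[i]) / log(dts[i - 1] / dts[i])
    }
  }
  out
}

#' Time to reach an equilibrium state
#'
#' The earliest stored time t* such that every node stays within `tol` (max
#' norm over nodes and species) of `xstar` at all stored times >= t*.
#'
#' The default tolerance 1e-3 is calibrated so that, for games whose reduced
#' dynamics contract like `exp(-t)` near the mixed state, the reported time
#' matches when trajectories become visually indistinguishable from the
#' equilibrium.
#'
#' @param traj a `trajectory`.
#' @param xstar target state (length-n vector).
#' @param tol max-norm tolerance (default 1e-3).
#' @return list with `time` (`NA` when never reached within the horizon),
#'   `tol` and `final_deviation`.
#' @export
time_to_equilibrium <- function(traj, xstar, tol = 1e-3) {
  if (tol <= 0) stop("tol must be positive")
  dev <- apply(abs(sweep(traj$states, 3, xstar)), 1, max)
  # sup over the trailing window via reversed running maximum
  trail <- rev(cummax(rev(dev)))
  ok <- which(trail < tol)
  list(time = if (length(ok)) traj$times[ok[1]] else NA_real_,
       tol = tol, final_deviation = dev[length(dev)])
}

#' Time after which all nodes are synchronized
#'
#' The earliest stored time after which the largest inter-node spread (max
#' over species of the node-wise range) stays below `tol` at every
#' subsequent stored time.
#'
#' @param traj a `trajectory` with at least 2 nodes.
#' @param tol spread tolerance (default 1e-3).
#' @return earliest stored time, or `NA` when never synchronized.
#' @export
synchronization_time <- function(traj, tol = 1e-3) {
  if (tol <= 0) stop("tol must be positive")
  d <- dim(traj$states)
  if (d[2] < 2) stop("synchronization needs at least 2 nodes")
  spread <- apply(traj$states, c(1, 3), function(v) max(v) - min(v))
  worst <- apply(spread, 1, max)
  trail <- rev(cummax(rev(worst)))
  ok <- which(trail < tol)
  if (length(ok)) traj$times[ok[1]] else NA_real_
}

#' Barycentric to Cartesian coordinates for three species
#'
#' Maps a 3-species simplex point to the equilateral triangle in the plane:
#' `(x1 + x2/2, sqrt(3)/2 * x2)`, so the vertices (1,0,0), (0,1,0), (0,0,1)
#' go to (1,0), (1/2, sqrt(3)/2) and (0,0).
#'
#' @param x length-3 frequency vector, or a matrix with 3 columns.
#' @return length-2 vector, or a 2-column matrix.
#' @export
to_cartesian <- function(x) {
  if (is.null(dim(x))) {
    if (length(x) != 3) stop("barycentric mapping needs exactly 3 species")
    c(x[1] + x[2] / 2, sqrt(3) / 2 * x[2])
  } else {
    if (ncol(x) != 3) stop("barycentric mapping needs exactly 3 species")
    cbind(x[, 1] + x[, 2] / 2, sqrt(3) / 2 * x[, 2])
  }
}

#' Grid-refinement convergence study
#'
#' Runs the model once per step size plus once on a fine reference grid
#' (same scheme), then tabulates L2 / L-infinity errors and experimental
#' orders of convergence.
#'
#' @param M a [model_spec].
#' @param x0 initial ensemble state.
#' @param dts strictly decreasing step sizes.
#' @param reference_dt fine reference step; must divide every entry of
#'   `dts`.
#' @param t_end shared horizon.
#' @param epsilon corrector tolerance passed to every run.
#' @return a `convergence_report` data frame with columns `dt`, `l2`,
#'   `eoc2`, `linf`, `eocinf`.
#' @export
run_convergence_study <- function(M, x0, dts, reference_dt, t_end,
                                  epsilon = 1e-14) {
  if (any(diff(dts) >= 0)) stop("dts must be strictly decreasing")
  for (dt in dts) {
    r <- dt / reference_dt
    if (abs(r - round(r)) > 1e-6) {
      stop("reference_dt must divide every dt (fails for dt = ", dt, ")")
    }
  }
  # store the reference only at the coarsest resolution all grids share
  stride <- round(min(dts) / reference_dt)
  n_ref <- round(t_end / reference_dt)
  if (n_ref %% stride != 0) stride <- 1
  ref <- integrate_model(M, x0, integrator_config(
    dt = reference_dt, t_end = t_end, epsilon = epsilon, store_every = stride))
  # stored reference grid now has spacing min(dts)
  l2 <- linf <- numeric(length(dts))
  for (q in seq_along(dts)) {
    traj <- integrate_model(M, x0, integrator_config(
      dt = dts[q], t_end = t_end, epsilon = epsilon))
    err <- trajectory_error(traj, ref)
    l2[q] <- err$l2
    linf[q] <- err$linf
  }
  out <- data.frame(dt = dts, l2 = l2, eoc2 = eoc(l2, dts),
                    linf = linf, eocinf = eoc(linf, dts))
  attr(out, "reference_dt") <- reference_dt
  attr(out, "t_end") <- t_end
  class(out) <- c("convergence_report", "data.frame")
  out
}

#' Write a convergence report as CSV
#'
#' @param report a `convergence_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_convergence_csv <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
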