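#' Experiment presets
#'
#' Canned configurations for the benchmark experiments: a single node playing
#' rock-paper-scissors (four initial conditions), two- and three-species
#' games on the prototype networks with linear transport, and the delayed
#' transport experiment on the roundabout.
#'
#' @name presets
NULL

#' Single-node rock-paper-scissors benchmark
#'
#' One node, RPS payoffs, `dt = 0.01`.  Initial conditions:
#' IC1 = (0.9, 0.05, 0.05), IC2 = (0.4, 0.4, 0.2), IC3 = (1/3, 1/3, 1/3)
#' (the mixed equilibrium), IC4 = (0.6, 0.1, 0.3).
#'
#' @param ic_label one of `"IC1"`..`"IC4"`.
#' @param t_end horizon (default 100).
#' @param dt step size (default 0.01).
#' @return a `run_config` list.
#' @export
preset_test1 <- function(ic_label = c("IC1", "IC2", "IC3", "IC4"),
                         t_end = 100, dt = 0.01) {
  ic_label <- match.arg(ic_label)
  ics <- list(
    IC1 = c(0.9, 0.05, 0.05),
    IC2 = c(0.4, 0.4, 0.2),
    IC3 = c(1 / 3, 1 / 3, 1 / 3),
    IC4 = c(0.6, 0.1, 0.3)
  )
  run_config(
    network = "none", game = "RPS",
    transport = transport_spec("none"),
    initial_conditions = matrix(ics[[ic_label]], nrow = 1),
    integrator = integrator_config(dt = dt, t_end = t_end),
    label = paste0("test1-", ic_label)
  )
}

#' Linear-transport network benchmark
#'
#' Node 1 starts at the mixed equilibrium of the game, all other nodes at a
#' pure state.  With two species the game is the hawk-dove variant, node 1 =
#' (1/2, 1/2), others = (0, 1); with three species the game is RPS, node 1 =
#' (1/3, 1/3, 1/3), others = (0, 1, 0).  A transfer velocity at or above the
#' network's stability bound is accepted with a warning (that regime is
#' explored deliberately).
#'
#' @param network `"inline"`, `"triangle"`, `"triangle-oriented"`,
#'   `"roundabout"` or `"roundabout-oriented"`.
#' @param nu transfer velocity.
#' @param n_species 2 (hawk-dove) or 3 (RPS).
#' @param t_end horizon; defaults to 20 for two species, 200 for three.
#' @param dt step size (default 0.01).
#' @return a `run_config` list.
#' @export
preset_test2_linear <- function(network, nu, n_species = 2,
                                t_end = if (n_species == 2) 20 else 200,
                                dt = 0.01) {
  if (nu < 0) stop("nu must be nonnegative")
  G <- build_network(network)
  if (nu >= stability_bound(G)) {
    warning("nu = ", nu, " is at or above the stability bound ",
            format(stability_bound(G)), " for the ", network, " network")
  }
  if (n_species == 2) {
    game <- "HDG"
    mixed <- c(1 / 2, 1 / 2)
    pure <- c(0, 1)
  } else if (n_species == 3) {
    game <- "RPS"
    mixed <- c(1 / 3, 1 / 3, 1 / 3)
    pure <- c(0, 1, 0)
  } else {
    stop("n_species must be 2 or 3")
  }
  x0 <- rbind(mixed, matrix(pure, G$N - 1, n_species, byrow = TRUE))
  rownames(x0) <- NULL
  run_config(
    network = network, game = game,
    transport = transport_spec("linear", nu = nu),
    initial_conditions = x0,
    integrator = integrator_config(dt = dt, t_end = t_end),
    label = sprintf("test2-linear-%s-nu%g", network, nu)
  )
}

#' Delayed-transport roundabout benchmark
#'
#' Roundabout network, RPS on all nodes, survival rate `p = 2` on every
#' edge.  Travel times: `tau1` on the stub edges (1-2 and 5-6), `tau2` on
#' the quadrangle edges (2-3, 3-5, 5-4, 4-2).  Node 1 starts at the mixed
#' equilibrium; nodes 2-6 are seeded uniform draws on the simplex.
#'
#' The preset uses the `"departure"` delayed-transport formulation (arrivals
#' that left the neighbor one travel time ago, relaxing the node's current
#' state): it keeps trajectories on the simplex and produces the bounded,
#' synchronizing dynamics this experiment is about, whereas the `"printed"`
#' variant drives the ensemble off the unit interval (see the methods
#' vignette).
#'
#' @param tau1 stub travel time.
#' @param tau2 quadrangle travel time.
#' @param seed integer seed for the random initial conditions.
#' @param t_end horizon (default 200).
#' @param dt step size (default 0.01).
#' @param formulation delayed-transport variant, see [transport_spec].
#' @return a `run_config` list.
#' @export
preset_test2_nonlinear <- function(tau1 = 1 / 2, tau2 = 1, seed = 1,
                                   t_end = 200, dt = 0.01,
                                   formulation = "departure") {
  if (tau1 < 0 || tau2 < 0) stop("travel times must be nonnegative")
  G <- build_roundabout()
  tau <- matrix(0, 6, 6)
  stub <- rbind(c(1, 2), c(5, 6))
  quad <- rbind(c(2, 3), c(3, 5), c(5, 4), c(4, 2))
  for (r in seq_len(nrow(stub))) {
    tau[stub[r, 1], stub[r, 2]] <- tau[stub[r, 2], stub[r, 1]] <- tau1
  }
  for (r in seq_len(nrow(quad))) {
    tau[quad[r, 1], quad[r, 2]] <- tau[quad[r, 2], quad[r, 1]] <- tau2
  }
  G <- network_graph(G$adjacency, tau = tau)
  x0 <- rbind(c(1, 1, 1) / 3,
              random_simplex_point(3, seed = seed, n_points = 5))
  run_config(
    network = G, game = "RPS",
    transport = transport_spec("delayed", p = 2, tau = 0,
                               formulation = formulation),
    initial_conditions = x0,
    integrator = integrator_config(dt = dt, t_end = t_end),
    seed = seed,
    label = sprintf("test2-nonlinear-tau1_%g-tau2_%g", tau1, tau2)
  )
}

#' Assemble a run configuration
#'
#' A fully-resolved description of one simulation: network (name, edge-list
#' path, or `network_graph`), game (name, CSV path, or `payoff_matrix`),
#' transport, initial conditions and integrator settings.
#'
#' @param network network name (see [build_network]), `"none"` for a single
#'   node, a path to an edge-list CSV, or a [network_graph].
#' @param game game name (see [builtin_game]), a path to a payoff CSV, or a
#'   [payoff_matrix].
#' @param transport a [transport_spec].
#' @param initial_conditions N x n matrix, or the string `"random"` (seeded
#'   simplex draws).
#' @param integrator an [integrator_config].
#' @param seed integer seed used when initial conditions are random.
#' @param label free text.
#' @return a `run_config` list.
#' @export
run_config <- function(network, game, transport = transport_spec("none"),
                       initial_conditions = "random",
                       integrator = integrator_config(), seed = 1,
                       label = "") {
  structure(list(network = network, game = game, transport = transport,
                 initial_conditions = initial_conditions,
                 integrator = integrator, seed = seed, label = label),
            class = "run_config")
}

resolve_network <- function(network) {
  if (inherits(network, "network_graph")) return(network)
  if (identical(network, "none")) {
    return(network_graph(matrix(0, 1, 1)))
  }
  if (file.exists(network)) return(read_edge_list(network))
  build_network(network)
}

resolve_game <- function(game) {
  if (inherits(game, "payoff_matrix")) return(game)
  if (file.exists(game)) return(read_payoff_csv(game))
  builtin_game(game)
}

#' Resolve a run configuration into model, initial state and settings
#'
#' @param config a `run_config`.
#' @return list with `model` ([model_spec]), `x0` and `integrator`.
#' @export
resolve_config <- function(config) {
  G <- resolve_network(config$network)
  A <- resolve_game(config$game)
  M <- model_spec(G, A, config$transport)
  x0 <- config$initial_conditions
  if (identical(x0, "random")) {
    x0 <- random_simplex_point(nrow(A), seed = config$seed, n_points = G$N)
    if (is.null(dim(x0))) x0 <- matrix(x0, nrow = 1)
  }
  list(model = M, x0 = unname(as.matrix(x0)), integrator = config$integrator)
}

#' Execute a run configuration
#'
#' Integrates the configured model and, when `out_dir` is given, writes the
#' tidy trajectory CSV (`time,node,species,frequency`) and a JSON run report
#' (label, settings, corrector statistics, simplex-drift maxima).  Outputs
#' are deterministic given the configuration and seed.
#'
#' @param config a `run_config`.
#' @param out_dir optional output directory.
#' @param stride down-sampling stride for the trajectory CSV.
#' @return the `trajectory`, invisibly when writing files.
#' @export
run_experiment <- function(config, out_dir = NULL, stride = 1) {
  rc <- resolve_config(config)
  traj <- integrate_model(rc$model, rc$x0, rc$integrator)
  if (is.null(out_dir)) return(traj)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  df <- trajectory_frame(traj)
  if (stride > 1) {
    keep <- traj$times[seq(1, length(traj$times), by = stride)]
    df <- df[df$time %in% keep, ]
  }
  utils::write.csv(df, file.path(out_dir, "trajectory.csv"), row.names = FALSE)
  report <- list(
    label = config$label, seed = config$seed,
    dt = rc$integrator$dt, t_end = rc$integrator$t_end,
    method = rc$integrator$method,
    transport = config$transport$kind,
    total_corrector_iters = traj$meta$total_corrector_iters,
    max_corrector_iters_used = traj$meta$max_corrector_iters_used,
    max_simplex_deviation = traj$meta$max_simplex_deviation,
    min_coordinate = traj$meta$min_coordinate
  )
  jsonlite::write_json(report, file.path(out_dir, "run.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(traj)
}
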