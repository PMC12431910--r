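#' File formats
#'
#' Payoff matrices travel as headerless n x n CSV; run configurations as
#' YAML; trajectories as tidy CSV (see [run_experiment]).
#'
#' @name io
NULL

#' Payoff matrix CSV I/O
#'
#' Headerless CSV, n rows by n columns.
#'
#' @param A a [payoff_matrix].
#' @param path file path.
#' @param label label for the matrix read back.
#' @return `read_payoff_csv` returns a [payoff_matrix]; `write_payoff_csv`
#'   returns `path` invisibly.
#' @export
write_payoff_csv <- function(A, path) {
  utils::write.table(unclass(structure(A, label = NULL)), path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_payoff_csv
#' @export
read_payoff_csv <- function(path, label = basename(path)) {
  payoff_matrix(as.matrix(utils::read.csv(path, header = FALSE)), label = label)
}

#' Run-configuration YAML I/O
#'
#' Round-trips a [run_config] through YAML.  Networks and games given as
#' objects are inlined (adjacency and edge-parameter matrices; payoff
#' entries); names and paths are stored as-is.
#'
#' @param config a `run_config`.
#' @param path file path.
#' @return `read_run_config` returns a `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  ser_mat <- function(m) if (is.null(m)) NULL else apply(unclass(m), 1, as.numeric, simplify = FALSE)
  net <- config$network
  if (inherits(net, "network_graph")) {
    net <- list(adjacency = ser_mat(net$adjacency), directed = net$directed,
                direction = net$direction, nu = ser_mat(net$nu),
                p = ser_mat(net$p), tau = ser_mat(net$tau))
  }
  game <- config$game
  if (inherits(game, "payoff_matrix")) {
    game <- list(entries = ser_mat(game), label = attr(game, "label"))
  }
  ic <- config$initial_conditions
  if (is.matrix(ic)) ic <- ser_mat(ic)
  doc <- list(
    label = config$label,
    seed = config$seed,
    network = net,
    game = game,
    transport = unclass(config$transport),
    initial_conditions = ic,
    integrator = unclass(config$integrator)
  )
  yaml::write_yaml(doc, path, precision = 17)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  doc <- yaml::read_yaml(path)
  known <- c("label", "seed", "network", "game", "transport",
             "initial_conditions", "integrator")
  extra <- setdiff(names(doc), known)
  if (length(extra)) stop("unknown configuration keys: ",
                          paste(extra, collapse = ", "))
  de_mat <- function(rows) {
    if (is.null(rows)) NULL else do.call(rbind, lapply(rows, as.numeric))
  }
  net <- doc$network
  if (is.list(net)) {
    net <- network_graph(de_mat(net$adjacency),
                         directed = isTRUE(net$directed),
                         nu = de_mat(net$nu), p = de_mat(net$p),
                         tau = de_mat(net$tau),
                         direction = if (is.null(net$direction)) "in" else net$direction)
  }
  game <- doc$game
  if (is.list(game)) {
    game <- payoff_matrix(de_mat(game$entries),
                          label = if (is.null(game$label)) "" else game$label)
  }
  ic <- doc$initial_conditions
  if (is.list(ic)) ic <- de_mat(ic)
  tr <- doc$transport
  it <- doc$integrator
  run_config(
    network = net, game = game,
    transport = transport_spec(tr$kind, nu = tr$nu, p = tr$p, tau = tr$tau,
                               formulation = tr$formulation),
    initial_conditions = ic,
    integrator = integrator_config(dt = it$dt, t_end = it$t_end,
                                   epsilon = it$epsilon,
                                   max_corrector_iters = it$max_corrector_iters,
                                   method = it$method,
                                   store_every = it$store_every,
                                   guard_tol = it$guard_tol),
    seed = doc$seed,
    label = doc$label
  )
}
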