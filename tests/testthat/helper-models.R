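# shared fixtures, built in code

RPS <- builtin_game("RPS")
HDG <- builtin_game("HDG")

# single-node model wrapper
single_node_model <- function(A) {
  model_spec(network_graph(matrix(0, 1, 1)), A)
}

# seeded simplex points for property sweeps
sweep_points <- function(n, m, seed = 42) {
  random_simplex_point(n, seed = seed, n_points = m)
}

# conserved quantity of the single-node RPS flow at the mixed equilibrium
rps_invariant <- function(traj) {
  apply(traj$states, 1, function(s) sum(log(s)) / 3)
}

# (2,2) Pade approximant of exp(z): the GL4 amplification factor
pade22 <- function(z) (1 + z / 2 + z^2 / 12) / (1 - z / 2 + z^2 / 12)

# transport-relevant adjacency reconstructed through the public neighbor API
neighbor_matrix_for_test <- function(G) {
  t(sapply(seq_len(G$N), function(i) as.integer(seq_len(G$N) %in% neighbors(G, i))))
}
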