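test_that("prototype topologies have the expected shape", {
  G <- build_inline(3)
  expect_equal(neighbors(G, 2), c(1L, 3L))
  expect_length(neighbors(G, 1), 1)
  expect_equal(unname(rowSums(G$adjacency)), c(1, 2, 1))
  expect_equal(dim(build_inline(2)$adjacency), c(2L, 2L))

  Tg <- build_triangle()
  expect_equal(neighbors(Tg, 1), c(2L, 3L))
  expect_equal(max_degree(Tg), 2)
  To <- build_triangle(oriented = TRUE)
  expect_true(all(rowSums(neighbor_matrix_for_test(To)) == 1))

  R <- build_roundabout()
  expect_equal(unname(rowSums(R$adjacency)), c(1, 3, 2, 2, 3, 1))
  expect_equal(max_degree(R), 3)
  # removing node 4 leaves the chain 1-2-3-5-6
  keep <- c(1, 2, 3, 5, 6)
  sub <- R$adjacency[keep, keep]
  expect_equal(sub, build_inline(5)$adjacency)
})

test_that("undirected neighbor relation is symmetric", {
  for (G in list(build_inline(5), build_triangle(), build_roundabout())) {
    for (i in seq_len(G$N)) {
      for (j in neighbors(G, i)) expect_true(i %in% neighbors(G, j))
    }
  }
})

test_that("stability bound is 1/max-degree and monotone under edge addition", {
  expect_equal(stability_bound(build_inline(3)), 0.5)
  expect_equal(stability_bound(build_triangle()), 0.5)
  expect_equal(stability_bound(build_roundabout()), 1 / 3)
  expect_equal(stability_bound(network_graph(matrix(0, 1, 1))), Inf)
  # add edges one at a time to an empty graph: bound never increases
  M <- matrix(0, 4, 4)
  prev <- Inf
  for (e in list(c(1, 2), c(2, 3), c(3, 4), c(1, 3), c(1, 4))) {
    M[e[1], e[2]] <- M[e[2], e[1]] <- 1
    b <- stability_bound(network_graph(M))
    expect_lte(b, prev)
    prev <- b
  }
})

test_that("transport stability margins implement the Lyapunov condition", {
  G <- build_inline(3)
  states <- rbind(c(0.9, 0.1), c(0.9, 0.1), c(0.9, 0.1))
  rep <- transport_stability_margins(G, HDG, c(0.5, 0.5), states, nu = 0.1)
  # node 2 has two neighbors: 2.9 - 2.26 - 0.2
  expect_equal(rep$margins[2], 0.44)
  expect_true(rep$satisfied)
  # at the equilibrium itself the first two terms cancel: margin is -nu|c(i)|
  at_eq <- matrix(0.5, 3, 2)
  rep2 <- transport_stability_margins(G, HDG, c(0.5, 0.5), at_eq, nu = 0.1)
  expect_equal(rep2$margins, -0.1 * c(1, 2, 1))
  expect_false(rep2$satisfied)
  # nu = 0 reduces to the pointwise ESS inequality
  pts <- sweep_points(2, 10, seed = 4)
  rep3 <- transport_stability_margins(build_inline(nrow(pts)), HDG, c(0.5, 0.5),
                                      pts, nu = 0)
  gaps <- apply(pts, 1, function(x) ess_gap(HDG, c(0.5, 0.5), x))
  expect_equal(rep3$margins, gaps)
  expect_true(all(rep3$margins > 0))  # strict inequality off the ESS
})

test_that("oriented variants follow the incoming-flow convention", {
  To <- build_triangle(oriented = TRUE)
  expect_equal(neighbors(To, 2), 1L)  # arc 1 -> 2 feeds node 2
  expect_equal(neighbors(To, 1), 3L)
  Ro <- build_roundabout(oriented = TRUE)
  expect_equal(neighbors(Ro, 2), c(1L, 4L))
  expect_equal(neighbors(Ro, 6), 5L)
  # out convention flips the relation
  Out <- network_graph(To$adjacency, directed = TRUE, direction = "out")
  expect_equal(neighbors(Out, 1), 2L)
})

test_that("edge-list CSV round-trips losslessly", {
  G <- build_roundabout()
  tau <- matrix(0, 6, 6)
  tau[G$adjacency == 1] <- 0.5
  G <- network_graph(G$adjacency, nu = 0.25, tau = tau)
  path <- withr::local_tempfile(fileext = ".csv")
  write_edge_list(G, path)
  G2 <- read_edge_list(path)
  expect_equal(G2$adjacency, G$adjacency)
  expect_equal(G2$nu[G$adjacency == 1], G$nu[G$adjacency == 1])
  expect_equal(G2$tau[G$adjacency == 1], G$tau[G$adjacency == 1])
  expect_null(G2$p)
})

test_that("malformed graphs are rejected", {
  expect_error(network_graph(matrix(1, 2, 2)), "self-loops")
  expect_error(network_graph(rbind(c(0, 1), c(0, 0))), "symmetric")
  expect_error(build_inline(1), "at least 2")
  expect_error(neighbors(build_inline(3), 9), "out of range")
  expect_error(build_network("petersen"), "unknown network")
})
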