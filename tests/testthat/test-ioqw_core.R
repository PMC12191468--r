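test_that("coin entries match hand-evaluated values in both variants", {
  tri <- load_fixture("triangle")
  C <- build_coin(tri)$C
  expect_equal(unname(diag(C)), rep(1, 3))
  expect_equal(C["1", "2"], -1 / 3)
  expect_identical(C, t(C))

  p3 <- load_fixture("path3")
  Cp <- build_coin(p3)$C
  expect_equal(Cp["1", "3"], 1 / 2)   # distance 2, no edge
  expect_equal(Cp["1", "2"], -1 / 3)

  # disconnected pairs take the Pa -> Inf limit, 0
  gd <- read_edge_list(c("a b", "c d"))
  Cd <- build_coin(gd)$C
  expect_equal(Cd["a", "c"], 0)
  expect_equal(Cd["a", "d"], 0)

  # ratio variant: edges 1/3, diagonal 1
  Cr <- build_coin(tri, variant = "ratio")$C
  expect_equal(Cr["1", "2"], 1 / 3)
  expect_equal(unname(diag(Cr)), rep(1, 3))

  # max_distance truncation sends far pairs to the disconnected limit
  p3t <- build_coin(p3, max_distance = 1)$C
  expect_equal(p3t["1", "3"], 0)
  expect_equal(p3t["1", "2"], -1 / 3)
})

test_that("shift operator is the direct sum of identity and row-stochastic Ahat", {
  p3 <- load_fixture("path3")
  s <- build_shift(p3)
  expect_equal(unname(s$Ahat["2", ]), c(0.5, 0, 0.5))
  expect_equal(unname(rowSums(s$Ahat)), rep(1, 3))

  st <- load_fixture("star", n = 5)
  expect_equal(unname(build_shift(st)$Ahat["1", -1]), rep(1 / 4, 4))

  S <- as_shift_matrix(s)
  expect_equal(S[1:3, 1:3], diag(3))
  expect_true(all(S[1:3, 4:6] == 0) && all(S[4:6, 1:3] == 0))

  # isolated node: zero row, no NaN
  gi <- new_ioqw_graph(cbind("a", "b"), labels = c("a", "b", "z"))
  expect_equal(unname(build_shift(gi)$Ahat["z", ]), c(0, 0, 0))
})

test_that("evolution operator equals its block-diagonal closed form", {
  p3 <- load_fixture("path3")
  coin <- build_coin(p3)
  s <- build_shift(p3)

  u0 <- build_evolution(s, coin, t = 0)
  expect_equal(as_evolution_matrix(u0), diag(6))

  u1 <- build_evolution(s, coin, t = 1)
  expect_equal(u1$top, coin$C)
  expect_equal(u1$bottom, s$Ahat %*% coin$C)

  u2 <- build_evolution(s, coin, t = 2)
  expect_equal(as_evolution_matrix(u2),
               as_evolution_matrix(u1) %*% as_evolution_matrix(u1))
  expect_error(build_evolution(s, coin, t = -1), "non-negative")

  # structure oracle: dense 2N x 2N power of S.L(C) matches the blocks
  for (seed in c(11, 12, 13)) {
    g <- rand_graph(sample(6:15, 1), p = 0.4, seed = seed)
    coin <- build_coin(g); s <- build_shift(g)
    L <- matrix(0, 2 * g$N, 2 * g$N)
    L[seq_len(g$N), seq_len(g$N)] <- coin$C
    L[g$N + seq_len(g$N), g$N + seq_len(g$N)] <- coin$C
    U_dense <- as_shift_matrix(s) %*% L
    U2_dense <- U_dense %*% U_dense
    expect_equal(as_evolution_matrix(build_evolution(s, coin, 2)), U2_dense,
                 tolerance = 1e-10)
  }
})

test_that("initial state is uniform with unit norm", {
  g2 <- read_edge_list("a b")
  expect_equal(initial_state(g2), rep(0.5, 4))
  k <- load_fixture("karate")
  psi <- initial_state(k)
  expect_lt(abs(sqrt(sum(psi^2)) - 1), 1e-12)
  expect_equal(length(unique(psi)), 1)
})

test_that("measurement vectors carry degree/M weights on neighbours in both sectors", {
  p3 <- load_fixture("path3")
  m <- measurement_vector(p3, "2")
  expect_equal(m, c(0.5, 0, 0.5, 0.5, 0, 0.5))

  st <- load_fixture("star", n = 5)
  leaf <- measurement_vector(st, "2")     # single neighbour: centre, deg 4, M 4
  expect_equal(sort(unique(leaf)), c(0, 1))
  expect_equal(sum(leaf > 0), 2)

  gi <- new_ioqw_graph(cbind("a", "b"), labels = c("a", "b", "z"))
  expect_equal(measurement_vector(gi, "z"), numeric(6))
  expect_error(measurement_vector(p3, "nope"), "unknown node")
})

test_that("scores are non-negative and equal on vertex-transitive graphs", {
  g6 <- load_fixture("cycle", n = 6)
  r <- suppressWarnings(rank_nodes(g6))
  expect_true(all(r$scores >= 0))
  expect_lt(diff(range(r$scores)), 1e-10)
  # tie-break on equal scores is ascending label
  expect_equal(r$ranking, as.character(1:6))
})

test_that("observe() on the evolution object matches the fast pipeline", {
  for (seed in c(21, 22)) {
    g <- rand_graph(12, p = 0.35, seed = seed)
    coin <- build_coin(g); s <- build_shift(g)
    u <- build_evolution(s, coin, t = 2)
    expect_equal(observe(u, initial_state(g), g)$scores,
                 rank_nodes(g, t = 2)$scores, tolerance = 1e-12)
  }
})

test_that("scaling the initial state rescales scores without reordering", {
  g <- load_fixture("karate")
  coin <- build_coin(g); s <- build_shift(g)
  u <- build_evolution(s, coin, t = 2)
  base <- observe(u, initial_state(g), g)
  scaled <- observe(u, 3.7 * initial_state(g), g)
  expect_equal(scaled$scores, 3.7^2 * base$scores, tolerance = 1e-10)
  expect_identical(scaled$ranking, base$ranking)
})

test_that("ranking commutes with node relabelling (permutation equivariance)", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(6:30, 1)
    g <- rand_graph(n, p = runif(1, 0.15, 0.5), seed = 300 + rep)
    perm <- sample(n)
    # relabel node i -> p_i, keeping the same structure
    el <- igraph::as_edgelist(g$ig)
    relab <- stats::setNames(as.character(perm), g$labels)
    g2 <- new_ioqw_graph(cbind(relab[el[, 1]], relab[el[, 2]]),
                         labels = as.character(seq_len(n)))
    r1 <- suppressWarnings(rank_nodes(g))
    r2 <- suppressWarnings(rank_nodes(g2))
    expect_equal(unname(r2$scores[relab[names(r1$scores)]]),
                 unname(r1$scores), tolerance = 1e-9)
  }
})

test_that("the walk is not unitary: total score is not conserved", {
  g <- load_fixture("karate")
  r <- rank_nodes(g)
  expect_gt(abs(sum(r$scores) - 1), 0.01)
})

test_that("karate ranking puts the two leaders first and finds the known influential set", {
  r <- rank_nodes(load_fixture("karate"), t = 2)
  expect_equal(r$ranking[1:3], c("1", "34", "3"))
  expect_equal(r$ranking[1:6], c("1", "34", "3", "33", "2", "14"))
  expect_setequal(r$ranking[1:10],
                  c("1", "34", "3", "33", "2", "14", "4", "8", "9", "32"))
  # the ratio variant misses one of the reference top-10 nodes
  rr <- rank_nodes(load_fixture("karate"), t = 2, variant = "ratio")
  expect_equal(length(intersect(rr$ranking[1:10], r$ranking[1:10])), 9)
})

test_that("degenerate inputs are handled", {
  expect_error(rank_nodes(load_fixture("karate"), t = 1.5), "integer")
  expect_warning(rank_nodes(read_edge_list(c("a b", "c d"))), "disconnected")
})
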