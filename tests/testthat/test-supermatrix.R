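test_that("supermatrix assembly fills declared blocks and alternative sinks", {
  md <- quiet_synth(seed = 2)
  net <- md$network
  pri <- md$truth$alternative_priorities
  sm <- build_supermatrix(net, pri)
  n_nodes <- length(danpselect:::network_elements(net)) +
    length(net$alternatives)
  expect_equal(dim(sm$W), c(24, 24))
  expect_equal(n_nodes, 24)
  # alternatives are identity sinks
  alts <- net$alternatives
  expect_equal(sm$W[alts, alts], diag(6), ignore_attr = TRUE)
  # missing context is reported by name
  expect_error(build_supermatrix(net, pri[-3]), names(pri)[3])
})

test_that("a network with no outgoing blocks is flagged non-rankable", {
  net <- decision_network(
    "g", list(cluster("K", "criterion", c("k1", "k2"))), c("A", "B"),
    blocks = list()
  )
  raw <- build_supermatrix(net, priorities = list())
  expect_error(weight_supermatrix(raw), "not rankable")
})

test_that("weighted supermatrix columns sum to one", {
  md <- quiet_synth(seed = 3)
  raw <- build_supermatrix(md$network, md$truth$alternative_priorities,
                           inner_blocks = lapply(md$truth$influence, function(A) {
                             inner_dependence(total_relation(
                               normalize_direct_matrix(A)$M))
                           }))
  w <- weight_supermatrix(raw)
  expect_lt(max(abs(colSums(w$W) - 1)), 1e-9)
  # limit preserves column-stochasticity
  l <- limit_supermatrix(w)
  expect_lt(max(abs(colSums(l$W) - 1)), 1e-8)
})

test_that("limit supermatrix matches brute-force repeated multiplication", {
  set.seed(31)
  for (rep in 1:8) {
    n <- sample(6:10, 1)
    W <- rand_stochastic(n)
    L <- limit_supermatrix(W)
    P <- W
    for (t in 1:600) P <- W %*% P
    expect_lt(max(abs(L$W - P)), 1e-8)
    expect_equal(L$info$path, "power")
  }
})

test_that("cyclic structures fall back to the Cesaro average", {
  L <- limit_supermatrix(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(unname(L$W), matrix(0.5, 2, 2))
  expect_equal(L$info$path, "cesaro")

  # identical columns converge in one squaring
  W <- matrix(c(0.3, 0.7, 0.3, 0.7), 2, 2)
  L2 <- limit_supermatrix(W)
  expect_equal(L2$W, W, ignore_attr = TRUE)
  expect_equal(L2$info$squarings, 1L)

  expect_error(limit_supermatrix(matrix(c(0.5, 0.6, 0.5, 0.4), 2, 2)),
               "column-stochastic")
})

test_that("a strict hierarchy's limit composes the level priorities", {
  # goal-less 2-level hierarchy: criteria -> alternatives
  net <- decision_network(
    "g", list(cluster("K", "criterion", c("k1", "k2"))), c("A", "B"),
    blocks = list(list(from = "K", to = "alternatives")),
    cluster_weights = c(K = 1)
  )
  pri <- list(k1 = c(A = 0.9, B = 0.1), k2 = c(A = 0.2, B = 0.8))
  L <- limit_supermatrix(weight_supermatrix(build_supermatrix(net, pri)))
  # each criterion column carries exactly its alternative priorities
  expect_equal(L$W[c("A", "B"), "k1"], pri$k1, tolerance = 1e-9)
  expect_equal(L$W[c("A", "B"), "k2"], pri$k2, tolerance = 1e-9)
  gw <- c(k1 = 0.6, k2 = 0.4)
  composed <- as.vector(L$W[c("A", "B"), c("k1", "k2")] %*% gw)
  expect_equal(composed, unname(0.6 * pri$k1 + 0.4 * pri$k2),
               tolerance = 1e-9)
})

test_that("identity inner dependence does not change absorbed priorities", {
  md <- quiet_synth(seed = 4)
  net <- md$network
  pri <- md$truth$alternative_priorities
  ids <- lapply(net$clusters, function(cl) diag(length(cl$elements)))
  names(ids) <- danpselect:::network_cluster_labels(net)
  l_plain <- limit_supermatrix(weight_supermatrix(build_supermatrix(net, pri)))
  l_ident <- limit_supermatrix(weight_supermatrix(
    build_supermatrix(net, pri, inner_blocks = ids)))
  expect_lt(max(abs(l_plain$W - l_ident$W)), 1e-9)
})

test_that("block normalisation modes differ only by the half factor", {
  # irreducible stochastic matrix: every node keeps stationary mass
  set.seed(41)
  W <- rand_stochastic(6)
  l <- limit_supermatrix(W)
  l$node_cluster[] <- rep(c("K1", "K2"), each = 3)
  unit <- block_normalize(l, mode = "unit")
  half <- block_normalize(l, mode = "half")
  expect_equal(half$weight, unit$weight / 2)
  expect_equal(sum(unit$weight[unit$block == "K1"]), 1)
  expect_equal(sum(half$weight[half$block == "K2"]), 0.5)

  # vector method: per-block targets
  x <- c(a = 1, b = 3, c = 2, d = 2)
  blocks <- c(a = "K1", b = "K1", c = "K2", d = "K2")
  u <- block_normalize(x, blocks, mode = "unit")
  expect_equal(u$weight, c(0.25, 0.75, 0.5, 0.5))
  expect_error(block_normalize(c(a = 0, b = 0), c(a = "K", b = "K")),
               "zero mass")
})
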