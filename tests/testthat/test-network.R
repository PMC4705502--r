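test_that("the bundled case-study network has the published structure", {
  f <- system.file("extdata", "sixsigma_network.yaml", package = "danpselect")
  net <- load_network(f)
  sizes <- vapply(net$clusters, function(cl) length(cl$elements), integer(1))
  expect_identical(unname(sizes), c(3L, 5L, 4L, 3L, 3L))
  expect_length(net$alternatives, 6)
  expect_length(danpselect:::subcriteria(net), 15)
  expect_equal(sum(danpselect:::criteria_weights(net)), 1)
  # in-code fixture and shipped config agree
  expect_equal(net, sixsigma_model()$network)
})

test_that("minimal and malformed network documents validate as specified", {
  doc <- list(goal = "g",
              clusters = list(list(label = "K", kind = "criterion",
                                   elements = list("k1"))),
              alternatives = list("a1"))
  net <- load_network(doc)
  expect_s3_class(net, "decision_network")

  doc$blocks <- list(list(from = "Benfit", to = "K"))
  expect_error(load_network(doc), "Benfit")

  doc$blocks <- NULL
  doc$clusters[[1]]$elements <- list("k1", "k1")
  expect_error(load_network(doc), "uplicate")

  expect_error(decision_network("g", list(cluster("K", "criterion", "k1")),
                                alternatives = character()),
               "alternative")
  expect_error(decision_network("g",
                                list(cluster("K", "criterion", c("x", "y"))),
                                "a", cluster_weights = c(K = 0.8)),
               "sum to 1")
})

test_that("aggregation schemes behave as documented", {
  two <- function(v) matrix(c(1, 1 / v, v, 1), 2, 2,
                            dimnames = rep(list(c("x", "y")), 2))
  inf2 <- function(v) matrix(c(0, 1, v, 0), 2, 2,
                             dimnames = rep(list(c("x", "y")), 2))
  j1 <- judgment_set("p1", anp = list(K = two(2)), dematel = list(K = inf2(3)))
  j2 <- judgment_set("p2", anp = list(K = two(8)), dematel = list(K = inf2(4)))

  agg <- aggregate_judgments(list(j1, j2))
  expect_equal(agg$anp$K["x", "y"], 4)       # sqrt(2 * 8)
  expect_equal(agg$anp$K["y", "x"], 1 / 4)
  expect_equal(agg$dematel$K["x", "y"], 3.5) # (3 + 4) / 2

  # single participant: identity
  expect_equal(aggregate_judgments(list(j1))$anp, j1$anp)
  # permutation invariance over participants
  expect_equal(aggregate_judgments(list(j2, j1)), agg)
  # mismatched contexts reported by name
  j3 <- judgment_set("p3", anp = list(Q = two(2)), dematel = list(K = inf2(1)))
  expect_error(aggregate_judgments(list(j1, j3)), "context 'Q'|context 'K'")
})

test_that("geometric aggregation preserves reciprocity on random matrices", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(3:7, 1)
    sets <- lapply(1:4, function(p) {
      judgment_set(paste0("p", p), anp = list(K = rand_reciprocal(n)))
    })
    agg <- aggregate_judgments(sets)$anp$K
    expect_lt(max(abs(t(agg) * agg - 1)), 1e-12)
  }
})

test_that("results write/read round trip preserves weights exactly", {
  tm <- tiny_model()
  res <- run_anp(tm$network, tm$judgments)
  d <- withr::local_tempdir()
  paths <- write_results(res, d)
  expect_true(all(file.exists(paths)))
  back <- read_weight_table(paths[["weights"]])
  expect_equal(back$GW, res$weights$GW, tolerance = 1e-15)
  expect_equal(back$node, res$weights$node)
  manifest <- jsonlite::read_json(paths[["manifest"]])
  expect_equal(manifest$method, "ANP")
  expect_error(write_results(list(), tempfile()), "mcdm_result")
})

test_that("judgment directory trees round trip", {
  tm <- tiny_model()
  d <- withr::local_tempdir()
  write_judgments(tm$judgments, d)
  back <- load_judgments(d)
  expect_length(back, 1)
  expect_equal(back[[1]]$anp[order(names(back[[1]]$anp))],
               tm$judgments$anp[order(names(tm$judgments$anp))])
  expect_equal(back[[1]]$dematel[order(names(back[[1]]$dematel))],
               tm$judgments$dematel[order(names(tm$judgments$dematel))])
})
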